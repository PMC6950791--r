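q6: [0, 3, 5, 10]
q8: [0, 1, 2, 3]
q9: [1, 2, 3, 4]
q10: [0, 3, 5, 10]
q13: [0, 1, 2, 3]
q14: [1, 2, 3, 4]
q15: [0, 3, 5, 10]
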