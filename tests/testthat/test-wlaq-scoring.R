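test_that("default points table satisfies the scale invariants", {
  pts <- wlaq_points_default()
  expect_length(pts, 7)
  for (q in names(pts)) {
    expect_length(pts[[q]], 4)
    expect_true(all(pts[[q]] >= 0))
    expect_false(is.unsorted(pts[[q]]))
  }
  expect_identical(sum(vapply(pts, max, integer(1))), 44L)
})

test_that("points config round-trips through YAML and rejects bad tables", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_points_config(wlaq_points_default(), path)
  expect_identical(unclass(read_points_config(path)),
                   unclass(wlaq_points_default()))
  shipped <- system.file("extdata", "points_default.yaml", package = "wlaqfit")
  expect_identical(unclass(read_points_config(shipped)),
                   unclass(wlaq_points_default()))
  bad <- wlaq_points_default()
  bad$q6 <- c(0L, 3L, 5L, 11L) # maxima no longer sum to 44
  expect_error(validate_points(bad), "44")
  bad <- wlaq_points_default()
  bad$q9 <- c(4L, 3L, 2L, 1L)
  expect_error(validate_points(bad), "non-decreasing")
})

test_that("PA score matches hand-computed examples", {
  # ceiling: every question at the heaviest option
  expect_identical(
    score_pa(make_response(q6 = 4, q8 = 4, q9 = 4, q10 = 4,
                           q13 = 4, q14 = 4, q15 = 4))$value, 44L)
  # floor: all option 1, conditional items skipped
  expect_identical(score_pa(make_response())$value, 0L)
  # mixed answers: 5 + 2 + 2 + 3 + 0 + 0 + 0
  expect_identical(
    score_pa(make_response(q6 = 3, q8 = 3, q9 = 2, q10 = 2, q13 = 1))$value,
    12L)
})

test_that("skip logic zeroes Q9/Q10 whenever Q8 = 1, regardless of storage", {
  stored <- score_pa(make_response(q8 = 1, q9 = 4, q10 = 4))
  absent <- score_pa(make_response(q8 = 1, q9 = NA, q10 = NA))
  expect_identical(stored$value, 0L)
  expect_identical(stored$value, absent$value)
  expect_identical(stored$per_question_points[["q9"]], 0L)
  # symmetric family: Q13 gates Q14/Q15
  expect_identical(
    score_pa(make_response(q13 = 1, q14 = 4, q15 = 4))$value, 0L)
})

test_that("score is bounded, monotone in options, and matches a plain oracle", {
  set.seed(11)
  resp <- random_responses(200)
  for (i in seq_len(nrow(resp))) {
    r <- as.list(resp[i, ])
    s <- score_pa(r)
    expect_gte(s$value, 0)
    expect_lte(s$value, 44)
    expect_identical(s$value, as.integer(oracle_score(r)))
    expect_identical(s$value, sum(s$per_question_points))
    # raising one answerable option never decreases the score
    for (q in c("q6", "q8", "q13")) {
      if (r[[q]] < 4) {
        r2 <- r
        r2[[q]] <- r[[q]] + 1
        if (q == "q8" && r[[q]] == 1) { r2$q9 <- 1; r2$q10 <- 1 }
        if (q == "q13" && r[[q]] == 1) { r2$q14 <- 1; r2$q15 <- 1 }
        expect_gte(score_pa(r2)$value, s$value)
      }
    }
  }
})

test_that("missing required conditional answers raise errors naming the field", {
  expect_error(score_pa(make_response(q8 = 3, q9 = NA, q10 = 2)),
               "q9 required when q8>1")
  expect_error(score_pa(make_response(q13 = 2, q14 = 1, q15 = NA)),
               "q15 required when q13>1")
  expect_error(score_pa(make_response(q6 = 5)), "q6")
  expect_error(score_pa(make_response(q6 = 0)), "q6")
})

test_that("total sitting time adds the four domains", {
  expect_equal(total_sitting_time(make_response(sit = c(12, 382, 241, 513))),
               1148)
  expect_equal(total_sitting_time(make_response(sit = c(16, 435, 183, 566))),
               1200)
  expect_equal(total_sitting_time(make_response(sit = c(0, 0, 0, 0))), 0)
  expect_error(total_sitting_time(make_response(sit = c(-1, 0, 0, 0))),
               "non-negative")
  # additive and order-invariant in the domain fields
  r <- make_response(sit = c(10, 20, 30, 40))
  perm <- r[c(1:7, 10, 8, 11, 9)]
  expect_equal(total_sitting_time(perm), total_sitting_time(r))
})

test_that("validate_cohort rejects invalid rows with machine-readable reasons", {
  cohort <- generate_cohort(cohort_spec(n = 5, seed = 21))
  cohort$q8[2] <- 3L
  cohort$q9[2] <- NA_integer_
  res <- suppressMessages(validate_cohort(cohort))
  expect_identical(nrow(res$participants), 4L)
  expect_identical(res$rejections$row, 2L)
  expect_match(res$rejections$reason, "q9 required when q8>1")

  cohort <- generate_cohort(cohort_spec(n = 3, seed = 22))
  cohort$sit_work_min[1] <- 1500
  res <- suppressMessages(validate_cohort(cohort))
  expect_identical(nrow(res$participants), 2L)
  expect_match(res$rejections$reason[1], "1440")
})

test_that("validate_cohort handles empty input, duplicates, and BMI checks", {
  empty <- generate_cohort(cohort_spec(n = 1, seed = 1))[0, ]
  res <- validate_cohort(empty)
  expect_identical(nrow(res$participants), 0L)
  expect_identical(nrow(res$rejections), 0L)

  dup <- generate_cohort(cohort_spec(n = 2, seed = 2))
  dup$id <- c("A", "A")
  expect_error(suppressMessages(validate_cohort(dup)), "duplicated")

  co <- generate_cohort(cohort_spec(n = 2, seed = 3))
  co$bmi[1] <- NA_real_                       # blank BMI: recomputed
  co$bmi[2] <- co$bmi[2] + 5                  # inconsistent BMI: rejected
  res <- suppressMessages(validate_cohort(co))
  expect_identical(nrow(res$participants), 1L)
  expect_equal(res$participants$bmi[1],
               co$weight_kg[1] / (co$height_cm[1] / 100)^2)
  expect_match(res$rejections$reason, "bmi inconsistent")
})

test_that("cohort files round-trip through read/write", {
  cohort <- generate_cohort(cohort_spec(n = 20, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(nrow(back), 20L)
  expect_equal(back$vo2max, cohort$vo2max, tolerance = 1e-12)
  expect_identical(as.integer(back$q9), cohort$q9)
  res <- suppressMessages(validate_cohort(back))
  expect_identical(nrow(res$rejections), 0L)
  expect_error(read_cohort(withr::local_tempfile()), "not found")
})
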