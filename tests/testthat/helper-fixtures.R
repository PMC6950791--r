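# Shared fixtures and independent oracles used across test files.

# A complete, valid response with every question answered.
make_response <- function(q6 = 1, q8 = 1, q9 = NA, q10 = NA,
                          q13 = 1, q14 = NA, q15 = NA,
                          sit = c(12, 382, 241, 513)) {
  list(q6 = q6, q8 = q8, q9 = q9, q10 = q10,
       q13 = q13, q14 = q14, q15 = q15,
       sit_commute_min = sit[1], sit_work_min = sit[2],
       sit_leisure_workday_min = sit[3], sit_nonworkday_min = sit[4])
}

# Random valid responses as a tibble (fixed by the caller's seed).
random_responses <- function(n) {
  q8 <- sample(1:4, n, replace = TRUE)
  q13 <- sample(1:4, n, replace = TRUE)
  tibble::tibble(
    q6 = sample(1:4, n, replace = TRUE),
    q8 = q8,
    q9 = ifelse(q8 > 1, sample(1:4, n, replace = TRUE), NA_integer_),
    q10 = ifelse(q8 > 1, sample(1:4, n, replace = TRUE), NA_integer_),
    q13 = q13,
    q14 = ifelse(q13 > 1, sample(1:4, n, replace = TRUE), NA_integer_),
    q15 = ifelse(q13 > 1, sample(1:4, n, replace = TRUE), NA_integer_),
    sit_commute_min = runif(n, 0, 60),
    sit_work_min = runif(n, 0, 600),
    sit_leisure_workday_min = runif(n, 0, 300),
    sit_nonworkday_min = runif(n, 0, 800)
  )
}

# Score one response row with plain lookups -- an oracle independent of the
# vectorised implementation path.
oracle_score <- function(r, pts = wlaq_points_default()) {
  total <- pts$q6[r$q6] + pts$q8[r$q8] + pts$q13[r$q13]
  if (r$q8 > 1) total <- total + pts$q9[r$q9] + pts$q10[r$q10]
  if (r$q13 > 1) total <- total + pts$q14[r$q14] + pts$q15[r$q15]
  total
}

# Literal leave-one-out PRESS: refit the model n times, one row held out.
brute_force_press <- function(cohort, predictors, outcome = "vo2max") {
  fml <- stats::reformulate(predictors, response = outcome)
  sum(vapply(seq_len(nrow(cohort)), function(i) {
    fit <- stats::lm(fml, data = cohort[-i, ])
    (cohort[[outcome]][i] -
       stats::predict(fit, newdata = cohort[i, ]))^2
  }, numeric(1)))
}

# A small numeric cohort with arbitrary (non-questionnaire) predictors for
# regression edge-case tests.
toy_cohort <- function(n, p = 2) {
  X <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  dat <- tibble::as_tibble(X)
  dat$vo2max <- 30 + X %*% rnorm(p) + rnorm(n, 0, 2)
  dat$vo2max <- as.numeric(dat$vo2max)
  dat$id <- as.character(seq_len(n))
  dat
}

# Analytic mean of a normal truncated to [lo, hi]: the generator's true
# population mean for a marginal draw.
trunc_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Expected population mean of the PA score under a cohort spec: direct
# expectation over the option vectors (conditional items weighted by the
# probability their gate question exceeds option 1).
expected_pa_mean <- function(spec, pts = wlaq_points_default()) {
  one_sex <- function(pr) {
    p_q8 <- 1 - pr$q8[1]
    p_q13 <- 1 - pr$q13[1]
    sum(pr$q6 * pts$q6) + sum(pr$q8 * pts$q8) + sum(pr$q13 * pts$q13) +
      p_q8 * (sum(pr$q9 * pts$q9) + sum(pr$q10 * pts$q10)) +
      p_q13 * (sum(pr$q14 * pts$q14) + sum(pr$q15 * pts$q15))
  }
  w <- spec$sex_fraction_male
  (1 - w) * one_sex(spec$option_probs$F) + w * one_sex(spec$option_probs$M)
}
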