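test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(3, 10)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("structural signs propagate into cohort correlations", {
  co <- generate_cohort(cohort_spec(n = 3000, seed = 111))
  expect_gt(pearson_r(co$pa_score, co$vo2max)$r, 0)
  expect_lt(pearson_r(co$age, co$vo2max)$r, 0)
})

test_that("r on standardised inputs equals the OLS slope of z(y) on z(x)", {
  set.seed(121)
  x <- rnorm(80)
  y <- 0.6 * x + rnorm(80, 0, 0.8)
  dat <- tibble::tibble(zx = as.numeric(scale(x)),
                        vo2max = as.numeric(scale(y)),
                        id = as.character(1:80))
  slope <- unname(fit_ols(dat, "zx")$coefficients["zx"])
  expect_equal(slope, pearson_r(x, y)$r, tolerance = 1e-12)
})

test_that("t and chi-squared tests behave classically", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 6) # pooled df = n1 + n2 - 2
  expect_error(two_sample_t(1, x), "at least 2")
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("the sex difference in body weight is detected with near-full power", {
  # group parameters of the emulated cohort's body weight
  set.seed(131)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    women <- rnorm(93, 54.2, 8.1)
    men <- rnorm(105, 68.7, 9.1)
    if (two_sample_t(women, men)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.99)
})

test_that("constant error is zero when predictions equal measurements", {
  co <- generate_cohort(cohort_spec(n = 90, seed = 141))
  ce <- constant_error(co, predicted = co$vo2max)
  expect_true(all(abs(ce$ce[ce$n > 0]) < 1e-12))
})

test_that("whole-cohort CE vanishes for a model fitted on that cohort", {
  co <- generate_cohort(cohort_spec(n = 198, seed = 151))
  fit <- fit_ols(co, c("age", "sex", "bmi", "pa_score"))
  ce <- constant_error(co, fit)
  expect_lt(abs(ce$ce[ce$partition == "all"]), 1e-10)
})

test_that("subgroup CEs aggregate exactly to the whole-cohort CE", {
  co <- generate_cohort(cohort_spec(n = 157, seed = 161))
  ce <- constant_error(co, predicted = predict_cohort(co)$vo2max_pred)
  overall <- ce$ce[ce$partition == "all"]
  for (part in c("sex", "age", "fitness")) {
    sub <- ce[ce$partition == part & ce$n > 0, ]
    expect_identical(sum(sub$n), 157L)
    expect_equal(sum(sub$n * sub$ce) / sum(sub$n), overall, tolerance = 1e-12)
  }
})

test_that("fitness tertiles are equal-count thirds with stable ties", {
  t198 <- fitness_tertile_sizes <- table(wlaqfit:::fitness_tertile(rnorm(198)))
  expect_identical(as.integer(t198), c(66L, 66L, 66L))
  # ties broken by input order: first tied rows take the lower tertile
  tied <- wlaqfit:::fitness_tertile(rep(1, 6))
  expect_identical(as.character(tied),
                   c("Low", "Low", "Middle", "Middle", "High", "High"))
  # empty subgroup is reported, not an exception
  co <- generate_cohort(cohort_spec(n = 12, seed = 171))
  co$age <- rep(35, 12) # no 40-49 or 50-59 members
  ce <- constant_error(co, predicted = co$vo2max)
  row <- ce[ce$partition == "age" & ce$subgroup == "50-59", ]
  expect_identical(row$n, 0L)
  expect_true(is.na(row$ce))
})

test_that("ICC matches an independently computed reference", {
  # expected values frozen from an external mixed-model implementation
  v1 <- c(10, 12, 15, 20, 22, 25, 28, 30, 33, 35, 40, 44)
  v2 <- c(11, 10, 17, 19, 24, 23, 30, 28, 31, 38, 41, 42)
  res <- icc(v1, v2)
  expect_equal(res$icc, 0.9844011860255254, tolerance = 1e-12)
  expect_equal(round(res$ci_lower, 2), 0.95)
  expect_equal(round(res$ci_upper, 2), 1.00)

  w1 <- c(3, 5, 2, 8, 6, 9, 4, 7, 5, 6)
  w2 <- c(4, 3, 4, 6, 8, 7, 6, 5, 3, 8)
  res <- icc(w1, w2)
  expect_equal(res$icc, 0.5329593267882187, tolerance = 1e-12)
  expect_equal(round(res$ci_lower, 2), -0.15)
  expect_equal(round(res$ci_upper, 2), 0.86)

  res1 <- icc(w1, w2, model = "one-way")
  expect_equal(res1$icc, 0.5444596443228453, tolerance = 1e-12)
  expect_equal(round(res1$ci_lower, 2), -0.05)
  expect_equal(round(res1$ci_upper, 2), 0.86)
})

test_that("ICC invariants: range, CI ordering, classification rule", {
  p <- simulate_retest_pairs(40, between_share = 0.6, seed = 181)
  res <- icc(p$visit1, p$visit2)
  expect_true(res$icc >= -1 && res$icc <= 1)
  expect_lte(res$ci_lower, res$icc)
  expect_gte(res$ci_upper, res$icc)

  same <- c(5, 9, 14, 20, 26, 31)
  perfect <- icc(same, same)
  expect_equal(perfect$icc, 1)
  expect_identical(perfect$class, "excellent")

  expect_identical(classify_icc(0.39), "poor")
  expect_identical(classify_icc(0.40), "fair-to-good")
  expect_identical(classify_icc(0.75), "fair-to-good")
  expect_identical(classify_icc(0.76), "excellent")
  expect_identical(classify_icc(0.87), "excellent")
})

test_that("ICC rejects incomplete pairs and tiny samples", {
  expect_error(icc(c(1, 2, NA, 4, 5, 6), c(1, 2, 3, 4, 5, 6)), "incomplete")
  expect_error(icc(1:4, 1:4), "at least 5")
})

test_that("ICC estimator recovers the generating variance share", {
  reps <- 100
  est <- vapply(seq_len(reps), function(r) {
    p <- simulate_retest_pairs(2000, between_share = 0.87, seed = 9000 + r)
    icc(p$visit1, p$visit2)$icc
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.87), 0.01)
})

test_that("the reliability table covers every questionnaire-derived value", {
  co <- generate_cohort(cohort_spec(n = 97, seed = 191))
  v2 <- generate_retest(co, retest_spec(seed = 192))
  tab <- reliability_table(co, v2)
  expect_identical(nrow(tab), 13L)
  expect_true("PA score" %in% tab$measure)
  expect_identical(sum(grepl("^Sitting time", tab$measure)), 5L)
  expect_true(all(tab$ci_lower <= tab$icc & tab$icc <= tab$ci_upper))
  # imperfect repeatability: categorical items below 1
  expect_true(all(tab$icc[tab$measure == "PA score"] < 1))
  # row order must not matter: shuffle visit 2
  shuffled <- v2[sample(nrow(v2)), ]
  expect_equal(reliability_table(co, shuffled)$icc, tab$icc)
  bad <- v2
  bad$id[1] <- "missing-person"
  expect_error(reliability_table(co, bad), "same participant ids")
})
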