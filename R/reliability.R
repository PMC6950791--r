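#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return A tibble with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Unpaired Student's t-test (equal variances)
#'
#' Classical two-sample t with pooled variance, as conventionally used for
#' sex-difference comparisons of descriptive characteristics; Welch's
#' unequal-variance form is available behind `var_equal = FALSE`.
#'
#' @param x,y numeric vectors, each with n >= 2.
#' @param var_equal pool the variances (classical Student) if `TRUE`.
#' @return A tibble with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; tables are r x c counts (e.g. occupation
#' or answer-option frequencies by sex).
#'
#' @param counts matrix of non-negative integer counts.
#' @return A tibble with `chisq`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(chisq = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Constant-error validation by subgroup
#'
#' The constant error CE is the mean of (measured - predicted) VO2max; its
#' sign flags systematic under- (positive) or over- (negative) estimation
#' within a subgroup. Reports CE with SD for the whole cohort and for three
#' standard partitions: sex, age decade (30-39 / 40-49 / 50-59), and
#' fitness tertile -- equal-count thirds of the measured-VO2max rank, ties
#' broken by stable input order.
#'
#' @param cohort a cohort tibble with measured `vo2max`.
#' @param fit a `wlaq_fit` whose predictions are validated; it must have been
#'   fit on a cohort of the same size/order, or supply `predicted`.
#' @param predicted optional numeric vector of predictions overriding
#'   `fit$fitted`.
#' @return A tibble with one row per subgroup: `partition`, `subgroup`, `n`,
#'   `pct`, `measured_mean`, `measured_sd`, `predicted_mean`, `predicted_sd`,
#'   `ce`, `ce_sd`. Empty subgroups appear with `n = 0` and `NA` statistics.
#' @export
constant_error <- function(cohort, fit = NULL, predicted = NULL) {
  if (is.null(predicted)) {
    stopifnot(inherits(fit, "wlaq_fit"))
    predicted <- unname(fit$fitted)
  }
  measured <- cohort$vo2max
  if (anyNA(measured)) stop("all rows need measured vo2max", call. = FALSE)
  stopifnot(length(predicted) == length(measured))
  n_all <- length(measured)

  age_bin <- cut(cohort$age, breaks = c(-Inf, 40, 50, Inf),
                 labels = c("30-39", "40-49", "50-59"), right = FALSE)
  tertile <- fitness_tertile(measured)
  sex_lab <- factor(ifelse(cohort$sex == 1, "Men", "Women"),
                    levels = c("Women", "Men"))

  one <- function(partition, groups) {
    lv <- levels(groups)
    rows <- lapply(lv, function(g) {
      idx <- which(groups == g)
      n <- length(idx)
      if (n == 0) {
        return(tibble::tibble(
          partition = partition, subgroup = g, n = 0L, pct = 0,
          measured_mean = NA_real_, measured_sd = NA_real_,
          predicted_mean = NA_real_, predicted_sd = NA_real_,
          ce = NA_real_, ce_sd = NA_real_))
      }
      d <- measured[idx] - predicted[idx]
      tibble::tibble(
        partition = partition, subgroup = g, n = n, pct = 100 * n / n_all,
        measured_mean = mean(measured[idx]), measured_sd = stats::sd(measured[idx]),
        predicted_mean = mean(predicted[idx]), predicted_sd = stats::sd(predicted[idx]),
        ce = mean(d), ce_sd = stats::sd(d))
    })
    dplyr::bind_rows(rows)
  }

  d_all <- measured - predicted
  overall <- tibble::tibble(
    partition = "all", subgroup = "All", n = n_all, pct = 100,
    measured_mean = mean(measured), measured_sd = stats::sd(measured),
    predicted_mean = mean(predicted), predicted_sd = stats::sd(predicted),
    ce = mean(d_all), ce_sd = stats::sd(d_all))

  dplyr::bind_rows(
    overall,
    one("sex", sex_lab),
    one("age", age_bin),
    one("fitness", tertile)
  )
}

# Equal-count thirds of the measured-VO2max rank; stable first-occurrence
# ordering breaks ties, so sizes differ by at most one.
fitness_tertile <- function(vo2max) {
  n <- length(vo2max)
  ord <- order(vo2max)               # stable in R: ties keep input order
  sizes <- diff(round(seq(0, n, length.out = 4)))
  labels <- rep(c("Low", "Middle", "High"), times = sizes)
  out <- character(n)
  out[ord] <- labels
  factor(out, levels = c("Low", "Middle", "High"))
}

#' Intraclass correlation coefficient for test-retest pairs
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' computed from the mean squares of the subjects x visits layout, with an
#' F-distribution 95% confidence interval (McGraw-Wong). The qualitative
#' class follows the conventional thresholds: below 0.40 poor, 0.40-0.75
#' (inclusive) fair-to-good, above 0.75 excellent. A one-way random-effects
#' form is available for sensitivity analysis.
#'
#' @param visit1,visit2 numeric vectors of the two administrations; complete
#'   pairs only (any `NA` is an error), n >= 5.
#' @param model `"two-way"` (default; mixed, absolute agreement) or
#'   `"one-way"` (random effects).
#' @param conf confidence level, default 0.95.
#' @param measure optional measure name carried into the report.
#' @return A tibble of class `wlaq_icc`: `measure`, `icc`, `ci_lower`,
#'   `ci_upper`, `class`.
#' @examples
#' p <- simulate_retest_pairs(200, between_share = 0.87, seed = 7)
#' icc(p$visit1, p$visit2)
#' @export
icc <- function(visit1, visit2, model = c("two-way", "one-way"),
                conf = 0.95, measure = NA_character_) {
  model <- match.arg(model)
  stopifnot(length(visit1) == length(visit2))
  if (anyNA(visit1) || anyNA(visit2)) {
    stop("incomplete pair: ICC requires complete cases", call. = FALSE)
  }
  n <- length(visit1)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  k <- 2
  Y <- cbind(visit1, visit2)
  grand <- mean(Y)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  ss_total <- sum((Y - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  msr <- ss_rows / (n - 1)
  alpha <- 1 - conf

  if (model == "two-way") {
    ss_err <- ss_total - ss_rows - ss_cols
    mse <- ss_err / ((n - 1) * (k - 1))
    msc <- ss_cols / (k - 1)
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    est <- if (denom == 0) 1 else (msr - mse) / denom
    # McGraw & Wong CI for the absolute-agreement single-measure ICC
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) {
      lo <- hi <- est
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
      fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    }
  } else {
    ss_within <- ss_total - ss_rows
    msw <- ss_within / (n * (k - 1))
    denom <- msr + (k - 1) * msw
    est <- if (denom == 0) 1 else (msr - msw) / denom
    if (msw == 0) {
      lo <- hi <- est
    } else {
      fobs <- msr / msw
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  }
  out <- tibble::tibble(
    measure = measure, icc = est,
    ci_lower = min(lo, est), ci_upper = max(hi, est),
    class = classify_icc(est)
  )
  class(out) <- c("wlaq_icc", class(out))
  out
}

#' Qualitative reliability class of an ICC point estimate
#'
#' @param est ICC point estimate(s).
#' @return `"poor"` below 0.40, `"fair-to-good"` from 0.40 to 0.75
#'   inclusive, `"excellent"` above 0.75.
#' @export
classify_icc <- function(est) {
  ifelse(est < 0.40, "poor",
         ifelse(est <= 0.75, "fair-to-good", "excellent"))
}

# Question-level point contributions after skip logic, for reliability rows.
effective_points <- function(responses, points) {
  question_points(responses, points)
}

#' Test-retest reliability table for all questionnaire-derived values
#'
#' One ICC report per derived value: the four domain sitting times and their
#' total; exercise frequency for the two leisure domains (Q8, Q13 points);
#' exercise duration for the two leisure domains (Q9, Q14 points); PA or
#' exercise intensity for working time and the two leisure domains (Q6, Q10,
#' Q15 points); and the PA score -- thirteen rows. Question-level values enter
#' as their assigned point contributions after skip logic (a skipped item
#' counts 0), so pairs are complete whenever both administrations are.
#'
#' @param visit1,visit2 response tibbles for the two administrations, matched
#'   by `id` (same ids, any order).
#' @param points a `wlaq_points` table.
#' @param model ICC formulation, passed to [icc()].
#' @return A tibble with twelve `wlaq_icc` rows: `measure`, `icc`,
#'   `ci_lower`, `ci_upper`, `class`.
#' @export
reliability_table <- function(visit1, visit2,
                              points = wlaq_points_default(),
                              model = "two-way") {
  points <- validate_points(points)
  if (!setequal(visit1$id, visit2$id)) {
    stop("visit1 and visit2 must contain the same participant ids",
         call. = FALSE)
  }
  visit2 <- visit2[match(visit1$id, visit2$id), , drop = FALSE]
  p1 <- effective_points(visit1, points)
  p2 <- effective_points(visit2, points)
  total1 <- visit1$sit_commute_min + visit1$sit_work_min +
    visit1$sit_leisure_workday_min + visit1$sit_nonworkday_min
  total2 <- visit2$sit_commute_min + visit2$sit_work_min +
    visit2$sit_leisure_workday_min + visit2$sit_nonworkday_min

  rows <- list(
    list("Sitting time: commuting", visit1$sit_commute_min, visit2$sit_commute_min),
    list("Sitting time: working", visit1$sit_work_min, visit2$sit_work_min),
    list("Sitting time: leisure on workday", visit1$sit_leisure_workday_min,
         visit2$sit_leisure_workday_min),
    list("Sitting time: non-workday", visit1$sit_nonworkday_min,
         visit2$sit_nonworkday_min),
    list("Sitting time: total", total1, total2),
    list("Exercise frequency: leisure on workday", p1[, "q8"], p2[, "q8"]),
    list("Exercise frequency: non-workday", p1[, "q13"], p2[, "q13"]),
    list("Exercise duration: leisure on workday", p1[, "q9"], p2[, "q9"]),
    list("Exercise duration: non-workday", p1[, "q14"], p2[, "q14"]),
    list("PA intensity: working time", p1[, "q6"], p2[, "q6"]),
    list("Exercise intensity: leisure on workday", p1[, "q10"], p2[, "q10"]),
    list("Exercise intensity: non-workday", p1[, "q15"], p2[, "q15"]),
    list("PA score", rowSums(p1), rowSums(p2))
  )
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    icc(r[[2]], r[[3]], model = model, measure = r[[1]])
  }))
  out
}
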