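#' Fit an ordinary-least-squares VO2max prediction model
#'
#' Multiple linear regression of measured VO2max (or another outcome) on a
#' set of cohort predictors, with the fit statistics used to judge
#' non-exercise prediction equations: R^2, adjusted R^2, the standard error
#' of the estimate SEE = sqrt(SSE / (n - p - 1)), and %SEE = 100 x SEE /
#' mean(outcome).
#'
#' @param cohort a cohort tibble; every row must have the outcome and all
#'   predictors (no missing values).
#' @param predictors character vector of predictor column names, e.g.
#'   `c("age", "sex", "bmi", "pa_score")`; sex must be coded 0 = women,
#'   1 = men.
#' @param outcome outcome column name, default `"vo2max"`.
#' @param label optional model label carried into reports.
#' @return An object of class `wlaq_fit`: list with `label`, `outcome`,
#'   `predictors`, `n`, `p`, `coefficients` (intercept first), `r2`,
#'   `adj_r2`, `see`, `pct_see`, `fitted`, `residuals`, and the underlying
#'   `lm` fit.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, seed = 1))
#' fit <- fit_ols(cohort, c("age", "sex", "bmi", "pa_score"))
#' coef(fit$lm)
#' @export
fit_ols <- function(cohort, predictors, outcome = "vo2max", label = NULL) {
  stopifnot(length(predictors) >= 1)
  if (anyDuplicated(predictors)) {
    stop("duplicated predictors: ",
         paste(unique(predictors[duplicated(predictors)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[cols]
  if (anyNA(dat)) stop("missing values in outcome or predictors", call. = FALSE)
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 1) {
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }

  X <- stats::model.matrix(
    stats::reformulate(predictors), data = dat)
  qr_x <- qr(X, tol = 1e-12)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear predictors: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  cond <- kappa(X, exact = TRUE)
  if (cond > 1e8) {
    stop("design matrix condition number ", format(cond, digits = 3),
         " exceeds 1e8; rescale or drop predictors", call. = FALSE)
  }

  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = dat)
  y <- dat[[outcome]]
  sse <- sum(stats::residuals(fit)^2)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    warning("constant outcome: R^2 reported as 0", call. = FALSE)
    r2 <- 0
    adj_r2 <- 0
  } else {
    r2 <- 1 - sse / ss_total
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  see <- sqrt(sse / (n - p - 1))

  structure(list(
    label = label %||% paste(predictors, collapse = "+"),
    outcome = outcome,
    predictors = predictors,
    n = n, p = p,
    coefficients = stats::coef(fit),
    r2 = r2, adj_r2 = adj_r2,
    see = see,
    pct_see = if (mean(y) > 0) percent_see(see, mean(y)) else NA_real_,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    lm = fit
  ), class = "wlaq_fit")
}

#' @export
print.wlaq_fit <- function(x, ...) {
  cat("VO2max prediction model:", x$label, "\n")
  cat(sprintf("  n = %d, p = %d\n", x$n, x$p))
  print(round(x$coefficients, 4))
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, SEE = %.2f (%.1f%%)\n",
              x$r2, x$adj_r2, x$see, x$pct_see))
  invisible(x)
}

#' Standard error of the estimate as a percentage of the outcome mean
#'
#' @param see standard error of the estimate, in outcome units.
#' @param outcome_mean mean of the outcome; must be positive.
#' @return `100 * see / outcome_mean`.
#' @examples
#' percent_see(4.29, 38.39) # ~11.2
#' @export
percent_see <- function(see, outcome_mean) {
  if (outcome_mean <= 0) stop("outcome mean must be positive", call. = FALSE)
  100 * see / outcome_mean
}

#' PRESS leave-one-out cross-validation of a fitted model
#'
#' The predicted residual error sum of squares is the sum of squared
#' prediction errors when each case is predicted by the model refit without
#' it: PRESS = sum_i (y_i - yhat_(-i))^2. It is computed exactly through the
#' leverage identity e_i / (1 - h_ii) with h_ii the hat-matrix diagonal (no
#' literal refitting). From it, R2p = 1 - PRESS / SS_total and
#' SEEp = sqrt(PRESS / N) with N the cohort size -- note the divisor is N,
#' not N - p - 1, matching the cross-validation convention this mirrors.
#'
#' @param fit a `wlaq_fit` from [fit_ols()].
#' @return A list of class `wlaq_press` with `press_statistic`, `r2p`,
#'   `seep`.
#' @export
press <- function(fit) {
  stopifnot(inherits(fit, "wlaq_fit"))
  h <- stats::hatvalues(fit$lm)
  if (any(h >= 1 - 1e-10)) {
    stop("leave-one-out undefined: observation(s) ",
         paste(which(h >= 1 - 1e-10), collapse = ", "),
         " have leverage 1 (self-determined point)", call. = FALSE)
  }
  loo <- fit$residuals / (1 - h)
  press_stat <- sum(loo^2)
  y <- fit$fitted + fit$residuals
  ss_total <- sum((y - mean(y))^2)
  r2p <- if (ss_total == 0) 0 else 1 - press_stat / ss_total
  structure(list(
    press_statistic = press_stat,
    r2p = r2p,
    seep = sqrt(press_stat / fit$n)
  ), class = "wlaq_press")
}

#' @export
print.wlaq_press <- function(x, ...) {
  cat(sprintf("PRESS = %.3f, R2p = %.3f, SEEp = %.3f\n",
              x$press_statistic, x$r2p, x$seep))
  invisible(x)
}

# The six fixed model specifications: one body-fat variable (BMI, waist
# girth, or %fat), each with and without the PA score, always alongside age
# and sex.
model_family_specs <- function() {
  tibble::tribble(
    ~label,    ~body_fat,  ~with_pa,
    "bmi",     "bmi",      FALSE,
    "bmi+pa",  "bmi",      TRUE,
    "wg",      "wg_cm",    FALSE,
    "wg+pa",   "wg_cm",    TRUE,
    "fat",     "pct_fat",  FALSE,
    "fat+pa",  "pct_fat",  TRUE
  )
}

#' Fit the six-model VO2max prediction grid
#'
#' Fits the full family of prediction equations -- age + sex + one of
#' {BMI, waist girth, %fat}, with and without the PA score -- and tabulates
#' coefficients, adjusted R^2, SEE, %SEE and the PRESS cross-validation
#' statistics for each, plus the adjusted-R^2 gain from adding the PA score
#' to each body-fat variant.
#'
#' @param cohort a cohort tibble with measured `vo2max` and all predictors.
#' @return A tibble with one row per model and columns `model`, `intercept`,
#'   `age`, `sex`, `bmi`, `wg_cm`, `pct_fat`, `pa_score`, `r2`, `adj_r2`,
#'   `see`, `pct_see`, `press`, `r2p`, `seep` (`NA` where a predictor is not
#'   in the model). The attribute `"pa_gain"` holds the with-PA minus
#'   without-PA adjusted-R^2 delta per body-fat variable.
#' @export
fit_model_family <- function(cohort) {
  specs <- model_family_specs()
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    preds <- c("age", "sex", specs$body_fat[i],
               if (specs$with_pa[i]) "pa_score")
    f <- fit_ols(cohort, preds, label = specs$label[i])
    pr <- press(f)
    cf <- f$coefficients
    get_cf <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else NA_real_
    tibble::tibble(
      model = specs$label[i],
      intercept = unname(cf["(Intercept)"]),
      age = get_cf("age"), sex = get_cf("sex"),
      bmi = get_cf("bmi"), wg_cm = get_cf("wg_cm"),
      pct_fat = get_cf("pct_fat"), pa_score = get_cf("pa_score"),
      r2 = f$r2, adj_r2 = f$adj_r2, see = f$see, pct_see = f$pct_see,
      press = pr$press_statistic, r2p = pr$r2p, seep = pr$seep
    )
  })
  grid <- dplyr::bind_rows(rows)
  gain <- tibble::tibble(
    body_fat = unique(specs$body_fat),
    adj_r2_gain = vapply(unique(specs$body_fat), function(v) {
      lab <- specs$label[specs$body_fat == v]
      grid$adj_r2[grid$model == lab[2]] - grid$adj_r2[grid$model == lab[1]]
    }, numeric(1))
  )
  attr(grid, "pa_gain") <- gain
  grid
}

#' Export measured-vs-predicted scatter data for the model grid
#'
#' One row per participant per model: the measured VO2max and the model's
#' in-sample prediction, for external plotting of agreement.
#'
#' @param cohort a cohort tibble with measured `vo2max` and predictors.
#' @param models model labels to include; default the full six-model family.
#' @return A tibble with columns `id`, `model`, `measured`, `predicted`.
#' @export
export_scatter <- function(cohort, models = model_family_specs()$label) {
  specs <- model_family_specs()
  specs <- specs[specs$label %in% models, , drop = FALSE]
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    preds <- c("age", "sex", specs$body_fat[i],
               if (specs$with_pa[i]) "pa_score")
    f <- fit_ols(cohort, preds, label = specs$label[i])
    tibble::tibble(id = cohort$id, model = specs$label[i],
                   measured = cohort$vo2max, predicted = unname(f$fitted))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
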