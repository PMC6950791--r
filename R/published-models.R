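#' Published VO2max prediction equations
#'
#' The six non-exercise prediction equations as published: one body-fat
#' variable (BMI, waist girth WG, or %fat), each with and without the m-WLAQ
#' PA score, always alongside age (years) and sex (0 = women, 1 = men). The
#' recommended everyday model is `"bmi+pa"`:
#' VO2max = 59.96 - 0.23 x age + 7.39 x sex - 0.79 x BMI + 0.33 x PA score.
#' Reported fit statistics (adjusted R^2, SEE, %SEE) and PRESS
#' cross-validation statistics (R2p, SEEp) accompany each row.
#'
#' @return A tibble with one row per model: `model`, `intercept`, `age`,
#'   `sex`, `bmi`, `wg_cm`, `pct_fat`, `pa_score` (`NA` where the predictor
#'   is not in the model), `adj_r2`, `see`, `pct_see`, `r2p`, `seep`.
#' @examples
#' published_models()
#' @export
published_models <- function() {
  tibble::tribble(
    ~model,   ~intercept,  ~age,  ~sex, ~bmi, ~wg_cm, ~pct_fat, ~pa_score, ~adj_r2, ~see, ~pct_see, ~r2p, ~seep,
    "bmi",    63.90, -0.25, 8.02, -0.79, NA,    NA,    NA,   0.43, 5.04, 13.1, 0.42, 5.08,
    "bmi+pa", 59.96, -0.23, 7.39, -0.79, NA,    NA,    0.33, 0.59, 4.29, 11.2, 0.58, 4.33,
    "wg",     70.39, -0.22, 8.82, NA,    -0.33, NA,    NA,   0.49, 4.78, 12.5, 0.48, 4.82,
    "wg+pa",  64.70, -0.21, 8.02, NA,    -0.29, NA,    0.29, 0.61, 4.17, 10.9, 0.60, 4.22,
    "fat",    62.45, -0.25, 2.95, NA,    NA,    -0.54, NA,   0.51, 4.69, 12.2, 0.49, 4.74,
    "fat+pa", 57.50, -0.24, 2.83, NA,    NA,    -0.48, 0.28, 0.62, 4.13, 10.8, 0.61, 4.18
  )
}

published_model_labels <- function() published_models()$model

# One published model row by label, or pass a one-row model tibble through.
published_model <- function(model) {
  if (is.character(model)) {
    tab <- published_models()
    i <- match(model, tab$model)
    if (is.na(i)) {
      stop("unknown model '", model, "'; choose one of: ",
           paste(tab$model, collapse = ", "), call. = FALSE)
    }
    return(tab[i, ])
  }
  stopifnot(is.data.frame(model), nrow(model) == 1)
  model
}

body_fat_var <- function(m) {
  vars <- c("bmi", "wg_cm", "pct_fat")
  vars[!is.na(unlist(m[vars]))]
}

#' Predict VO2max from a published equation
#'
#' Evaluates one of the shipped prediction equations for given inputs. Inputs
#' outside the population the equations were built on (age outside 30-60
#' years, PA score outside 0-44) trigger a warning but not an error -- the
#' models are linear and callers may extrapolate knowingly. Predictions below
#' 10 ml/kg/min warn as physiologically implausible; output is never
#' truncated or rounded.
#'
#' @param model model label (see [published_models()]) or a one-row model
#'   tibble in the same layout (e.g. a refitted grid row).
#' @param age age in years.
#' @param sex 0 = women, 1 = men (also accepts `"F"`/`"M"`).
#' @param body_fat value of the model's body-fat variable: BMI for the BMI
#'   models, waist girth in cm for the WG models, %fat for the fat models.
#' @param pa_score m-WLAQ PA score, 0-44 points; required by the `+pa`
#'   models and rejected by the others.
#' @return Predicted VO2max in ml/kg/min (vectorised over the inputs).
#' @examples
#' predict_vo2max("bmi+pa", age = 47.1, sex = 1, body_fat = 23.4,
#'                pa_score = 10.7) # 41.56
#' @export
predict_vo2max <- function(model, age, sex, body_fat, pa_score = NULL) {
  m <- published_model(model)
  if (is.character(sex)) sex <- parse_sex(sex)
  if (any(is.na(sex)) || any(!sex %in% c(0, 1))) {
    stop("sex must be 0 (women) or 1 (men), or F/M", call. = FALSE)
  }
  if (any(is.na(body_fat)) || any(body_fat <= 0)) {
    stop("body-fat value (", body_fat_var(m), ") must be positive",
         call. = FALSE)
  }
  has_pa <- !is.na(m$pa_score)
  if (has_pa && is.null(pa_score)) {
    stop("model '", m$model, "' requires a PA score", call. = FALSE)
  }
  if (!has_pa && !is.null(pa_score)) {
    stop("model '", m$model, "' does not use a PA score", call. = FALSE)
  }
  if (any(age < 30 | age > 60)) {
    warning("age outside the 30-60 year development range", call. = FALSE)
  }
  if (has_pa && any(pa_score < 0 | pa_score > 44)) {
    warning("PA score outside the 0-44 point range", call. = FALSE)
  }
  bf <- body_fat_var(m)
  pred <- m$intercept + m$age * age + m$sex * sex + m[[bf]] * body_fat
  if (has_pa) pred <- pred + m$pa_score * pa_score
  pred <- as.numeric(pred)
  if (any(pred < 10)) {
    warning("prediction below 10 ml/kg/min; outside plausible range",
            call. = FALSE)
  }
  pred
}

#' Batch-predict VO2max for a cohort table
#'
#' Applies a published (or refitted) equation row-wise to a cohort tibble in
#' the standard layout; equivalent to calling [predict_vo2max()] per row.
#'
#' @param cohort cohort tibble with `age`, `sex`, the model's body-fat column
#'   and (for `+pa` models) `pa_score`.
#' @param model model label or one-row model tibble.
#' @return The cohort with a `vo2max_pred` column appended.
#' @export
predict_cohort <- function(cohort, model = "bmi+pa") {
  m <- published_model(model)
  bf <- body_fat_var(m)
  if (!bf %in% names(cohort)) {
    stop("cohort lacks the model's body-fat column: ", bf, call. = FALSE)
  }
  pa <- if (!is.na(m$pa_score)) {
    if (!"pa_score" %in% names(cohort)) {
      stop("cohort lacks pa_score required by model '", m$model, "'",
           call. = FALSE)
    }
    cohort$pa_score
  } else NULL
  cohort$vo2max_pred <- predict_vo2max(m, cohort$age, cohort$sex,
                                       cohort[[bf]], pa)
  cohort
}
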