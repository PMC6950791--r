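# Sex-stratified descriptive calibration of the study cohort
# (93 women, 105 men): mean and SD per variable. vo2max rows are reference
# values only -- generation of vo2max is structural, not marginal.
default_marginals <- function() {
  tibble::tribble(
    ~variable,                  ~sex, ~mean, ~sd,
    "age",                      "F",  46.7,  7.5,
    "age",                      "M",  47.1,  7.1,
    "height_cm",                "F", 158.8,  5.2,
    "height_cm",                "M", 171.2,  5.6,
    "bmi",                      "F",  21.5,  2.9,
    "bmi",                      "M",  23.4,  2.9,
    "wg_cm",                    "F",  75.8,  8.9,
    "wg_cm",                    "M",  82.9,  8.3,
    "pct_fat",                  "F",  29.0,  5.6,
    "pct_fat",                  "M",  22.5,  5.3,
    "vo2max",                   "F",  35.0,  5.5,
    "vo2max",                   "M",  41.4,  6.2,
    "sit_commute_min",          "F",  12,    18,
    "sit_commute_min",          "M",  16,    21,
    "sit_work_min",             "F", 382,   147,
    "sit_work_min",             "M", 435,   162,
    "sit_leisure_workday_min",  "F", 241,   103,
    "sit_leisure_workday_min",  "M", 183,    85,
    "sit_nonworkday_min",       "F", 513,   166,
    "sit_nonworkday_min",       "M", 566,   192
  )
}

# Published answer-option frequencies per sex. q9/q10 (and q14/q15) vectors
# are conditional on the gate question being above option 1.
default_option_probs <- function() {
  list(
    F = list(
      q6  = c(81, 7, 5, 0) / 93,
      q8  = c(45, 6, 27, 15) / 93,
      q9  = c(1, 12, 25, 10) / 48,
      q10 = c(15, 29, 4, 0) / 48,
      q13 = c(39, 17, 24, 13) / 93,
      q14 = c(2, 4, 27, 21) / 54,
      q15 = c(10, 38, 6, 0) / 54
    ),
    M = list(
      q6  = c(76, 19, 9, 1) / 105,
      q8  = c(54, 18, 18, 15) / 105,
      q9  = c(2, 6, 22, 21) / 51,
      q10 = c(4, 32, 14, 1) / 51,
      q13 = c(36, 23, 32, 14) / 105,
      q14 = c(2, 8, 27, 32) / 69,
      q15 = c(10, 41, 17, 1) / 69
    )
  )
}

# Physiologic truncation bounds for the marginal draws.
trunc_bounds <- list(
  age = c(30, 60), height_cm = c(130, 210), bmi = c(15, 45),
  wg_cm = c(50, 130), pct_fat = c(5, 55),
  sit_commute_min = c(0, 1440), sit_work_min = c(0, 1440),
  sit_leisure_workday_min = c(0, 1440), sit_nonworkday_min = c(0, 1440)
)

#' Specification for a synthetic worker cohort
#'
#' Bundles everything the generator needs: sample size, sex mix,
#' sex-stratified marginal means/SDs for demographics, anthropometrics and
#' the four sitting-time domains, per-sex answer-option probabilities for the
#' seven PA questions, and the structural VO2max model (one of the six
#' published equation models) plus a Gaussian residual SD. Defaults are the
#' study's own descriptive statistics, so a default cohort emulates the
#' published sample of 93 women and 105 men.
#'
#' @param n number of participants (>= 1).
#' @param sex_fraction_male probability a participant is male; default 105/198.
#' @param marginals tibble with columns `variable`, `sex` (`"F"`/`"M"`),
#'   `mean`, `sd`.
#' @param option_probs per-sex list of length-4 probability vectors for
#'   `q6, q8, q9, q10, q13, q14, q15` (`q9`, `q10`, `q14`, `q15` conditional
#'   on their gate question exceeding option 1).
#' @param model structural model label, one of
#'   `"bmi", "bmi+pa", "wg", "wg+pa", "fat", "fat+pa"`; measured VO2max is
#'   this equation evaluated on the drawn predictors plus noise.
#' @param residual_sd SD of the Gaussian residual added to the structural
#'   equation, ml/kg/min; default 4.29, the published SEE of the BMI+PA model.
#' @param seed optional integer seed; fixed seed gives a bit-identical cohort.
#' @return A validated list of class `wlaq_cohort_spec`.
#' @export
cohort_spec <- function(n,
                        sex_fraction_male = 105 / 198,
                        marginals = default_marginals(),
                        option_probs = default_option_probs(),
                        model = "bmi+pa",
                        residual_sd = 4.29,
                        seed = NULL) {
  spec <- structure(
    list(n = n, sex_fraction_male = sex_fraction_male,
         marginals = marginals, option_probs = option_probs,
         model = model, residual_sd = residual_sd, seed = seed),
    class = "wlaq_cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "wlaq_cohort_spec"))
  if (!is.numeric(spec$n) || length(spec$n) != 1 || spec$n < 1 ||
      spec$n != round(spec$n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (spec$sex_fraction_male < 0 || spec$sex_fraction_male > 1) {
    stop("sex_fraction_male must be in [0, 1]", call. = FALSE)
  }
  m <- spec$marginals
  if (!all(c("variable", "sex", "mean", "sd") %in% names(m))) {
    stop("marginals must have columns variable, sex, mean, sd", call. = FALSE)
  }
  if (any(m$sd < 0)) stop("marginal SDs must be non-negative", call. = FALSE)
  need <- setdiff(unique(default_marginals()$variable), "vo2max")
  for (sx in c("F", "M")) {
    have <- m$variable[m$sex == sx]
    if (!all(need %in% have)) {
      stop("marginals for sex ", sx, " missing: ",
           paste(setdiff(need, have), collapse = ", "), call. = FALSE)
    }
    probs <- spec$option_probs[[sx]]
    if (!all(wlaq_questions %in% names(probs))) {
      stop("option_probs for sex ", sx, " must cover all seven questions",
           call. = FALSE)
    }
    for (q in wlaq_questions) {
      p <- probs[[q]]
      if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop("option probabilities for ", q, " (sex ", sx,
             ") must be 4 non-negative values summing to 1", call. = FALSE)
      }
    }
  }
  if (!spec$model %in% published_model_labels()) {
    stop("model must be one of: ",
         paste(published_model_labels(), collapse = ", "), call. = FALSE)
  }
  if (spec$residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (!is.null(spec$seed)) {
    stopifnot(is.numeric(spec$seed), length(spec$seed) == 1)
  }
  spec
}

#' Specification for a test-retest replicate
#'
#' Controls how a second questionnaire administration (one week later in the
#' emulated design) differs from the first: each categorical answer is kept
#' with probability `stay_probability`, otherwise it drifts to an adjacent
#' option (reflecting at the scale ends, preserving ordinal structure);
#' sitting minutes get zero-mean Gaussian within-subject noise.
#'
#' @param stay_probability chance a categorical answer is unchanged; in \[0,1\].
#' @param sitting_within_sd within-subject SD of re-reported sitting minutes
#'   (min/day); length 1, or length 4 in domain order commute / work /
#'   leisure-workday / non-workday. The default `c(14, 39, 49, 129)` is
#'   calibrated so the implied population ICCs of the four domains match the
#'   published test-retest reliabilities.
#' @param between_share between-subject share of total variance for
#'   constructed continuous score pairs (see [simulate_retest_pairs()]);
#'   in (0,1), default 0.87.
#' @param seed optional integer seed.
#' @return A validated list of class `wlaq_retest_spec`.
#' @export
retest_spec <- function(stay_probability = 0.8,
                        sitting_within_sd = c(14, 39, 49, 129),
                        between_share = 0.87,
                        seed = NULL) {
  if (stay_probability < 0 || stay_probability > 1) {
    stop("stay_probability must be in [0, 1]", call. = FALSE)
  }
  if (!length(sitting_within_sd) %in% c(1L, 4L) || any(sitting_within_sd < 0)) {
    stop("sitting_within_sd must be 1 or 4 non-negative values", call. = FALSE)
  }
  if (between_share <= 0 || between_share >= 1) {
    stop("between_share must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(stay_probability = stay_probability,
         sitting_within_sd = rep_len(sitting_within_sd, 4L),
         between_share = between_share, seed = seed),
    class = "wlaq_retest_spec"
  )
}

#' Read or write a cohort spec as YAML
#'
#' @param path YAML file path.
#' @return `read_cohort_spec()` returns a `wlaq_cohort_spec`;
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  marg <- do.call(rbind, lapply(raw$marginals, function(r) {
    tibble::tibble(variable = r$variable, sex = r$sex,
                   mean = r$mean, sd = r$sd)
  }))
  cohort_spec(
    n = raw$n,
    sex_fraction_male = raw$sex_fraction_male,
    marginals = tibble::as_tibble(marg),
    option_probs = lapply(raw$option_probs, function(sx) lapply(sx, unlist)),
    model = raw$model,
    residual_sd = raw$residual_sd,
    seed = raw$seed
  )
}

#' @rdname read_cohort_spec
#' @param spec a `wlaq_cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  spec <- validate_cohort_spec(spec)
  out <- list(
    n = spec$n,
    sex_fraction_male = spec$sex_fraction_male,
    marginals = lapply(seq_len(nrow(spec$marginals)), function(i) {
      as.list(spec$marginals[i, ])
    }),
    option_probs = lapply(spec$option_probs, function(sx) lapply(sx, as.numeric)),
    model = spec$model,
    residual_sd = spec$residual_sd,
    seed = spec$seed
  )
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
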