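# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by inverse CDF; exact under the uniform stream, so
# deterministic and unbiased within the truncation window.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  zero <- sd == 0
  out[zero] <- mean[zero]
  if (any(!zero)) {
    i <- !zero
    plo <- stats::pnorm(lower, mean[i], sd[i])
    phi <- stats::pnorm(upper, mean[i], sd[i])
    out[i] <- stats::qnorm(stats::runif(sum(i), plo, phi), mean[i], sd[i])
  }
  out
}

# Per-sex categorical draw: probability vectors indexed by sex code 0/1.
sample_option <- function(sex, probs_f, probs_m) {
  n <- length(sex)
  out <- integer(n)
  for (code in c(0L, 1L)) {
    idx <- which(sex == code)
    if (length(idx) == 0) next
    p <- if (code == 0L) probs_f else probs_m
    out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = p)
  }
  out
}

marginal_lookup <- function(marginals, variable, sex_code) {
  sx <- ifelse(sex_code == 1L, "M", "F")
  key <- paste(marginals$variable, marginals$sex)
  mean <- marginals$mean[match(paste(variable, sx), key)]
  sd <- marginals$sd[match(paste(variable, sx), key)]
  list(mean = mean, sd = sd)
}

#' Generate a synthetic worker cohort
#'
#' Draws participants with the statistical structure the downstream analysis
#' assumes: sex is Bernoulli; age, height, BMI, waist girth, %fat and the
#' four sitting-time domains are per-sex truncated normals at the calibrated
#' means/SDs; weight is derived as BMI x (height in m)^2 so the
#' anthropometrics are internally consistent; questionnaire answers are drawn
#' from the per-sex option frequencies honouring skip logic (Q9/Q10 drawn
#' only when Q8 > 1, Q14/Q15 only when Q13 > 1); the PA score is computed by
#' the scoring module; and measured VO2max is the chosen structural equation
#' plus Gaussian residual noise, truncated below at 10 ml/kg/min. If the
#' three workday sitting domains exceed 1440 min/day (rare at the default
#' SDs) they are rescaled proportionally onto the cap.
#'
#' @param spec a [cohort_spec()].
#' @param points points table used for the PA score.
#' @return A cohort tibble in the standard column layout, with `pa_score` and
#'   `total_sitting_min` derived; identical spec + seed gives an identical
#'   cohort.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 42))
#' mean(cohort$vo2max)
#' @export
generate_cohort <- function(spec, points = wlaq_points_default()) {
  spec <- validate_cohort_spec(spec)
  points <- validate_points(points)
  n <- as.integer(spec$n)
  with_seed(spec$seed, {
    sex <- as.integer(stats::runif(n) < spec$sex_fraction_male)

    draw <- function(variable) {
      par <- marginal_lookup(spec$marginals, variable, sex)
      b <- trunc_bounds[[variable]]
      rnorm_trunc(n, par$mean, par$sd, b[1], b[2])
    }
    age <- draw("age")
    height_cm <- draw("height_cm")
    bmi <- draw("bmi")
    wg_cm <- draw("wg_cm")
    pct_fat <- draw("pct_fat")
    weight_kg <- bmi * (height_cm / 100)^2
    sit <- lapply(sitting_domains, draw)
    names(sit) <- sitting_domains
    # enforce the workday cap by proportional rescaling
    workday <- sit$sit_commute_min + sit$sit_work_min +
      sit$sit_leisure_workday_min
    over <- workday > 1440
    if (any(over)) {
      f <- 1440 / workday[over]
      for (d in sitting_domains[1:3]) sit[[d]][over] <- sit[[d]][over] * f
    }

    pf <- spec$option_probs$F
    pm <- spec$option_probs$M
    q6 <- sample_option(sex, pf$q6, pm$q6)
    q8 <- sample_option(sex, pf$q8, pm$q8)
    q9 <- q10 <- rep(NA_integer_, n)
    active <- q8 > 1L
    if (any(active)) {
      q9[active] <- sample_option(sex[active], pf$q9, pm$q9)
      q10[active] <- sample_option(sex[active], pf$q10, pm$q10)
    }
    q13 <- sample_option(sex, pf$q13, pm$q13)
    q14 <- q15 <- rep(NA_integer_, n)
    active <- q13 > 1L
    if (any(active)) {
      q14[active] <- sample_option(sex[active], pf$q14, pm$q14)
      q15[active] <- sample_option(sex[active], pf$q15, pm$q15)
    }

    cohort <- tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, height_cm = height_cm, weight_kg = weight_kg,
      bmi = bmi, wg_cm = wg_cm, pct_fat = pct_fat,
      vo2max = NA_real_,
      q6 = q6, q8 = q8, q9 = q9, q10 = q10,
      q13 = q13, q14 = q14, q15 = q15,
      sit_commute_min = sit$sit_commute_min,
      sit_work_min = sit$sit_work_min,
      sit_leisure_workday_min = sit$sit_leisure_workday_min,
      sit_nonworkday_min = sit$sit_nonworkday_min
    )
    cohort$pa_score <- as.integer(rowSums(question_points(cohort, points)))
    cohort$total_sitting_min <- cohort$sit_commute_min + cohort$sit_work_min +
      cohort$sit_leisure_workday_min + cohort$sit_nonworkday_min

    mu <- structural_vo2max(cohort, spec$model)
    cohort$vo2max <- if (spec$residual_sd == 0) {
      mu
    } else {
      rnorm_trunc(n, mu, spec$residual_sd, lower = 10)
    }
    cohort
  })
}

# Evaluate a published equation model on cohort predictors (no noise).
structural_vo2max <- function(cohort, model) {
  m <- published_model(model)
  mu <- rep(m$intercept, nrow(cohort)) +
    m$age * cohort$age + m$sex * cohort$sex
  for (v in c("bmi", "wg_cm", "pct_fat")) {
    if (!is.na(m[[v]])) mu <- mu + m[[v]] * cohort[[v]]
  }
  if (!is.na(m$pa_score)) mu <- mu + m$pa_score * cohort$pa_score
  mu
}

# Ordinal drift: keep with prob `stay`, else step to an adjacent option,
# reflecting at the ends of the 1..4 scale.
drift_option <- function(opt, stay) {
  n <- length(opt)
  move <- stats::runif(n) >= stay
  dir <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  out <- opt
  step <- opt + dir
  step[step < 1L] <- 2L
  step[step > 4L] <- 3L
  out[move] <- step[move]
  out
}

#' Generate a second questionnaire administration for a cohort
#'
#' Emulates a one-week test-retest design: every categorical answer is kept
#' with probability `stay_probability` or moved to an adjacent option;
#' sitting minutes are re-reported with zero-mean Gaussian within-subject
#' noise, clipped to \[0, 1440\] (and the workday cap re-enforced by
#' rescaling). Skip logic stays consistent: if Q8 drifts onto option 1 at
#' visit 2, Q9/Q10 become absent; if it drifts off option 1, the newly
#' required answers are drawn from the visit-1 empirical distribution among
#' respondents who answered them (uniform fallback when none did). Q13/Q14/
#' Q15 behave symmetrically.
#'
#' @param cohort a visit-1 cohort tibble (from [generate_cohort()] or
#'   [validate_cohort()]).
#' @param spec a [retest_spec()].
#' @param points points table used to re-derive the visit-2 PA score.
#' @return A tibble of visit-2 responses (same ids and layout as the
#'   questionnaire columns of `cohort`, plus `pa_score` and
#'   `total_sitting_min`).
#' @export
generate_retest <- function(cohort, spec = retest_spec(),
                            points = wlaq_points_default()) {
  stopifnot(inherits(spec, "wlaq_retest_spec"))
  if (nrow(cohort) == 0) stop("cohort must be non-empty", call. = FALSE)
  points <- validate_points(points)
  n <- nrow(cohort)
  with_seed(spec$seed, {
    stay <- spec$stay_probability

    redraw_conditional <- function(visit1_vals, idx_new) {
      pool <- visit1_vals[!is.na(visit1_vals)]
      if (length(pool) == 0) pool <- 1:4
      pool[sample.int(length(pool), length(idx_new), replace = TRUE)]
    }
    drift_family <- function(gate1, a1, b1) {
      gate2 <- drift_option(gate1, stay)
      a2 <- b2 <- rep(NA_integer_, n)
      keep <- gate2 > 1L & gate1 > 1L     # answered both visits: drift
      new <- gate2 > 1L & gate1 == 1L     # newly required: draw empirically
      a2[keep] <- drift_option(a1[keep], stay)
      b2[keep] <- drift_option(b1[keep], stay)
      if (any(new)) {
        a2[new] <- redraw_conditional(a1, which(new))
        b2[new] <- redraw_conditional(b1, which(new))
      }
      list(gate = gate2, a = a2, b = b2)
    }

    q6_2 <- drift_option(cohort$q6, stay)
    fam8 <- drift_family(cohort$q8, cohort$q9, cohort$q10)
    fam13 <- drift_family(cohort$q13, cohort$q14, cohort$q15)

    sit2 <- lapply(seq_along(sitting_domains), function(k) {
      d <- sitting_domains[k]
      x <- cohort[[d]] + stats::rnorm(n, 0, spec$sitting_within_sd[k])
      pmin(pmax(x, 0), 1440)
    })
    names(sit2) <- sitting_domains
    workday <- sit2$sit_commute_min + sit2$sit_work_min +
      sit2$sit_leisure_workday_min
    over <- workday > 1440
    if (any(over)) {
      f <- 1440 / workday[over]
      for (d in sitting_domains[1:3]) sit2[[d]][over] <- sit2[[d]][over] * f
    }

    visit2 <- tibble::tibble(
      id = cohort$id,
      q6 = q6_2, q8 = fam8$gate, q9 = fam8$a, q10 = fam8$b,
      q13 = fam13$gate, q14 = fam13$a, q15 = fam13$b,
      sit_commute_min = sit2$sit_commute_min,
      sit_work_min = sit2$sit_work_min,
      sit_leisure_workday_min = sit2$sit_leisure_workday_min,
      sit_nonworkday_min = sit2$sit_nonworkday_min
    )
    visit2$pa_score <- as.integer(rowSums(question_points(visit2, points)))
    visit2$total_sitting_min <- visit2$sit_commute_min + visit2$sit_work_min +
      visit2$sit_leisure_workday_min + visit2$sit_nonworkday_min
    visit2
  })
}

#' Simulate paired measurements with a known intraclass correlation
#'
#' Constructs `n` subjects with a latent subject effect of variance
#' `between_share` and two visit measurements carrying independent residuals
#' of variance `1 - between_share` (total variance 1), so the population ICC
#' of the pair equals `between_share` exactly by construction. Used to check
#' that the ICC estimator recovers a known reliability.
#'
#' @param n number of subjects.
#' @param between_share between-subject share of total variance, in (0, 1).
#' @param mean grand mean added to both visits.
#' @param seed optional integer seed.
#' @return A tibble with columns `id`, `visit1`, `visit2`.
#' @examples
#' pairs <- simulate_retest_pairs(500, between_share = 0.87, seed = 1)
#' icc(pairs$visit1, pairs$visit2)$icc
#' @export
simulate_retest_pairs <- function(n, between_share = 0.87, mean = 0,
                                  seed = NULL) {
  if (between_share <= 0 || between_share >= 1) {
    stop("between_share must be in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    subject <- stats::rnorm(n, 0, sqrt(between_share))
    wsd <- sqrt(1 - between_share)
    tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      visit1 = mean + subject + stats::rnorm(n, 0, wsd),
      visit2 = mean + subject + stats::rnorm(n, 0, wsd)
    )
  })
}
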