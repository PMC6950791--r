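#' Score the m-WLAQ physical-activity composite for one respondent
#'
#' Looks up the point value of each selected answer option and sums them into
#' the 0-44-point PA score. Skip logic: Q9 and Q10 are only asked when Q8
#' (workday exercise frequency) is above option 1 ("none/almost none"); when
#' Q8 = 1 they contribute 0 points regardless of any stored value. Q14/Q15
#' behave the same way with respect to Q13 (non-workday frequency). A skipped
#' item may be recorded as `NA` (ABSENT); `NA` is distinct from an option that
#' happens to carry 0 points, so audit output can tell "skipped" from "none".
#'
#' @param response a list or one-row data frame with elements `q6`, `q8`,
#'   `q9`, `q10`, `q13`, `q14`, `q15` holding answer-option indices 1-4
#'   (`q9`, `q10`, `q14`, `q15` may be `NA` when skipped).
#' @param points a `wlaq_points` table; defaults to the published weights.
#' @return A list of class `wlaq_pa_score` with `value` (integer total) and
#'   `per_question_points` (named integer vector of the seven contributions).
#' @examples
#' score_pa(list(q6 = 4, q8 = 4, q9 = 4, q10 = 4, q13 = 4, q14 = 4, q15 = 4))
#' @export
score_pa <- function(response, points = wlaq_points_default()) {
  points <- validate_points(points)
  df <- tibble::as_tibble(response[wlaq_questions])
  stopifnot(nrow(df) == 1L)
  check_response_options(df)
  pts <- question_points(df, points)
  out <- list(
    value = as.integer(rowSums(pts)),
    per_question_points = as.integer(pts[1L, ])
  )
  names(out$per_question_points) <- wlaq_questions
  structure(out, class = "wlaq_pa_score")
}

#' @export
print.wlaq_pa_score <- function(x, ...) {
  cat("m-WLAQ PA score:", x$value, "/ 44\n")
  print(x$per_question_points)
  invisible(x)
}

# Vectorised per-question point lookup with skip logic applied.
# `df` must already have passed check_response_options().
question_points <- function(df, points) {
  n <- nrow(df)
  pts <- matrix(0L, nrow = n, ncol = length(wlaq_questions),
                dimnames = list(NULL, wlaq_questions))
  skipped <- list(
    q9 = df$q8 == 1L, q10 = df$q8 == 1L,
    q14 = df$q13 == 1L, q15 = df$q13 == 1L
  )
  for (q in wlaq_questions) {
    opt <- as.integer(df[[q]])
    val <- ifelse(is.na(opt), 0L, points[[q]][ifelse(is.na(opt), 1L, opt)])
    if (q %in% names(skipped)) val[skipped[[q]]] <- 0L
    pts[, q] <- val
  }
  pts
}

# Option-range and skip-logic presence checks, vectorised; stops on the first
# offending field so errors name it.
check_response_options <- function(df) {
  for (q in c("q6", "q8", "q13")) {
    opt <- df[[q]]
    if (any(is.na(opt))) stop(q, " is required", call. = FALSE)
    if (any(opt < 1 | opt > 4 | opt != round(opt))) {
      stop(q, " option index must be in 1..4", call. = FALSE)
    }
  }
  for (q in c("q9", "q10", "q14", "q15")) {
    opt <- df[[q]]
    gate <- if (q %in% c("q9", "q10")) df$q8 else df$q13
    gate_name <- if (q %in% c("q9", "q10")) "q8" else "q13"
    if (any(is.na(opt) & gate > 1L)) {
      stop(q, " required when ", gate_name, ">1", call. = FALSE)
    }
    ok <- is.na(opt) | (opt >= 1 & opt <= 4 & opt == round(opt))
    if (!all(ok)) stop(q, " option index must be in 1..4", call. = FALSE)
  }
  invisible(df)
}

sitting_domains <- c("sit_commute_min", "sit_work_min",
                     "sit_leisure_workday_min", "sit_nonworkday_min")

#' Total daily sitting time across the four m-WLAQ domains
#'
#' Sums sitting minutes reported for commuting, working time, leisure time on
#' a workday, and a non-workday into the total min/day figure.
#'
#' @param response a list or one-row data frame with `sit_commute_min`,
#'   `sit_work_min`, `sit_leisure_workday_min`, `sit_nonworkday_min`.
#' @return Total sitting time, minutes per day.
#' @examples
#' total_sitting_time(list(sit_commute_min = 12, sit_work_min = 382,
#'                         sit_leisure_workday_min = 241,
#'                         sit_nonworkday_min = 513)) # 1148
#' @export
total_sitting_time <- function(response) {
  v <- vapply(sitting_domains, function(d) as.numeric(response[[d]]), numeric(1))
  if (any(is.na(v))) stop("all four sitting-time domains are required", call. = FALSE)
  if (any(v < 0)) stop("sitting minutes must be non-negative", call. = FALSE)
  sum(v)
}
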