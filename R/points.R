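#' Default m-WLAQ points table
#'
#' The m-WLAQ physical-activity (PA) score is the sum of the points assigned
#' to the selected answer options of seven questions: Q6 (PA intensity during
#' working time), Q8/Q9/Q10 (exercise frequency, duration and intensity in
#' leisure time on a workday) and Q13/Q14/Q15 (the same three for a
#' non-workday). Intensity items (Q6, Q10, Q15) are weighted most heavily,
#' reaching 10 points each, so the total ranges from 0 to 44.
#'
#' @return An object of class `wlaq_points`: a named list with one integer
#'   vector of four point values per question, indexed by answer option 1-4.
#' @examples
#' pts <- wlaq_points_default()
#' sum(vapply(pts, max, numeric(1))) # 44
#' @export
wlaq_points_default <- function() {
  validate_points(list(
    q6  = c(0L, 3L, 5L, 10L),
    q8  = c(0L, 1L, 2L, 3L),
    q9  = c(1L, 2L, 3L, 4L),
    q10 = c(0L, 3L, 5L, 10L),
    q13 = c(0L, 1L, 2L, 3L),
    q14 = c(1L, 2L, 3L, 4L),
    q15 = c(0L, 3L, 5L, 10L)
  ))
}

wlaq_questions <- c("q6", "q8", "q9", "q10", "q13", "q14", "q15")

#' Validate a points table
#'
#' Checks that every question has exactly four non-negative, non-decreasing
#' integer point values and that the per-question maxima sum to the scale
#' ceiling of 44.
#'
#' @param points a named list of numeric vectors as in [wlaq_points_default()].
#' @return The validated table, classed `wlaq_points`, invisibly usable
#'   downstream.
#' @export
validate_points <- function(points) {
  if (!is.list(points) || !setequal(names(points), wlaq_questions)) {
    stop("points table must be a named list with entries: ",
         paste(wlaq_questions, collapse = ", "), call. = FALSE)
  }
  points <- points[wlaq_questions]
  for (q in wlaq_questions) {
    v <- points[[q]]
    if (length(v) != 4L) {
      stop("question ", q, " must have exactly 4 option point values",
           call. = FALSE)
    }
    if (any(v < 0) || any(v != round(v))) {
      stop("question ", q, " point values must be non-negative integers",
           call. = FALSE)
    }
    if (is.unsorted(v)) {
      stop("question ", q, " point values must be non-decreasing", call. = FALSE)
    }
    points[[q]] <- as.integer(v)
  }
  total_max <- sum(vapply(points, max, integer(1)))
  if (total_max != 44L) {
    stop("per-question maxima must sum to 44, got ", total_max, call. = FALSE)
  }
  structure(points, class = "wlaq_points")
}

#' Read a points table from a YAML config file
#'
#' The shipped default (`system.file("extdata", "points_default.yaml",
#' package = "wlaqfit")`) equals the published point weights; an alternative
#' file lets users explore other weightings without code change.
#'
#' @param path path to a YAML file mapping each question to 4 point values.
#' @return A validated `wlaq_points` table.
#' @export
read_points_config <- function(path) {
  if (!file.exists(path)) {
    stop("points config not found: ", path, call. = FALSE)
  }
  validate_points(yaml::read_yaml(path))
}

#' Write a points table to a YAML config file
#'
#' @param points a `wlaq_points` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points_config <- function(points, path) {
  points <- validate_points(points)
  yaml::write_yaml(lapply(points, as.integer), path)
  invisible(path)
}
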