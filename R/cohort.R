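cohort_columns <- c(
  "id", "age", "sex", "height_cm", "weight_kg", "bmi", "wg_cm", "pct_fat",
  "vo2max", "q6", "q8", "q9", "q10", "q13", "q14", "q15",
  "sit_commute_min", "sit_work_min", "sit_leisure_workday_min",
  "sit_nonworkday_min"
)

#' Read a cohort file
#'
#' Reads a delimited participant table (comma by default) with the fixed
#' header: `id, age, sex, height_cm, weight_kg, bmi, wg_cm, pct_fat, vo2max,
#' q6, q8, q9, q10, q13, q14, q15, sit_commute_min, sit_work_min,
#' sit_leisure_workday_min, sit_nonworkday_min`. Blank cells are `NA`
#' (for the skip-gated questions `NA` means "skipped"; for `vo2max` it means
#' "not measured"). Sex may be coded `F`/`M` or `0`/`1`.
#'
#' @param path path to the delimited file.
#' @param delim field delimiter, default `","`.
#' @return A tibble of raw rows (unvalidated; see [validate_cohort()]).
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(
                            id = readr::col_character(),
                            sex = readr::col_character(),
                            .default = readr::col_double()
                          ))
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing) > 0) {
    stop("cohort file lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a cohort table
#'
#' @param cohort a cohort tibble (validated or raw).
#' @param path output path.
#' @param delim field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  keep <- intersect(c(cohort_columns, "pa_score", "total_sitting_min"),
                    names(cohort))
  readr::write_delim(cohort[keep], path, delim = delim, na = "")
  invisible(path)
}

# Normalise the sex column to 0 = women, 1 = men. Unrecognised codes -> NA.
parse_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- rep(NA_integer_, length(s))
  out[s %in% c("F", "W", "0", "FEMALE", "WOMAN")] <- 0L
  out[s %in% c("M", "1", "MALE", "MAN")] <- 1L
  out
}

#' Validate raw cohort rows and derive questionnaire scores
#'
#' Applies the m-WLAQ validity rules row by row and splits the input into
#' accepted participants (with derived `pa_score` and `total_sitting_min`)
#' and rejected rows with machine-readable reasons. Rules: answer options in
#' 1-4 with the skip-logic presence requirement (`q9`/`q10` required when
#' `q8 > 1`, `q14`/`q15` when `q13 > 1`); each sitting domain within
#' \[0, 1440\] min/day and the three workday domains summing to at most 1440;
#' sex parseable; age, height, weight, girth and %fat positive when present.
#' BMI is recomputed as weight/(height in m)^2 when height and weight are
#' present, filled in when blank, and cross-checked against a supplied value
#' (tolerance 0.1 BMI units).
#'
#' @param records a raw cohort tibble as returned by [read_cohort()].
#' @param points a `wlaq_points` table used to derive the PA score.
#' @return A list with `participants` (accepted rows plus `pa_score`,
#'   `total_sitting_min`) and `rejections` (tibble of `id`, `row`, `reason`).
#'   Duplicated participant ids are an error, not a rejection.
#' @examples
#' spec <- cohort_spec(n = 10, seed = 1)
#' res <- validate_cohort(generate_cohort(spec))
#' nrow(res$participants) # 10
#' @export
validate_cohort <- function(records, points = wlaq_points_default()) {
  points <- validate_points(points)
  empty_rej <- tibble::tibble(id = character(), row = integer(),
                              reason = character())
  if (nrow(records) == 0) {
    return(list(participants = records, rejections = empty_rej))
  }
  if (anyDuplicated(records$id)) {
    stop("duplicated participant id: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }

  df <- records
  df$sex <- parse_sex(df$sex)

  reasons <- vector("list", nrow(df))
  add <- function(i, msg) reasons[[i]] <<- c(reasons[[i]], msg)

  for (i in seq_len(nrow(df))) {
    if (is.na(df$sex[i])) add(i, "sex must be F/M or 0/1")
    for (v in c("age", "height_cm", "weight_kg", "wg_cm", "pct_fat")) {
      if (!is.na(df[[v]][i]) && df[[v]][i] <= 0) add(i, paste(v, "must be positive"))
    }
    # questionnaire options + skip logic
    row_q <- df[i, wlaq_questions]
    err <- tryCatch({ check_response_options(row_q); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) add(i, err)
    # sitting-time bounds
    for (d in sitting_domains) {
      x <- df[[d]][i]
      if (is.na(x)) add(i, paste(d, "is required"))
      else if (x < 0 || x > 1440) add(i, paste(d, "outside [0, 1440] min/day"))
    }
    workday <- sum(df$sit_commute_min[i], df$sit_work_min[i],
                   df$sit_leisure_workday_min[i])
    if (!is.na(workday) && workday > 1440) {
      add(i, "workday sitting domains exceed 1440 min/day")
    }
    # BMI consistency
    h <- df$height_cm[i]; w <- df$weight_kg[i]
    if (!is.na(h) && !is.na(w) && h > 0) {
      bmi_calc <- w / (h / 100)^2
      if (is.na(df$bmi[i])) {
        df$bmi[i] <- bmi_calc
      } else if (abs(df$bmi[i] - bmi_calc) > 0.1) {
        add(i, "bmi inconsistent with height/weight (tolerance 0.1)")
      }
    }
  }

  bad <- which(!vapply(reasons, is.null, logical(1)))
  rejections <- if (length(bad) > 0) {
    tibble::tibble(
      id = rep(as.character(records$id[bad]),
               lengths(reasons[bad])),
      row = rep(bad, lengths(reasons[bad])),
      reason = unlist(reasons[bad])
    )
  } else empty_rej

  keep <- setdiff(seq_len(nrow(df)), bad)
  participants <- df[keep, , drop = FALSE]
  if (nrow(participants) > 0) {
    pts <- question_points(participants, points)
    participants$pa_score <- as.integer(rowSums(pts))
    participants$total_sitting_min <- participants$sit_commute_min +
      participants$sit_work_min + participants$sit_leisure_workday_min +
      participants$sit_nonworkday_min
  } else {
    participants$pa_score <- integer(0)
    participants$total_sitting_min <- numeric(0)
  }
  message(sprintf("validate_cohort: %d accepted, %d rejected",
                  nrow(participants), length(bad)))
  list(participants = participants, rejections = rejections)
}
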