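#' Round half away from zero
#'
#' Percentage frequencies are displayed rounded half-up (58.82 -> 59),
#' matching the convention of the published frequency table, rather than
#' R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stable tri-state status vocabulary
status_levels <- function() c("present", "absent", "undocumented")
laterality_levels <- function() c("asymmetric", "symmetric", "unknown")

assert_cohort <- function(cohort, call = rlang::caller_env()) {
  if (!is.data.frame(cohort)) {
    rlang::abort("`cohort` must be a data frame.", call = call)
  }
  missing_cols <- setdiff(c("patient_id", patient_columns(), feature_columns()),
                          names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("`cohort` is missing required columns: ",
             paste(utils::head(missing_cols, 5), collapse = ", "),
             if (length(missing_cols) > 5) ", ..."),
      call = call
    )
  }
  if (anyDuplicated(cohort$patient_id)) {
    rlang::abort("`patient_id` values must be unique.", call = call)
  }
  invisible(cohort)
}

match_timepoint <- function(timepoint) {
  rlang::arg_match0(timepoint, timepoints())
}
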