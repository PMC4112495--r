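#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

# patient-level (non-feature) columns and their prototypes
patient_column_prototypes <- function() {
  c(
    list(
      sex = NA_character_,
      age_at_presentation = NA_real_,
      symptom_duration_years = NA_real_,
      insidious_onset = NA,
      family_history = NA,
      tau_mutation = NA,
      pathology = NA_character_,
      mmse = NA_real_,
      acer = NA_real_
    ),
    stats::setNames(rep(list(FALSE), length(exclusion_flags())),
                    exclusion_columns())
  )
}

patient_columns <- function() names(patient_column_prototypes())

# feature observation columns: <feature>_pres / <feature>_ever
feature_columns <- function() {
  codes <- feature_codes()
  c(paste0(codes, "_pres"), paste0(codes, "_ever"))
}

cohort_column_order <- function() {
  c("patient_id", patient_columns(), feature_columns())
}

#' Construct a single patient record
#'
#' Builds a one-row cohort tibble in the package's flat dialect: one row per
#' patient, with each clinical feature encoded in a pair of columns
#' `<feature>_pres` / `<feature>_ever` holding `""` (undocumented),
#' `"absent"`, `"present"`, or `"present,asymmetric"` /
#' `"present,symmetric"` for the motor features that carry a laterality
#' qualifier.
#'
#' @param patient_id Unique patient identifier.
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age Age at presentation in years.
#' @param duration Symptom duration at assessment in years.
#' @param insidious_onset Logical; insidious onset with gradual progression.
#' @param family_history Logical; two or more affected relatives.
#' @param tau_mutation Logical; known tau (MAPT) mutation.
#' @param pathology Optional neuropathological label, one of `"CBD"`,
#'   `"AD"`, `"FTLD_TDP"`, `"LBD_AD_mixed"`, `"other"`. Never consulted by
#'   the classifiers (pathologists were blinded to clinical features and the
#'   engine is blinded to pathology).
#' @param mmse,acer Optional cognitive screening scores (out of 30 / 100),
#'   carried as opaque metadata.
#' @param exclusions Character vector of triggered exclusion-criterion
#'   names; see [exclusion_flags()].
#' @param pres,ever Feature observations at presentation / ever during the
#'   clinical course: a character vector of feature codes (implying
#'   `"present"`) or a named character vector of cell values, e.g.
#'   `c(limb_rigidity = "present,asymmetric", depression = "absent")`.
#' @param ever_from_pres If `TRUE` (default), any feature present at
#'   presentation and not mentioned in `ever` is copied forward as present
#'   ever, keeping the record longitudinally consistent.
#' @return A one-row cohort tibble.
#' @examples
#' new_patient("P01", age = 67, duration = 2,
#'             pres = c(limb_rigidity = "present,asymmetric",
#'                      limb_apraxia = "present"))
#' @export
new_patient <- function(patient_id,
                        sex = "unknown",
                        age = NA_real_,
                        duration = NA_real_,
                        insidious_onset = TRUE,
                        family_history = FALSE,
                        tau_mutation = FALSE,
                        pathology = NA_character_,
                        mmse = NA_real_,
                        acer = NA_real_,
                        exclusions = character(),
                        pres = character(),
                        ever = character(),
                        ever_from_pres = TRUE) {
  bad_excl <- setdiff(exclusions, exclusion_flags())
  if (length(bad_excl) > 0) {
    rlang::abort(paste0("Unknown exclusion flag(s): ",
                        paste(bad_excl, collapse = ", ")))
  }
  norm_obs <- function(x) {
    if (length(x) == 0) return(character())
    if (is.null(names(x))) x <- stats::setNames(rep("present", length(x)), x)
    bad <- setdiff(names(x), feature_codes())
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown feature code(s): ",
                          paste(bad, collapse = ", ")))
    }
    x
  }
  pres <- norm_obs(pres)
  ever <- norm_obs(ever)
  if (ever_from_pres) {
    carried <- pres[startsWith(pres, "present") & !(names(pres) %in% names(ever))]
    ever <- c(ever, carried)
  }

  row <- c(
    list(patient_id = as.character(patient_id)),
    patient_column_prototypes(),
    stats::setNames(rep(list(""), length(feature_columns())), feature_columns())
  )
  row$sex <- sex
  row$age_at_presentation <- as.numeric(age)
  row$symptom_duration_years <- as.numeric(duration)
  row$insidious_onset <- insidious_onset
  row$family_history <- family_history
  row$tau_mutation <- tau_mutation
  row$pathology <- pathology
  row$mmse <- as.numeric(mmse)
  row$acer <- as.numeric(acer)
  for (e in exclusions) row[[paste0("excl_", e)]] <- TRUE
  for (f in names(pres)) row[[paste0(f, "_pres")]] <- unname(pres[[f]])
  for (f in names(ever)) row[[paste0(f, "_ever")]] <- unname(ever[[f]])

  out <- tibble::as_tibble(row)[cohort_column_order()]
  check_cells(out)
  out
}

#' Combine patient records into a cohort
#'
#' @param ... One-row patient tibbles from [new_patient()] (or cohorts to
#'   concatenate).
#' @return A cohort tibble; errors if patient ids collide.
#' @export
cohort <- function(...) {
  out <- dplyr::bind_rows(...)
  assert_cohort(out)
  out
}

# parse "status[,laterality]" cells; "" -> undocumented
parse_cells <- function(x) {
  x <- ifelse(is.na(x), "", trimws(x))
  parts <- stringr::str_split_fixed(x, ",", 2)
  status <- ifelse(parts[, 1] == "", "undocumented", parts[, 1])
  laterality <- ifelse(parts[, 2] == "", "unknown", trimws(parts[, 2]))
  tibble::tibble(status = status, laterality = laterality)
}

check_cells <- function(cohort, call = rlang::caller_env()) {
  cells <- unlist(cohort[feature_columns()], use.names = FALSE)
  parsed <- parse_cells(cells)
  bad <- !(parsed$status %in% status_levels()) |
    !(parsed$laterality %in% laterality_levels()) |
    (parsed$status != "present" & parsed$laterality != "unknown")
  if (any(bad)) {
    rlang::abort(
      paste0("Invalid feature cell value(s): ",
             paste(unique(cells[bad])[1:min(3, sum(bad))], collapse = ", ")),
      call = call
    )
  }
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The on-disk dialect is UTF-8 comma-separated text with a header row and
#' one patient per row. Feature columns are `<feature>_pres` /
#' `<feature>_ever` with values `present`, `absent` or empty
#' (= undocumented), and an optional `,asymmetric` / `,symmetric` qualifier
#' on present motor features. Undocumented is preserved as a distinct state
#' through I/O: an empty cell is never coerced to `absent`.
#'
#' @param path File path.
#' @param aliases Optional named character vector mapping file column names
#'   to canonical cohort column names (`c(file_col = "canonical_col")`).
#' @param strict If `TRUE`, unrecognized columns are an error; otherwise a
#'   warning, and the columns are dropped.
#' @return `read_cohort()`: a cohort tibble. `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, aliases = NULL, strict = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(aliases)) {
    hit <- names(aliases)[names(aliases) %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- unname(aliases[hit])
  }
  if (!("patient_id" %in% names(raw))) {
    rlang::abort("Cohort file must have a `patient_id` column.")
  }
  unknown <- setdiff(names(raw), cohort_column_order())
  if (length(unknown) > 0) {
    msg <- paste0("Unrecognized column(s): ", paste(unknown, collapse = ", "))
    if (strict) rlang::abort(msg) else rlang::warn(msg)
    raw <- raw[setdiff(names(raw), unknown)]
  }
  if (anyDuplicated(raw$patient_id)) {
    dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
    rlang::abort(paste0("Duplicate patient_id: ", paste(dup, collapse = ", ")))
  }

  proto <- patient_column_prototypes()
  for (col in names(proto)) {
    if (!(col %in% names(raw))) {
      raw[[col]] <- rep(proto[[col]], nrow(raw))
    } else if (is.logical(proto[[col]])) {
      raw[[col]] <- as.logical(raw[[col]])
      if (startsWith(col, "excl_")) raw[[col]][is.na(raw[[col]])] <- FALSE
    } else if (is.numeric(proto[[col]])) {
      raw[[col]] <- as.numeric(raw[[col]])
    }
  }
  for (col in feature_columns()) {
    if (!(col %in% names(raw))) raw[[col]] <- ""
    raw[[col]][is.na(raw[[col]])] <- ""
  }
  out <- raw[cohort_column_order()]
  check_cells(out)
  assert_cohort(out)
  out
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  assert_cohort(cohort)
  readr::write_csv(cohort[cohort_column_order()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Pivot a cohort to long per-observation form
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per patient, feature and timepoint:
#'   `patient_id`, `feature`, `timepoint` (`"presentation"` or `"ever"`),
#'   `status` (`present`/`absent`/`undocumented`) and `laterality`
#'   (`asymmetric`/`symmetric`/`unknown`).
#' @export
cohort_observations <- function(cohort) {
  assert_cohort(cohort)
  long <- tidyr::pivot_longer(
    cohort[c("patient_id", feature_columns())],
    cols = -"patient_id",
    names_to = c("feature", "timepoint"),
    names_pattern = "^(.*)_(pres|ever)$",
    values_to = "cell"
  )
  long$timepoint <- ifelse(long$timepoint == "pres", "presentation", "ever")
  dplyr::bind_cols(
    long[c("patient_id", "feature", "timepoint")],
    parse_cells(long$cell)
  )
}

#' Validate longitudinal consistency of a cohort
#'
#' Validation never throws: it returns a (possibly empty) tibble of issues.
#' Checked rules: a feature documented present at presentation must not be
#' documented absent ever (longitudinal monotonicity); symptom duration must
#' be non-negative; a laterality qualifier is only meaningful on the motor
#' core features.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `patient_id`, `issue`, `feature` (`NA` for
#'   record-level issues).
#' @export
validate_cohort <- function(cohort) {
  assert_cohort(cohort)
  obs <- cohort_observations(cohort)

  wide <- tidyr::pivot_wider(obs[c("patient_id", "feature", "timepoint", "status")],
                             names_from = "timepoint", values_from = "status")
  mono <- wide[wide$presentation == "present" & wide$ever == "absent", ]
  issues <- tibble::tibble(
    patient_id = mono$patient_id,
    issue = rep("presentation_present_but_ever_absent", nrow(mono)),
    feature = mono$feature
  )

  neg <- cohort$patient_id[!is.na(cohort$symptom_duration_years) &
                             cohort$symptom_duration_years < 0]
  issues <- dplyr::bind_rows(issues, tibble::tibble(
    patient_id = neg,
    issue = rep("negative_duration", length(neg)),
    feature = rep(NA_character_, length(neg))
  ))

  lat <- obs[obs$laterality != "unknown" & !(obs$feature %in% motor_features()), ]
  lat <- dplyr::distinct(lat[c("patient_id", "feature")])
  issues <- dplyr::bind_rows(issues, tibble::tibble(
    patient_id = lat$patient_id,
    issue = rep("laterality_on_nonmotor_feature", nrow(lat)),
    feature = lat$feature
  ))

  dplyr::arrange(issues, .data$patient_id, .data$issue, .data$feature)
}

#' Write a validation report as JSON lines
#'
#' @param issues Issue tibble from [validate_cohort()].
#' @param path Output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_validation_issues <- function(issues, path) {
  lines <- vapply(seq_len(nrow(issues)), function(i) {
    jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
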