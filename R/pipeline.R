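#' Run the full validation analysis on a cohort
#'
#' Orchestrates the study replica in one deterministic pass: record
#' validation, phenotype and diagnosis classification at both timepoints,
#' documented-denominator frequency tables per pathology group, correlation
#' of the CBD group's frequency profile against the packaged published
#' reference, nested classification summaries, sensitivity/specificity at
#' both certainty levels, and per-feature 2x2 group comparisons under each
#' requested test.
#'
#' @param cohort A cohort tibble (see [read_cohort()], [simulate_cohort()],
#'   [demo_cohort()]).
#' @param reference Published reference profile; see [armstrong_reference()].
#' @param methods 2x2 test methods to run; see [contingency_test()].
#' @param label Free-text cohort label carried into the report.
#' @return A `cbd_validation` object: a list of tibbles (`issues`,
#'   `diagnoses`, `frequencies`, `correlation`, `classification`,
#'   `performance`, `group_tests`) with [print()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods. Sections that
#'   need a pathology contrast are populated with `NA` and a note when the
#'   cohort lacks one of the groups.
#' @examples
#' report <- run_validation(demo_cohort())
#' glance(report)
#' @export
run_validation <- function(cohort, reference = armstrong_reference(),
                           methods = c("pearson", "yates", "fisher"),
                           label = "cohort") {
  assert_cohort(cohort)
  issues <- validate_cohort(cohort)
  diagnoses <- diagnose(cohort)

  has_path <- !is.na(cohort$pathology)
  group_of <- ifelse(!has_path, NA_character_,
                     ifelse(cohort$pathology == "CBD", "CBD", "mimic"))
  groups <- unique(stats::na.omit(group_of))

  frequencies <- purrr::map_dfr(groups, function(g) {
    sub <- cohort[group_of %in% g, ]
    purrr::map_dfr(timepoints(), function(t) {
      out <- feature_frequency(sub, t)
      out$group <- g
      out
    })
  })

  correlation <- purrr::map_dfr(timepoints(), function(t) {
    out <- tibble::tibble(timepoint = t, n = NA_integer_, r = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          note = NA_character_)
    if (!("CBD" %in% groups)) {
      out$note <- "no CBD-pathology group in cohort"
      return(out)
    }
    freq <- frequencies[frequencies$group == "CBD" &
                          frequencies$timepoint == t, ]
    ref_t <- reference[reference$timepoint == t &
                         !is.na(reference$published_pct), ]
    joined <- dplyr::inner_join(ref_t[c("feature", "published_pct")],
                                freq[c("feature", "pct")], by = "feature")
    joined <- joined[stats::complete.cases(joined), ]
    res <- tryCatch(profile_correlation(joined, .data$published_pct, .data$pct),
                    error = function(e) NULL)
    if (is.null(res)) {
      out$note <- "too few paired features with documented frequencies"
      return(out)
    }
    tibble::tibble(timepoint = t, n = res$n, r = res$r,
                   statistic = res$statistic, p_value = res$p_value,
                   note = NA_character_)
  })

  classification <- purrr::map_dfr(groups, function(g) {
    d <- diagnoses[diagnoses$patient_id %in% cohort$patient_id[group_of %in% g], ]
    out <- classification_summary(d)
    out$group <- g
    out
  })

  both_groups <- all(c("CBD", "mimic") %in% groups) && all(has_path)
  performance <- purrr::map_dfr(timepoints(), function(t) {
    purrr::map_dfr(c("probable_only", "probable_or_possible"), function(lv) {
      if (both_groups) {
        diagnostic_performance(cohort, diagnoses, t, lv)
      } else {
        tibble::tibble(timepoint = t, level = lv, n_cases = NA_integer_,
                       n_detected = NA_integer_, sensitivity = NA_real_,
                       n_controls = NA_integer_, n_controls_meeting = NA_integer_,
                       specificity = NA_real_)
      }
    })
  })

  group_tests <- if (both_groups) {
    purrr::map_dfr(timepoints(), function(t) {
      purrr::map_dfr(methods, function(m) {
        out <- compare_features(cohort, t, method = m)
        out$method <- m
        out
      })
    })
  } else {
    tibble::tibble()
  }

  structure(
    list(label = label, n_patients = nrow(cohort), groups = table(group_of),
         issues = issues, diagnoses = diagnoses, frequencies = frequencies,
         correlation = correlation, classification = classification,
         performance = performance, group_tests = group_tests),
    class = "cbd_validation"
  )
}

#' @export
print.cbd_validation <- function(x, ...) {
  cat("Armstrong-criteria validation report:", x$label, "\n")
  cat("  patients:", x$n_patients,
      paste0("(", paste(names(x$groups), x$groups, sep = "=", collapse = ", "), ")"),
      "\n")
  cat("  validation issues:", nrow(x$issues), "\n")
  for (i in seq_len(nrow(x$correlation))) {
    row <- x$correlation[i, ]
    cat(sprintf("  frequency-profile correlation (%s): r=%s over %s features\n",
                row$timepoint,
                ifelse(is.na(row$r), "NA", sprintf("%.3f", row$r)),
                ifelse(is.na(row$n), "-", row$n)))
  }
  perf <- x$performance
  for (i in seq_len(nrow(perf))) {
    row <- perf[i, ]
    if (is.na(row$sensitivity)) next
    cat(sprintf("  %s / %s: sensitivity %d/%d (%.0f%%), specificity %d/%d (%.0f%%)\n",
                row$timepoint, row$level, row$n_detected, row$n_cases,
                100 * row$sensitivity, row$n_controls - row$n_controls_meeting,
                row$n_controls, 100 * row$specificity))
  }
  invisible(x)
}

#' Tidiers for validation reports
#'
#' `tidy()` returns the per-feature group-comparison table (or the frequency
#' table when the cohort has no pathology contrast); `glance()` returns a
#' one-row summary with the profile correlations and the headline
#' sensitivity/specificity figures.
#'
#' @param x A `cbd_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cbd_validation
#' @export
tidy.cbd_validation <- function(x, ...) {
  if (nrow(x$group_tests) > 0) x$group_tests else x$frequencies
}

#' @rdname tidy.cbd_validation
#' @method glance cbd_validation
#' @export
glance.cbd_validation <- function(x, ...) {
  pick_perf <- function(t, lv, col) {
    v <- x$performance[[col]][x$performance$timepoint == t &
                                x$performance$level == lv]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    n_patients = x$n_patients,
    n_issues = nrow(x$issues),
    r_presentation = x$correlation$r[x$correlation$timepoint == "presentation"],
    r_ever = x$correlation$r[x$correlation$timepoint == "ever"],
    sensitivity_probable_presentation = pick_perf("presentation", "probable_only", "sensitivity"),
    sensitivity_probable_ever = pick_perf("ever", "probable_only", "sensitivity"),
    specificity_presentation = pick_perf("presentation", "probable_or_possible", "specificity"),
    specificity_ever = pick_perf("ever", "probable_or_possible", "specificity")
  )
}

#' Plot cohort vs published frequency profiles
#'
#' Scatter of the cohort's documented-denominator percentage frequencies in
#' the CBD group against the published reference, by timepoint, with the
#' identity line.
#'
#' @param object A `cbd_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbd_validation
#' @export
autoplot.cbd_validation <- function(object, ...) {
  freq <- object$frequencies[object$frequencies$group == "CBD", ]
  ref <- armstrong_reference()
  joined <- dplyr::inner_join(
    ref[!is.na(ref$published_pct), c("feature", "timepoint", "published_pct")],
    freq[c("feature", "timepoint", "pct")],
    by = c("feature", "timepoint")
  )
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$published_pct, y = .data$pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~timepoint) +
    ggplot2::labs(x = "Published frequency (%)", y = "Cohort frequency (%)",
                  title = "Clinical-feature frequency profile vs published reference") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100))
}

#' @rdname autoplot.cbd_validation
#' @param report A `cbd_validation` object.
#' @export
plot_frequency_profile <- function(report, ...) autoplot.cbd_validation(report, ...)

#' Write a validation report to disk
#'
#' Writes diff-able, timestamp-free artifacts: TSV tables (`frequencies`,
#' `classification`, `performance`, `group_tests`, `diagnoses`), a JSON
#' machine-readable summary (`summary.json` with the glance row and the
#' correlation section) and a short Markdown narrative (`report.md`).
#' Re-running on the same inputs reproduces the files byte for byte.
#'
#' @param report A `cbd_validation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  tsv(report$frequencies, "frequencies")
  tsv(report$classification, "classification")
  tsv(report$performance, "performance")
  tsv(report$diagnoses, "diagnoses")
  if (nrow(report$group_tests) > 0) tsv(report$group_tests, "group_tests")

  summary <- list(
    label = report$label,
    glance = as.list(glance.cbd_validation(report)),
    correlation = report$correlation
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)

  g <- glance.cbd_validation(report)
  fmt_pct <- function(p) ifelse(is.na(p), "undefined",
                                paste0(round_half_up(100 * p), "%"))
  md <- c(
    paste0("# Validation report: ", report$label),
    "",
    paste0("Patients: ", report$n_patients, "; validation issues: ",
           nrow(report$issues), "."),
    "",
    paste0("Frequency-profile correlation vs published reference: r = ",
           ifelse(is.na(g$r_presentation), "undefined",
                  sprintf("%.2f", g$r_presentation)),
           " at presentation, r = ",
           ifelse(is.na(g$r_ever), "undefined", sprintf("%.2f", g$r_ever)),
           " during the disease course."),
    "",
    paste0("Sensitivity (probable CBD): ",
           fmt_pct(g$sensitivity_probable_presentation), " at presentation, ",
           fmt_pct(g$sensitivity_probable_ever), " during the course. ",
           "Specificity (probable or possible CBD): ",
           fmt_pct(g$specificity_presentation), " at presentation, ",
           fmt_pct(g$specificity_ever), " during the course.")
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
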