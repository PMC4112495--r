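#' Documented-denominator feature frequencies
#'
#' Tabulates each clinical feature at a timepoint using the
#' documented-denominator convention: the denominator is the number of
#' patients whose record explicitly documents presence or absence of the
#' feature; undocumented records are excluded from the denominator (unlike
#' classification, which reads omission as absence). The
#' bradykinesia/clumsy-limb composite row counts a patient as present if
#' either member is documented present and as documented if either member is
#' documented.
#'
#' @param cohort A cohort tibble.
#' @param timepoint `"presentation"` or `"ever"`.
#' @param features Feature codes to tabulate (default: all).
#' @param include_composite Add the `bradykinesia_clumsy_limb` composite
#'   row used by the published reference table.
#' @return A tibble with columns `feature`, `timepoint`, `n_present`,
#'   `n_documented`, `pct` (full precision, percent scale; `NA` when the
#'   denominator is zero) and `pct_display` (rounded half-up to integer).
#' @examples
#' co <- cohort(
#'   new_patient("P1", pres = c(tremor = "present")),
#'   new_patient("P2", pres = c(tremor = "absent")),
#'   new_patient("P3")
#' )
#' feature_frequency(co, "presentation", "tremor")  # 1/2 (50)
#' @export
feature_frequency <- function(cohort, timepoint = "presentation",
                              features = NULL, include_composite = TRUE) {
  assert_cohort(cohort)
  timepoint <- match_timepoint(timepoint)
  features <- features %||% feature_codes()
  bad <- setdiff(features, feature_codes())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown feature code(s): ", paste(bad, collapse = ", ")))
  }
  suffix <- if (timepoint == "presentation") "_pres" else "_ever"
  status_of <- function(f) parse_cells(cohort[[paste0(f, suffix)]])$status

  one <- function(f) {
    s <- status_of(f)
    tibble::tibble(feature = f, timepoint = timepoint,
                   n_present = sum(s == "present"),
                   n_documented = sum(s != "undocumented"))
  }
  out <- purrr::map_dfr(features, one)

  if (include_composite && all(c("bradykinesia", "clumsy_limb") %in% features)) {
    b <- status_of("bradykinesia")
    c_ <- status_of("clumsy_limb")
    comp <- tibble::tibble(
      feature = "bradykinesia_clumsy_limb", timepoint = timepoint,
      n_present = sum(b == "present" | c_ == "present"),
      n_documented = sum(b != "undocumented" | c_ != "undocumented")
    )
    out <- dplyr::bind_rows(out, comp)
  }
  out$pct <- ifelse(out$n_documented > 0, 100 * out$n_present / out$n_documented,
                    NA_real_)
  out$pct_display <- round_half_up(out$pct)
  out
}

#' Correlate two frequency profiles
#'
#' Pearson product-moment correlation between two paired percentage (or
#' proportion) profiles, e.g. the cohort's per-feature frequencies against
#' the published reference. Pairs with a missing value in either column are
#' dropped before the calculation. Significance uses the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom, two-sided. The coefficient is scale
#' invariant, so percents and proportions give identical results.
#'
#' @param data A data frame of paired values (one row per feature).
#' @param x,y Columns to correlate (tidy-eval).
#' @return A one-row tibble: `n` (complete pairs), `r`, `statistic` (t) and
#'   `p_value`.
#' @examples
#' profile_correlation(armstrong_reference(), published_pct, cohort_pct)
#' @export
profile_correlation <- function(data, x, y) {
  xv <- as.numeric(rlang::eval_tidy(rlang::enquo(x), data))
  yv <- as.numeric(rlang::eval_tidy(rlang::enquo(y), data))
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) rlang::abort("Need at least 3 complete pairs to correlate.")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    rlang::abort("Cannot correlate a profile with zero variance.")
  }
  r <- stats::cor(xv, yv)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  tibble::tibble(n = n, r = r, statistic = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

as_2x2 <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2, 2))) rlang::abort("`tab` must be 2x2.")
    tab <- as.numeric(t(tab))
  }
  if (length(tab) != 4 || any(is.na(tab)) || any(tab < 0) ||
      any(tab != floor(tab))) {
    rlang::abort("`tab` must be four non-negative integer counts (a, b, c, d).")
  }
  tab
}

#' Test association in a 2x2 contingency table
#'
#' Rows are the two pathology groups and columns feature present/absent
#' (counts `a`, `b` in row 1 and `c`, `d` in row 2). Three methods:
#' `"pearson"` is the uncorrected chi-squared statistic in closed form
#' `n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom;
#' `"yates"` applies the continuity correction, subtracting `n/2` from
#' `|ad - bc|` (floored at zero); `"fisher"` is the exact conditional test,
#' summing the hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed table (two-sided).
#'
#' @param tab A 2x2 matrix/data frame or a length-4 count vector
#'   `c(a, b, c, d)` read row-wise.
#' @param method `"pearson"`, `"yates"` or `"fisher"`.
#' @return A one-row tibble: `method`, `statistic` (`NA` for Fisher), `df`,
#'   `p_value`.
#' @examples
#' contingency_test(c(8, 3, 2, 13), method = "pearson")
#' @export
contingency_test <- function(tab, method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  x <- as_2x2(tab)
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)

  if (method %in% c("pearson", "yates")) {
    if (any(margins == 0)) {
      rlang::abort(paste0("Chi-squared test undefined with a zero margin ",
                          "(row/column totals ", paste(margins, collapse = ", "),
                          "); use method = \"fisher\"."))
    }
    delta <- abs(a * d - b * c_)
    if (method == "yates") delta <- max(0, delta - n / 2)
    stat <- n * delta^2 / prod(margins)
    return(tibble::new_tibble(
      list(method = method, statistic = stat, df = 1,
           p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
      nrow = 1L))
  }

  tibble::new_tibble(
    list(method = "fisher", statistic = NA_real_, df = NA_real_,
         p_value = fisher_p(a, b, c_, d)),
    nrow = 1L)
}

# two-sided Fisher exact p: sum of hypergeometric probabilities of all
# tables with the observed margins that are no more probable than the
# observed table (relative tolerance guards ties against rounding, as in
# stats::fisher.test)
fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  r2 <- c_ + d
  k <- a + c_
  if (r1 + r2 == 0) return(1)
  support <- max(0, k - r2):min(r1, k)
  probs <- stats::dhyper(support, r1, r2, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

#' Per-feature group comparison (CBD pathology vs mimics)
#'
#' Builds, for every clinical feature, the 2x2 table of documented presence
#' against pathology group (mimics in the first row, CBD in the second,
#' matching the convention "8/11 in CBD mimic cases compared with 2/15 in
#' the CBD pathology group") and tests it. Undocumented observations are
#' excluded per feature. No multiplicity correction is applied by default
#' (per-feature raw p values); set `p_adjust` for reuse in other settings.
#'
#' @param cohort A cohort tibble; `pathology` must be non-missing. `"CBD"`
#'   defines the case group, every other label the mimic group.
#' @param timepoint `"presentation"` or `"ever"`.
#' @param method Test passed to [contingency_test()].
#' @param p_adjust Multiple-testing correction method for
#'   [stats::p.adjust()] (default `"none"`).
#' @param features Feature codes to compare (default: all).
#' @return A tibble with one row per feature: the group counts
#'   (`mimic_present`, `mimic_documented`, `cbd_present`,
#'   `cbd_documented`), `statistic`, `p_value` and `note` (`NA`, or why the
#'   feature was skipped).
#' @export
compare_features <- function(cohort, timepoint = "presentation",
                             method = "pearson", p_adjust = "none",
                             features = NULL) {
  assert_cohort(cohort)
  timepoint <- match_timepoint(timepoint)
  features <- features %||% feature_codes()
  if (any(is.na(cohort$pathology))) {
    n_drop <- sum(is.na(cohort$pathology))
    rlang::warn(paste0("Dropping ", n_drop, " record(s) without a pathology label."))
    cohort <- cohort[!is.na(cohort$pathology), ]
  }
  is_cbd <- cohort$pathology == "CBD"
  if (!any(is_cbd) || all(is_cbd)) {
    rlang::abort("Group comparison needs both CBD and non-CBD pathology records.")
  }
  suffix <- if (timepoint == "presentation") "_pres" else "_ever"

  out <- purrr::map_dfr(features, function(f) {
    s <- parse_cells(cohort[[paste0(f, suffix)]])$status
    mp <- sum(s == "present" & !is_cbd)
    md <- sum(s != "undocumented" & !is_cbd)
    cp <- sum(s == "present" & is_cbd)
    cd <- sum(s != "undocumented" & is_cbd)
    row <- tibble::tibble(feature = f, timepoint = timepoint,
                          mimic_present = mp, mimic_documented = md,
                          cbd_present = cp, cbd_documented = cd,
                          statistic = NA_real_, p_value = NA_real_,
                          note = NA_character_)
    if (md == 0 || cd == 0) {
      row$note <- "skipped: no documented observations in one group"
      return(row)
    }
    res <- tryCatch(
      contingency_test(c(mp, md - mp, cp, cd - cp), method = method),
      error = function(e) NULL
    )
    if (is.null(res)) {
      row$note <- "skipped: degenerate margin for chi-squared; use fisher"
    } else {
      row$statistic <- res$statistic
      row$p_value <- res$p_value
    }
    row
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Sensitivity and specificity against neuropathology
#'
#' Cases are records with CBD pathology, controls all other pathology
#' labels. Sensitivity is the proportion of cases meeting the criteria at
#' the chosen certainty level; specificity is the proportion of controls
#' *not* meeting them. Indeterminate diagnosis flags count as not met.
#'
#' @param cohort A cohort tibble with non-missing `pathology`.
#' @param diagnoses Tibble from [diagnose()] on the same cohort.
#' @param timepoint `"presentation"` or `"ever"`.
#' @param level `"probable_only"` or `"probable_or_possible"`.
#' @return A one-row tibble: `timepoint`, `level`, `n_cases`, `n_detected`,
#'   `sensitivity`, `n_controls`, `n_controls_meeting`, `specificity`
#'   (proportions; `NA` when a group is empty).
#' @export
diagnostic_performance <- function(cohort, diagnoses,
                                   timepoint = "presentation",
                                   level = c("probable_only", "probable_or_possible")) {
  assert_cohort(cohort)
  timepoint <- match_timepoint(timepoint)
  level <- rlang::arg_match(level)
  if (any(is.na(cohort$pathology))) {
    rlang::abort("Every record needs a pathology label for performance analysis.")
  }
  d <- diagnoses[diagnoses$timepoint == timepoint, ]
  d <- d[match(cohort$patient_id, d$patient_id), ]
  if (any(is.na(d$patient_id))) {
    rlang::abort("`diagnoses` must cover every cohort patient at this timepoint.")
  }
  met <- if (level == "probable_only") d$probable_cbd %in% TRUE else
    d$possible_cbd %in% TRUE
  is_case <- cohort$pathology == "CBD"
  n_cases <- sum(is_case)
  n_controls <- sum(!is_case)
  n_detected <- sum(met & is_case)
  n_controls_meeting <- sum(met & !is_case)
  tibble::tibble(
    timepoint = timepoint, level = level,
    n_cases = n_cases, n_detected = n_detected,
    sensitivity = if (n_cases > 0) n_detected / n_cases else NA_real_,
    n_controls = n_controls, n_controls_meeting = n_controls_meeting,
    specificity = if (n_controls > 0) 1 - n_controls_meeting / n_controls else NA_real_
  )
}

#' Nested classification summary
#'
#' Reproduces the study's reporting convention: patients are counted once
#' under their precedence-resolved primary label, and additionally under
#' every category they meet irrespective of precedence (the count printed in
#' parentheses). With nine probable-CBD primaries and nine possible-only
#' patients, the possible-CBD row reads 9 primary, 18 inclusive
#' ("including probable CBD").
#'
#' @param diagnoses Tibble from [diagnose()].
#' @return A tibble with one row per timepoint and category: `timepoint`,
#'   `category`, `primary_n`, `inclusive_n`, `display` (e.g. `"9 (18)"`).
#'   Primary counts sum to the number of classified patients within each
#'   timepoint.
#' @export
classification_summary <- function(diagnoses) {
  cats <- cbd_rules()$precedence
  purrr::map_dfr(unique(diagnoses$timepoint), function(t) {
    d <- diagnoses[diagnoses$timepoint == t, ]
    inclusive <- c(
      probable_CBD = sum(d$probable_cbd %in% TRUE),
      possible_CBD = sum(d$possible_cbd %in% TRUE),
      probable_CBS = sum(d$probable_cbs),
      possible_CBS = sum(d$possible_cbs),
      FBS_NAV_overlap = sum(d$fbs & d$nav),
      FBS = sum(d$fbs),
      NAV = sum(d$nav),
      PSPS = sum(d$psps),
      none = sum(d$primary == "none")
    )
    primary <- vapply(cats, function(cc) sum(d$primary == cc), numeric(1))
    tibble::tibble(
      timepoint = t, category = cats,
      primary_n = unname(primary),
      inclusive_n = unname(inclusive[cats]),
      display = paste0(unname(primary), " (", unname(inclusive[cats]), ")")
    )
  })
}
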