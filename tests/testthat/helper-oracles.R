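# Independent oracles used by the property-style tests. These deliberately
# take different computational routes from the package implementation.

# chi-squared by explicit expected counts, sum((O - E)^2 / E), with the
# continuity correction applied per cell as min(0.5, |O - E|)
chisq_oracle <- function(a, b, c_, d, correct = FALSE) {
  obs <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / expd)
}

# two-sided Fisher p by direct factorial enumeration over all tables with
# the observed margins (lchoose route, not dhyper)
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  if (r1 + r2 == 0) return(1)
  xs <- max(0, k - r2):min(r1, k)
  probs <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(r1 + r2, k))
  sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# hypergeometric probability vector for a margin set; used to check every
# observed table of the margin set in one pass
fisher_oracle_margin <- function(r1, r2, k) {
  xs <- max(0, k - r2):min(r1, k)
  probs <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(r1 + r2, k))
  vapply(seq_along(xs), function(i) {
    sum(probs[probs <= probs[i] * (1 + 1e-7)])
  }, numeric(1))
}

# brute-force CBS classifier: searches explicitly for qualifying pairs of
# core features instead of counting
cbs_oracle <- function(motor, cortical, asymmetric) {
  pair_exists <- function(v) {
    idx <- which(v)
    length(idx) >= 2 && any(utils::combn(idx, 2, function(p) all(v[p])))
  }
  single_exists <- function(v) any(v)
  if (asymmetric && pair_exists(motor) && pair_exists(cortical)) return("probable")
  if (single_exists(motor) && single_exists(cortical)) return("possible")
  "none"
}

# a cohort of random records: arbitrary tri-state observations (not
# necessarily longitudinally consistent), random demographics including
# missing ages/durations, occasional exclusion flags
random_cohort <- function(n, seed) {
  set.seed(seed)
  codes <- feature_codes()
  motor <- c("limb_rigidity", "bradykinesia", "clumsy_limb",
             "limb_dystonia", "myoclonus")
  cells <- function(f) {
    pool <- if (f %in% motor) {
      c("", "absent", "present", "present,asymmetric", "present,symmetric")
    } else {
      c("", "absent", "present")
    }
    sample(pool, n, replace = TRUE)
  }
  cols <- c(
    list(
      patient_id = sprintf("R%06d", seq_len(n)),
      sex = sample(c("M", "F", "unknown"), n, replace = TRUE),
      age_at_presentation = sample(c(NA, 35, 45, 49, 50, 51, 67, 80), n, replace = TRUE),
      symptom_duration_years = sample(c(NA, 0.5, 1, 2, 5, 10), n, replace = TRUE),
      insidious_onset = sample(c(TRUE, TRUE, TRUE, FALSE, NA), n, replace = TRUE),
      family_history = sample(c(FALSE, FALSE, FALSE, TRUE), n, replace = TRUE),
      tau_mutation = sample(c(FALSE, FALSE, FALSE, TRUE), n, replace = TRUE),
      pathology = sample(c("CBD", "AD", "FTLD_TDP", "other"), n, replace = TRUE),
      mmse = rep(NA_real_, n),
      acer = rep(NA_real_, n)
    ),
    stats::setNames(
      lapply(exclusion_flags(), function(f) {
        sample(c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE), n, replace = TRUE)
      }),
      paste0("excl_", exclusion_flags())
    ),
    stats::setNames(lapply(paste0(codes, "_pres"), function(cn) {
      cells(sub("_pres$", "", cn))
    }), paste0(codes, "_pres")),
    stats::setNames(lapply(paste0(codes, "_ever"), function(cn) {
      cells(sub("_ever$", "", cn))
    }), paste0(codes, "_ever"))
  )
  tibble::as_tibble(cols)
}
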