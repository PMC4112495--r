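#' Triggered exclusion criteria
#'
#' Both probable and possible CBD require that none of the eight exclusion
#' criteria apply (evidence of Lewy body disease, multiple system atrophy,
#' amyotrophic lateral sclerosis, semantic or logopenic variant primary
#' progressive aphasia, a structural lesion, GRN mutation or reduced plasma
#' progranulin, TDP-43 or FUS mutation, or biomarker evidence of Alzheimer's
#' disease). Flags are independent of the feature observations and default
#' to `FALSE`.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per triggered flag: `patient_id`,
#'   `exclusion`, ordered by patient and by fixed declaration order.
#' @export
check_exclusions <- function(cohort) {
  assert_cohort(cohort)
  flags <- exclusion_flags()
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    hit <- flags[vapply(flags, function(f) isTRUE(cohort[[paste0("excl_", f)]][i]),
                        logical(1))]
    tibble::tibble(patient_id = rep(cohort$patient_id[i], length(hit)),
                   exclusion = hit)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(patient_id = character(), exclusion = character())
  }
  rows
}

# three-valued AND over logical vectors (NA = indeterminate)
and3 <- function(...) Reduce(`&`, list(...))

#' Apply the probable/possible-CBD diagnostic criteria
#'
#' Evaluates the diagnostic rule table on each patient at the requested
#' timepoint(s). Both certainty levels require insidious onset with gradual
#' progression and symptom duration of at least one year, and no triggered
#' exclusion criterion. Probable CBD additionally requires age at
#' presentation of at least 50 years, no family history in two or more
#' relatives and no tau mutation, and is reached through probable CBS or
#' through FBS/NAV plus at least one CBS core feature (a)-(f). Possible CBD
#' is reached through possible CBS, FBS, NAV, or PSPS plus at least one CBS
#' core feature (b)-(f). Probable implies possible (nested certainty).
#'
#' A missing age, onset or duration on a record whose phenotype route would
#' otherwise qualify yields an indeterminate (`NA`) flag rather than a
#' silent `FALSE`; the rule firing is recorded in `trace`. The pathology
#' label and cognitive scores are never consulted.
#'
#' @param cohort A cohort tibble.
#' @param timepoint `"presentation"`, `"ever"`, or both (default).
#' @param rules Rule table from [cbd_rules()].
#' @return A tibble with one row per patient and timepoint: the five
#'   phenotype flags, `excluded`, `triggered_exclusions` (comma-separated),
#'   `probable_cbd` and `possible_cbd` (logical, `NA` = indeterminate),
#'   `primary` (single precedence-resolved label) and `trace`.
#' @examples
#' pt <- new_patient("P01", age = 67, duration = 2,
#'   pres = c(limb_rigidity = "present,asymmetric",
#'            limb_dystonia = "present,asymmetric",
#'            limb_apraxia = "present", cortical_sensory_loss = "present"))
#' diagnose(pt, "presentation")
#' @export
diagnose <- function(cohort, timepoint = timepoints(), rules = cbd_rules()) {
  assert_cohort(cohort)
  timepoint <- match.arg(timepoint, timepoints(), several.ok = TRUE)

  excl_long <- check_exclusions(cohort)
  triggered <- vapply(cohort$patient_id, function(id) {
    paste(excl_long$exclusion[excl_long$patient_id == id], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  excluded <- triggered != ""

  gate <- and3(cohort$insidious_onset,
               cohort$symptom_duration_years >= rules$gates$min_duration_years)
  demo_ok <- and3(cohort$age_at_presentation >= rules$probable_cbd$min_age_years,
                  !cohort$family_history,
                  !cohort$tau_mutation)

  purrr::map_dfr(timepoint, function(t) {
    ph <- phenotypes(cohort, t)
    prof <- cbs_profile(cohort, t)
    core_a_f <- prof$motor_a | prof$motor_b | prof$motor_c |
      prof$cortical_d | prof$cortical_e | prof$cortical_f
    core_b_f <- prof$motor_b | prof$motor_c |
      prof$cortical_d | prof$cortical_e | prof$cortical_f

    probable_route <- ph$probable_cbs | ((ph$fbs | ph$nav) & core_a_f)
    possible_route <- ph$possible_cbs | ph$fbs | ph$nav | (ph$psps & core_b_f)

    probable_cbd <- ifelse(excluded | !probable_route, FALSE,
                           and3(probable_route, gate, demo_ok))
    possible_cbd <- ifelse(excluded | !possible_route, FALSE,
                           and3(possible_route, gate))
    # nested certainty: probable reports possible as well
    possible_cbd <- possible_cbd | probable_cbd

    trace <- paste0(
      "exclusions=", ifelse(excluded, triggered, "none"),
      ";gate=", ifelse(is.na(gate), "indeterminate", ifelse(gate, "pass", "fail")),
      ";probable_route=", ifelse(ph$probable_cbs, "probable_cbs",
                          ifelse((ph$fbs | ph$nav) & core_a_f, "fbs_nav_plus_core", "none")),
      ";probable_demographics=", ifelse(is.na(demo_ok), "indeterminate",
                                        ifelse(demo_ok, "pass", "fail")),
      ";possible_route=", ifelse(ph$possible_cbs, "possible_cbs",
                          ifelse(ph$fbs, "fbs", ifelse(ph$nav, "nav",
                          ifelse(ph$psps & core_b_f, "psps_plus_core", "none"))))
    )

    out <- ph
    out$excluded <- excluded
    out$triggered_exclusions <- triggered
    out$probable_cbd <- probable_cbd
    out$possible_cbd <- possible_cbd
    out$primary <- primary_label(ph, probable_cbd, possible_cbd)
    out$trace <- trace
    out
  })
}

#' Assign the single primary label
#'
#' Patients are classified first by diagnosis, then by phenotype, in the
#' fixed precedence order probable CBD > possible CBD > probable CBS >
#' possible CBS > FBS > NAV > PSPS > none. A patient meeting both FBS and
#' NAV without a CBD diagnosis is reported as the FBS-NAV overlap category.
#' Indeterminate (`NA`) diagnosis flags are treated as not met for labelling
#' (the indeterminacy is preserved in the diagnosis flags and trace).
#'
#' @param ph Phenotype tibble from [phenotypes()] (columns `probable_cbs`,
#'   `possible_cbs`, `fbs`, `nav`, `psps`).
#' @param probable_cbd,possible_cbd Logical vectors from the diagnostic
#'   rules.
#' @return Character vector of primary labels.
#' @export
primary_label <- function(ph, probable_cbd, possible_cbd) {
  dplyr::case_when(
    probable_cbd %in% TRUE ~ "probable_CBD",
    possible_cbd %in% TRUE ~ "possible_CBD",
    ph$probable_cbs ~ "probable_CBS",
    ph$possible_cbs ~ "possible_CBS",
    ph$fbs & ph$nav ~ "FBS_NAV_overlap",
    ph$fbs ~ "FBS",
    ph$nav ~ "NAV",
    ph$psps ~ "PSPS",
    TRUE ~ "none"
  )
}

#' Export per-patient diagnosis traces as JSON lines
#'
#' @param diagnoses Tibble from [diagnose()].
#' @param path Output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_diagnosis_trace <- function(diagnoses, path) {
  lines <- vapply(seq_len(nrow(diagnoses)), function(i) {
    jsonlite::toJSON(as.list(diagnoses[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
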