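# Effective presence at a timepoint. At "ever", a feature documented present
# at presentation counts as present during the course even if the ever cell
# was left undocumented (longitudinal monotonicity); classification treats
# undocumented as absent. Returns logical matrices (patients x features).
presence_frame <- function(cohort, timepoint) {
  timepoint <- match_timepoint(timepoint)
  codes <- feature_codes()
  n <- nrow(cohort)
  present <- asym <- sym <- matrix(FALSE, n, length(codes),
                                   dimnames = list(NULL, codes))
  for (f in codes) {
    cp <- cohort[[paste0(f, "_pres")]]
    ce <- cohort[[paste0(f, "_ever")]]
    p_pres <- startsWith(cp, "present")
    if (timepoint == "presentation") {
      present[, f] <- p_pres
      asym[, f] <- cp == "present,asymmetric"
      sym[, f] <- cp == "present,symmetric"
    } else {
      present[, f] <- p_pres | startsWith(ce, "present")
      asym[, f] <- cp == "present,asymmetric" | ce == "present,asymmetric"
      sym[, f] <- cp == "present,symmetric" | ce == "present,symmetric"
    }
  }
  list(present = present, asym = asym, sym = sym)
}

#' Corticobasal-syndrome core feature profile
#'
#' Maps a patient's observations at a timepoint onto the six CBS core
#' features: the motor triad (a) limb rigidity or akinesia — satisfied by
#' limb rigidity, bradykinesia or clumsy limb, counted once — (b) limb
#' dystonia, (c) limb myoclonus; and the cortical triad (d) orobuccal or
#' limb apraxia, (e) cortical sensory deficit, (f) alien limb phenomena.
#' `asymmetric` is `TRUE` when at least one present motor core feature
#' carries an asymmetric laterality qualifier. Undocumented features count
#' as absent.
#'
#' @param cohort A cohort tibble.
#' @param timepoint `"presentation"` or `"ever"`.
#' @return A tibble with columns `patient_id`, `timepoint`, `motor_a`,
#'   `motor_b`, `motor_c`, `cortical_d`, `cortical_e`, `cortical_f`
#'   (logicals) and `asymmetric`.
#' @export
cbs_profile <- function(cohort, timepoint = "presentation") {
  assert_cohort(cohort)
  timepoint <- match_timepoint(timepoint)
  pf <- presence_frame(cohort, timepoint)
  a_members <- c("limb_rigidity", "bradykinesia", "clumsy_limb")
  tibble::tibble(
    patient_id = cohort$patient_id,
    timepoint = timepoint,
    motor_a = rowSums(pf$present[, a_members, drop = FALSE]) > 0,
    motor_b = pf$present[, "limb_dystonia"],
    motor_c = pf$present[, "myoclonus"],
    cortical_d = pf$present[, "limb_apraxia"],
    cortical_e = pf$present[, "cortical_sensory_loss"],
    cortical_f = pf$present[, "alien_limb"],
    asymmetric = rowSums(pf$asym[, motor_features(), drop = FALSE] &
                           pf$present[, motor_features(), drop = FALSE]) > 0
  )
}

#' Classify CBS certainty from a core-feature profile
#'
#' Probable CBS requires an asymmetric presentation of at least two of the
#' three motor core features plus at least two of the three cortical core
#' features; possible CBS (which may be symmetric) requires at least one of
#' each. Probable implies possible; the strongest label is returned.
#'
#' @param profile A profile tibble from [cbs_profile()] (or any data frame
#'   with the six core-feature logical columns and `asymmetric`).
#' @return The input with an added `cbs` column:
#'   `"probable"`, `"possible"` or `"none"`.
#' @export
classify_cbs <- function(profile) {
  need <- c("motor_a", "motor_b", "motor_c",
            "cortical_d", "cortical_e", "cortical_f", "asymmetric")
  missing <- setdiff(need, names(profile))
  if (length(missing) > 0) {
    rlang::abort(paste0("`profile` is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  n_motor <- rowSums(as.matrix(profile[c("motor_a", "motor_b", "motor_c")]))
  n_cort <- rowSums(as.matrix(profile[c("cortical_d", "cortical_e", "cortical_f")]))
  out <- tibble::as_tibble(profile)
  out$cbs <- dplyr::case_when(
    profile$asymmetric & n_motor >= 2 & n_cort >= 2 ~ "probable",
    n_motor >= 1 & n_cort >= 1 ~ "possible",
    TRUE ~ "none"
  )
  out
}

#' Individual syndrome classifiers
#'
#' Crisp rule classifiers for the three non-CBS Armstrong phenotypes, each
#' returning one logical per patient. `classify_fbs()`: at least two of
#' executive dysfunction, behavioural or personality changes, visuospatial
#' deficits. `classify_nav()`: effortful agrammatic speech plus at least one
#' of impaired grammar/sentence comprehension or apraxia of speech.
#' `classify_psps()`: at least three of five composite items — (a) axial or
#' symmetric limb rigidity/akinesia, (b) postural instability or falls,
#' (c) urinary incontinence, (d) behavioural changes, (e) supranuclear
#' vertical gaze palsy — with each composite counted once.
#'
#' @param cohort A cohort tibble.
#' @param timepoint `"presentation"` or `"ever"`.
#' @return Logical vector, one element per patient.
#' @export
classify_fbs <- function(cohort, timepoint = "presentation") {
  assert_cohort(cohort)
  pf <- presence_frame(cohort, timepoint)
  triad <- c("executive_dysfunction", "behavioural_changes", "visuospatial_deficits")
  rowSums(pf$present[, triad, drop = FALSE]) >= 2
}

#' @rdname classify_fbs
#' @export
classify_nav <- function(cohort, timepoint = "presentation") {
  assert_cohort(cohort)
  pf <- presence_frame(cohort, timepoint)
  pf$present[, "effortful_agrammatic_speech"] &
    (pf$present[, "impaired_grammar_comprehension"] |
       pf$present[, "apraxia_of_speech"])
}

#' @rdname classify_fbs
#' @export
classify_psps <- function(cohort, timepoint = "presentation") {
  assert_cohort(cohort)
  pf <- presence_frame(cohort, timepoint)
  a_members <- c("limb_rigidity", "bradykinesia", "clumsy_limb")
  symmetric_akinesia <- rowSums(pf$present[, a_members, drop = FALSE] &
                                  pf$sym[, a_members, drop = FALSE]) > 0
  item_a <- pf$present[, "axial_rigidity"] | symmetric_akinesia
  item_b <- pf$present[, "postural_instability"] | pf$present[, "falls"]
  item_c <- pf$present[, "urinary_incontinence"]
  item_d <- pf$present[, "behavioural_changes"]
  item_e <- pf$present[, "vertical_gaze_palsy"]
  (item_a + item_b + item_c + item_d + item_e) >= 3
}

#' Evaluate all five Armstrong phenotypes
#'
#' Runs every syndrome classifier on each patient at the requested
#' timepoint(s). The phenotypes are non-exclusive: a patient may meet
#' several simultaneously, and probable CBS implies possible CBS.
#'
#' @param cohort A cohort tibble.
#' @param timepoint `"presentation"`, `"ever"`, or both (default).
#' @return A tibble with one row per patient and timepoint and logical
#'   columns `probable_cbs`, `possible_cbs`, `fbs`, `nav`, `psps`.
#' @examples
#' pt <- new_patient("P01",
#'   pres = c(limb_rigidity = "present,asymmetric",
#'            limb_dystonia = "present,asymmetric",
#'            limb_apraxia = "present", cortical_sensory_loss = "present"))
#' phenotypes(pt, "presentation")
#' @export
phenotypes <- function(cohort, timepoint = timepoints()) {
  assert_cohort(cohort)
  timepoint <- match.arg(timepoint, timepoints(), several.ok = TRUE)
  purrr::map_dfr(timepoint, function(t) {
    cbs <- classify_cbs(cbs_profile(cohort, t))$cbs
    tibble::tibble(
      patient_id = cohort$patient_id,
      timepoint = t,
      probable_cbs = cbs == "probable",
      possible_cbs = cbs %in% c("probable", "possible"),
      fbs = classify_fbs(cohort, t),
      nav = classify_nav(cohort, t),
      psps = classify_psps(cohort, t)
    )
  })
}
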