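#' Clinical feature vocabulary
#'
#' One row per coded clinical feature, with its role in the Armstrong
#' phenotype rules. `cbs_core` marks the six corticobasal-syndrome core
#' features: the motor triad (a) limb rigidity or akinesia, (b) limb
#' dystonia, (c) limb myoclonus, and the cortical triad (d) orobuccal or
#' limb apraxia, (e) cortical sensory deficit, (f) alien limb phenomena.
#' Limb rigidity, bradykinesia and clumsy limb all map onto core feature
#' (a), so any of them counts that composite once. `psps_item` marks the
#' five progressive-supranuclear-palsy-syndrome items (postural instability
#' and falls share item "b"; axial rigidity carries item "a", which is also
#' satisfied by symmetric limb rigidity/akinesia). Features with no rule
#' role are carried for frequency statistics only.
#'
#' @return A tibble with columns `feature`, `label`, `motor` (carries a
#'   laterality qualifier), `cbs_core` ("a".."f" or `NA`), `fbs` (member of
#'   the frontal behavioural-spatial triad), `nav` ("lead" or "support" or
#'   `NA`), and `psps_item` ("a".."e" or `NA`).
#' @examples
#' cbd_features()
#' @export
cbd_features <- function() {
  tibble::tribble(
    ~feature,                        ~label,                                   ~motor, ~cbs_core, ~fbs,  ~nav,      ~psps_item,
    "limb_rigidity",                 "Limb rigidity",                          TRUE,   "a",       FALSE, NA,        NA,
    "bradykinesia",                  "Bradykinesia",                           TRUE,   "a",       FALSE, NA,        NA,
    "clumsy_limb",                   "Clumsy limb",                            TRUE,   "a",       FALSE, NA,        NA,
    "limb_dystonia",                 "Limb dystonia",                          TRUE,   "b",       FALSE, NA,        NA,
    "myoclonus",                     "Myoclonus",                              TRUE,   "c",       FALSE, NA,        NA,
    "limb_apraxia",                  "Orobuccal or limb apraxia",              FALSE,  "d",       FALSE, NA,        NA,
    "cortical_sensory_loss",         "Cortical sensory loss",                  FALSE,  "e",       FALSE, NA,        NA,
    "alien_limb",                    "Alien limb phenomena",                   FALSE,  "f",       FALSE, NA,        NA,
    "executive_dysfunction",         "Executive dysfunction",                  FALSE,  NA,        TRUE,  NA,        NA,
    "behavioural_changes",           "Behavioural changes",                    FALSE,  NA,        TRUE,  NA,        "d",
    "visuospatial_deficits",         "Visuospatial deficits",                  FALSE,  NA,        TRUE,  NA,        NA,
    "effortful_agrammatic_speech",   "Effortful, agrammatic speech",           FALSE,  NA,        FALSE, "lead",    NA,
    "impaired_grammar_comprehension","Impaired grammar/sentence comprehension",FALSE,  NA,        FALSE, "support", NA,
    "apraxia_of_speech",             "Apraxia of speech",                      FALSE,  NA,        FALSE, "support", NA,
    "axial_rigidity",                "Axial rigidity",                         FALSE,  NA,        FALSE, NA,        "a",
    "postural_instability",          "Postural instability",                   FALSE,  NA,        FALSE, NA,        "b",
    "falls",                         "Falls",                                  FALSE,  NA,        FALSE, NA,        "b",
    "urinary_incontinence",          "Urinary incontinence",                   FALSE,  NA,        FALSE, NA,        "c",
    "vertical_gaze_palsy",           "Supranuclear vertical gaze palsy",       FALSE,  NA,        FALSE, NA,        "e",
    "tremor",                        "Tremor",                                 FALSE,  NA,        FALSE, NA,        NA,
    "abnormal_gait",                 "Abnormal gait",                          FALSE,  NA,        FALSE, NA,        NA,
    "cognitive_impairment",          "Cognitive impairment (overall)",         FALSE,  NA,        FALSE, NA,        NA,
    "aphasia",                       "Aphasia",                                FALSE,  NA,        FALSE, NA,        NA,
    "depression",                    "Depression",                             FALSE,  NA,        FALSE, NA,        NA,
    "hyperreflexia",                 "Hyperreflexia",                          FALSE,  NA,        FALSE, NA,        NA,
    "speech_changes",                "Speech changes",                         FALSE,  NA,        FALSE, NA,        NA,
    "abnormal_eye_movement",         "Abnormal eye movement",                  FALSE,  NA,        FALSE, NA,        NA
  )
}

#' @rdname cbd_features
#' @export
feature_codes <- function() cbd_features()$feature

# features carrying a meaningful laterality qualifier (CBS motor core a-c)
motor_features <- function() {
  f <- cbd_features()
  f$feature[f$motor]
}

#' Exclusion criteria flag names
#'
#' The eight exclusion criteria applied to both probable and possible CBD.
#' Each corresponds to a logical cohort column `excl_<name>`, defaulting to
#' `FALSE`. Order is the fixed declaration order used in reports.
#'
#' @return Character vector of exclusion flag names.
#' @export
exclusion_flags <- function() cbd_rules()$exclusions

exclusion_columns <- function() paste0("excl_", exclusion_flags())

# the two analysis timepoints
timepoints <- function() c("presentation", "ever")
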