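probable_features <- c(limb_rigidity = "present,asymmetric",
                       limb_dystonia = "present,asymmetric",
                       limb_apraxia = "present",
                       cortical_sensory_loss = "present")

test_that("exclusions are listed in declaration order and dominate", {
  expect_equal(nrow(check_exclusions(new_patient("P0", age = 60))), 0)
  one <- check_exclusions(new_patient("P1", exclusions = "lewy_body_evidence"))
  expect_equal(one$exclusion, "lewy_body_evidence")
  # declaration order, not the order given at construction
  two <- check_exclusions(new_patient("P2", exclusions = c("structural_lesion",
                                                           "als_evidence")))
  expect_equal(two$exclusion, c("als_evidence", "structural_lesion"))

  d <- diagnose(new_patient("P3", age = 67, duration = 2,
                            exclusions = "ad_biomarker_evidence",
                            pres = probable_features), "presentation")
  expect_true(d$excluded)
  expect_false(d$probable_cbd)
  expect_false(d$possible_cbd)
  # the phenotype survives exclusion and drives the primary label
  expect_equal(d$primary, "probable_CBS")
})

test_that("probable CBD requires age, genetics and a qualifying phenotype", {
  d <- diagnose(new_patient("P1", age = 67, duration = 2,
                            pres = probable_features), "presentation")
  expect_true(d$probable_cbd)
  expect_true(d$possible_cbd)
  expect_equal(d$primary, "probable_CBD")

  young <- diagnose(new_patient("P2", age = 45, duration = 2,
                                pres = probable_features), "presentation")
  expect_false(young$probable_cbd)
  expect_true(young$possible_cbd)
  expect_equal(young$primary, "possible_CBD")

  fam <- diagnose(new_patient("P3", age = 67, duration = 2,
                              family_history = TRUE,
                              pres = probable_features), "presentation")
  expect_false(fam$probable_cbd)
  tau <- diagnose(new_patient("P4", age = 67, duration = 2,
                              tau_mutation = TRUE,
                              pres = probable_features), "presentation")
  expect_false(tau$probable_cbd)

  # FBS plus a core feature reaches probable without probable CBS
  fbs <- diagnose(new_patient("P5", age = 60, duration = 3,
                              pres = c(executive_dysfunction = "present",
                                       visuospatial_deficits = "present",
                                       limb_rigidity = "present,symmetric")),
                  "presentation")
  expect_true(fbs$probable_cbd)
  # ... but not without any core feature
  fbs2 <- diagnose(new_patient("P6", age = 60, duration = 3,
                               pres = c(executive_dysfunction = "present",
                                        visuospatial_deficits = "present")),
                   "presentation")
  expect_false(fbs2$probable_cbd)
  expect_true(fbs2$possible_cbd) # FBS alone reaches possible

  # the PSPS route to possible CBD needs a core feature from (b)-(f);
  # symmetric rigidity (composite a) does not qualify
  psps_a <- diagnose(new_patient("P7", age = 60, duration = 3,
                                 pres = c(axial_rigidity = "present",
                                          falls = "present",
                                          urinary_incontinence = "present")),
                     "presentation")
  expect_false(psps_a$possible_cbd)
  psps_b <- diagnose(new_patient("P8", age = 60, duration = 3,
                                 pres = c(axial_rigidity = "present",
                                          falls = "present",
                                          urinary_incontinence = "present",
                                          limb_dystonia = "present")),
                     "presentation")
  expect_true(psps_b$possible_cbd)

  # the onset/duration gate applies to both levels
  short <- diagnose(new_patient("P9", age = 67, duration = 0.5,
                                pres = probable_features), "presentation")
  expect_false(short$probable_cbd)
  expect_false(short$possible_cbd)
  abrupt <- diagnose(new_patient("P10", age = 67, duration = 2,
                                 insidious_onset = FALSE,
                                 pres = probable_features), "presentation")
  expect_false(abrupt$probable_cbd)

  none <- diagnose(new_patient("P11", age = 67, duration = 2), "presentation")
  expect_false(none$probable_cbd)
  expect_false(none$possible_cbd)
  expect_equal(none$primary, "none")
})

test_that("missing age or duration gives indeterminate, not silent false", {
  no_age <- diagnose(new_patient("P1", duration = 2,
                                 pres = probable_features), "presentation")
  expect_true(is.na(no_age$probable_cbd))
  expect_true(no_age$possible_cbd)
  expect_match(no_age$trace, "probable_demographics=indeterminate")

  no_dur <- diagnose(new_patient("P2", age = 67,
                                 pres = probable_features), "presentation")
  expect_true(is.na(no_dur$probable_cbd))
  expect_true(is.na(no_dur$possible_cbd))
  expect_match(no_dur$trace, "gate=indeterminate")

  # without a qualifying phenotype, missing fields still give plain false
  empty <- diagnose(new_patient("P3"), "presentation")
  expect_false(empty$probable_cbd)
  expect_false(empty$possible_cbd)
})

test_that("primary labels follow the fixed precedence with FBS-NAV overlap", {
  fbs_probable <- diagnose(new_patient("P1", age = 60, duration = 3,
                                       pres = c(executive_dysfunction = "present",
                                                behavioural_changes = "present",
                                                limb_rigidity = "present,symmetric")),
                           "presentation")
  expect_equal(fbs_probable$primary, "probable_CBD")

  overlap_features <- c(executive_dysfunction = "present",
                        visuospatial_deficits = "present",
                        effortful_agrammatic_speech = "present",
                        apraxia_of_speech = "present")
  # FBS and NAV together without a CBD diagnosis (excluded) -> overlap label
  overlap <- diagnose(new_patient("P2", age = 60, duration = 3,
                                  exclusions = "msa_evidence",
                                  pres = overlap_features), "presentation")
  expect_true(overlap$fbs && overlap$nav)
  expect_equal(overlap$primary, "FBS_NAV_overlap")

  fbs_only <- diagnose(new_patient("P3", age = 60, duration = 3,
                                   exclusions = "msa_evidence",
                                   pres = c(executive_dysfunction = "present",
                                            visuospatial_deficits = "present")),
                       "presentation")
  expect_equal(fbs_only$primary, "FBS")
})

test_that("diagnosis is deterministic and probable implies possible", {
  co <- random_cohort(400, seed = 11)
  d1 <- diagnose(co)
  d2 <- diagnose(co)
  expect_identical(d1, d2)

  # nesting at both certainty systems, indeterminates included
  expect_true(all(!(d1$probable_cbs) | d1$possible_cbs))
  expect_true(all(!(d1$probable_cbd %in% TRUE) | (d1$possible_cbd %in% TRUE)))
  # exclusion dominance
  expect_true(all(!d1$excluded | (!d1$probable_cbd & !d1$possible_cbd)))
})
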