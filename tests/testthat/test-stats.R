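test_that("frequencies use documented denominators and half-up display", {
  co <- cohort(
    new_patient("P1", pres = c(tremor = "present")),
    new_patient("P2", pres = c(tremor = "absent")),
    new_patient("P3")
  )
  fr <- feature_frequency(co, "presentation", "tremor", include_composite = FALSE)
  expect_equal(fr$n_present, 1)
  expect_equal(fr$n_documented, 2)
  expect_equal(fr$pct, 50)

  # 10/17 documented present prints as 59 (half-up rounding of 58.82)
  co2 <- cohort(purrr::map(1:17, function(i) {
    new_patient(paste0("Q", i),
                pres = c(limb_rigidity = if (i <= 10) "present" else "absent"))
  }))
  fr2 <- feature_frequency(co2, "presentation", "limb_rigidity",
                           include_composite = FALSE)
  expect_equal(fr2$pct_display, 59)
  expect_equal(round_half_up(c(58.5, 58.49, -2.5)), c(59, 58, -3))

  # zero documented -> undefined entry, no error
  fr3 <- feature_frequency(co, "presentation", "falls", include_composite = FALSE)
  expect_true(is.na(fr3$pct))

  # permutation invariance over patient order
  shuffled <- co2[rev(seq_len(nrow(co2))), ]
  expect_equal(feature_frequency(shuffled, "presentation"),
               feature_frequency(co2, "presentation"))

  # composite row: either member documents/presents the pair
  co3 <- cohort(
    new_patient("R1", pres = c(bradykinesia = "present")),
    new_patient("R2", pres = c(clumsy_limb = "absent")),
    new_patient("R3")
  )
  comp <- feature_frequency(co3, "presentation")
  comp <- comp[comp$feature == "bradykinesia_clumsy_limb", ]
  expect_equal(comp$n_present, 1)
  expect_equal(comp$n_documented, 2)
})

test_that("profile correlation matches cor.test and is scale invariant", {
  set.seed(5)
  df <- tibble::tibble(x = runif(12, 0, 100),
                       y = runif(12, 0, 100))
  mine <- profile_correlation(df, x, y)
  ref <- stats::cor.test(df$x, df$y)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p_value, ref$p.value)
  expect_equal(mine$statistic, unname(ref$statistic))

  # identity and exact-zero correlation edge cases
  expect_equal(profile_correlation(df, x, x)$r, 1)
  zero <- tibble::tibble(x = c(-1, 0, 1), y = c(1, -2, 1))
  expect_equal(profile_correlation(zero, x, y)$r, 0)
  expect_equal(profile_correlation(zero, x, y)$p_value, 1)

  # percents and proportions give the same r
  expect_equal(profile_correlation(df, x, y)$r,
               profile_correlation(dplyr::mutate(df, x = x / 100), x, y)$r)

  # missing pairs are dropped before the call
  df$na_col <- df$y
  df$na_col[1:3] <- NA
  expect_equal(profile_correlation(df, x, na_col)$n, 9)

  expect_error(profile_correlation(tibble::tibble(x = 1:2, y = 2:3), x, y),
               "at least 3")
  expect_error(profile_correlation(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "zero variance")
})

test_that("chi-squared statistics match the expected-counts oracle", {
  # the printed myoclonus contrast in closed form
  res <- contingency_test(c(8, 3, 2, 13), "pearson")
  expect_equal(res$statistic, 26 * 98^2 / 26400)
  expect_equal(res$p_value,
               suppressWarnings(chisq.test(matrix(c(8, 3, 2, 13), 2,
                                                  byrow = TRUE),
                                           correct = FALSE)$p.value))

  set.seed(21)
  for (k in 1:40) {
    tab <- rmultinom(1, sample(8:30, 1), prob = runif(4, 0.1, 1))[, 1]
    if (any(c(tab[1] + tab[2], tab[3] + tab[4],
              tab[1] + tab[3], tab[2] + tab[4]) == 0)) next
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(contingency_test(tab, "pearson")$statistic,
                 chisq_oracle(tab[1], tab[2], tab[3], tab[4]))
    expect_equal(contingency_test(tab, "yates")$statistic,
                 chisq_oracle(tab[1], tab[2], tab[3], tab[4], correct = TRUE))
    expect_equal(contingency_test(tab, "yates")$p_value,
                 suppressWarnings(chisq.test(m)$p.value))
  }

  # zero margin: chi-squared refuses and points at Fisher
  expect_error(contingency_test(c(0, 5, 0, 7), "pearson"), "fisher")
  expect_error(contingency_test(c(0, 5, 0, 7), "yates"), "fisher")
  expect_error(contingency_test(c(1, 2, 3), "pearson"), "non-negative integer")
})

test_that("Fisher p agrees with enumeration and with fisher.test", {
  cases <- list(c(8, 3, 2, 13), c(10, 3, 8, 10), c(1, 9, 11, 3),
                c(0, 5, 0, 7), c(5, 0, 1, 4), c(2, 2, 2, 2))
  for (tab in cases) {
    p <- contingency_test(tab, "fisher")$p_value
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]))
    m <- matrix(tab, 2, byrow = TRUE)
    if (sum(tab) > 0) expect_equal(p, fisher.test(m)$p.value)
  }
})

test_that("group comparison reconstructs the printed contingency tables", {
  co <- demo_cohort()
  gt <- compare_features(co, "presentation", method = "pearson")

  myo <- gt[gt$feature == "myoclonus", ]
  expect_equal(c(myo$mimic_present, myo$mimic_documented - myo$mimic_present,
                 myo$cbd_present, myo$cbd_documented - myo$cbd_present),
               c(8, 3, 2, 13))
  vis <- gt[gt$feature == "visuospatial_deficits", ]
  expect_equal(c(vis$mimic_present, vis$mimic_documented - vis$mimic_present,
                 vis$cbd_present, vis$cbd_documented - vis$cbd_present),
               c(10, 3, 8, 10))

  # features undocumented in a group are skipped with a notice
  falls <- gt[gt$feature == "falls", ]
  expect_true(is.na(falls$p_value))
  expect_match(falls$note, "skipped")

  # optional multiplicity correction never shrinks a p value
  holm <- compare_features(co, "presentation", method = "fisher",
                           p_adjust = "holm")
  raw <- compare_features(co, "presentation", method = "fisher")
  keep <- !is.na(raw$p_value)
  expect_true(all(holm$p_value[keep] >= raw$p_value[keep]))

  expect_error(compare_features(co[co$pathology == "CBD", ], "presentation"),
               "both CBD and non-CBD")
})

test_that("performance summaries compute the published arithmetic", {
  co <- demo_cohort()
  d <- diagnose(co)

  sens <- diagnostic_performance(co, d, "presentation", "probable_only")
  expect_equal(sens$n_detected, 9)
  expect_equal(sens$n_cases, 19)
  expect_equal(sens$sensitivity, 9 / 19)

  spec <- diagnostic_performance(co, d, "presentation", "probable_or_possible")
  expect_equal(spec$n_controls_meeting, 14)
  expect_equal(spec$specificity, 0)

  ever <- diagnostic_performance(co, d, "ever", "probable_only")
  expect_equal(ever$n_detected, 13)

  # no controls -> specificity undefined, not an error
  cbd_only <- co[co$pathology == "CBD", ]
  solo <- diagnostic_performance(cbd_only, diagnose(cbd_only),
                                 "presentation", "probable_only")
  expect_true(is.na(solo$specificity))
  expect_equal(solo$sensitivity, 9 / 19)

  no_label <- co
  no_label$pathology[1] <- NA
  expect_error(diagnostic_performance(no_label, d, "presentation"),
               "pathology label")
})

test_that("classification summaries nest inclusive counts over primaries", {
  co <- demo_cohort()
  d <- diagnose(co)
  cbd <- d[d$patient_id %in% co$patient_id[co$pathology == "CBD"], ]
  cs <- classification_summary(cbd)
  pres <- cs[cs$timepoint == "presentation", ]

  # nine probable primaries plus nine possible-only -> "9 (18)"
  expect_equal(pres$display[pres$category == "possible_CBD"], "9 (18)")
  expect_equal(pres$primary_n[pres$category == "probable_CBD"], 9)

  # inclusive >= primary everywhere; primaries partition the patients
  expect_true(all(cs$inclusive_n >= cs$primary_n))
  expect_equal(sum(pres$primary_n), 19)

  # a patient meeting everything is one primary but counted in every row
  rich <- diagnose(new_patient("X1", age = 67, duration = 2, pres = c(
    limb_rigidity = "present,asymmetric", limb_dystonia = "present,asymmetric",
    limb_apraxia = "present", cortical_sensory_loss = "present",
    executive_dysfunction = "present", visuospatial_deficits = "present",
    behavioural_changes = "present",
    effortful_agrammatic_speech = "present", apraxia_of_speech = "present",
    axial_rigidity = "present", falls = "present")))
  one <- classification_summary(rich)
  one_pres <- one[one$timepoint == "presentation", ]
  expect_equal(sum(one_pres$primary_n), 1)
  expect_true(all(one_pres$inclusive_n[!(one_pres$category %in% "none")] == 1))

  empty <- classification_summary(diagnose(new_patient("X2")[0, ]))
  expect_equal(nrow(empty), 0)
})
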