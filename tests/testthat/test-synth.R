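test_that("equal configurations generate identical cohorts", {
  plan <- tiny_plan()
  eff <- effect_config(pitch_shift_ids = 1.5, seed = 42)
  c1 <- generate_cohort(plan, vowel_inventory(), eff)
  c2 <- generate_cohort(plan, vowel_inventory(), eff)
  expect_identical(c1$tokens, c2$tokens)
  expect_identical(c1$phrases, c2$phrases)
  expect_identical(c1$roster, c2$roster)
  c3 <- generate_cohort(plan, vowel_inventory(),
                        effect_config(pitch_shift_ids = 1.5, seed = 43))
  expect_false(identical(c1$phrases, c3$phrases))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_cohort(tiny_plan(n_families = 2),
                            effects = effect_config(seed = 9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("every token and phrase carries the modelling covariates", {
  coh <- generate_cohort(tiny_plan(), vowel_inventory(),
                         effect_config(seed = 1))
  covars <- c("family_id", "speaker_id", "parent_gender", "child_gender",
              "session", "child_age_days", "register", "recording_order")
  expect_true(all(covars %in% names(coh$tokens)))
  expect_true(all(c(covars, "onset", "n_syllables", "phonation_time",
                    "f0_min", "f0_mean", "f0_max") %in% names(coh$phrases)))
  expect_true(all(coh$phrases$f0_min <= coh$phrases$f0_mean))
  expect_true(all(coh$phrases$f0_mean <= coh$phrases$f0_max))
  expect_setequal(unique(coh$phrases$register), c("ADS", "IDS"))
  # every surviving family x session has exactly one ADS and one IDS recording
  per_cell <- table(coh$roster$family_id, coh$roster$session)
  recs <- unique(coh$phrases[, c("family_id", "session", "register")])
  expect_equal(nrow(recs), 2 * nrow(coh$roster))
})

test_that("a neutral configuration produces no register contrast", {
  coh <- generate_cohort(cohort_plan(n_families = 50,
                                     phrases_per_recording = 8,
                                     tokens_per_category_per_session = 3),
                         vowel_inventory(), effect_config(seed = 7))
  ph <- add_pitch_measures(coh$phrases)
  # paired within recording-pair: difference of per-recording mean pitch
  agg <- stats::aggregate(pitch_st ~ family_id + session + register, ph, mean)
  wide <- merge(subset(agg, register == "IDS"),
                subset(agg, register == "ADS"),
                by = c("family_id", "session"))
  tt <- stats::t.test(wide$pitch_st.x - wide$pitch_st.y)
  expect_lt(abs(tt$statistic), 4)
  dur <- stats::aggregate(duration_ms ~ family_id + session + register,
                          coh$tokens, function(x) mean(log(x)))
  wd <- merge(subset(dur, register == "IDS"), subset(dur, register == "ADS"),
              by = c("family_id", "session"))
  expect_lt(abs(stats::t.test(wd$duration_ms.x - wd$duration_ms.y)$statistic), 4)
})

test_that("peripheralization expands the IDS vowel space and leaves ADS alone", {
  inv <- vowel_inventory()
  areas <- vapply(c(1, 1.2, 1.5, 2), function(k) {
    eff <- effect_config(peripheralization_ids = k, seed = 1)
    m <- expected_category_means(inv, eff, gender = "mother",
                                 register = "IDS")
    idx <- match(inv$corner_triple, m$category)
    polygon_area(m$f1[idx], m$f2[idx])
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  ads <- vapply(c(1, 2), function(k) {
    m <- expected_category_means(inv, effect_config(peripheralization_ids = k),
                                 gender = "mother", register = "ADS")
    idx <- match(inv$corner_triple, m$category)
    polygon_area(m$f1[idx], m$f2[idx])
  }, numeric(1))
  expect_equal(ads[1], ads[2])
  # and the effect is visible in generated tokens
  coh <- generate_cohort(cohort_plan(n_families = 30,
                                     phrases_per_recording = 2,
                                     tokens_per_category_per_session = 5),
                         inv, effect_config(peripheralization_ids = 1.5,
                                            seed = 3))
  s <- suppressMessages(summarize_sessions(coh$tokens, coh$phrases))$sessions
  expect_gt(mean(s$vowel_space_corner[s$register == "IDS"], na.rm = TRUE),
            mean(s$vowel_space_corner[s$register == "ADS"], na.rm = TRUE))
})

test_that("waveform layouts are honoured exactly and validated", {
  w <- generate_waveform(data.frame(duration = 1, voiced = TRUE,
                                    amplitude = 0.5))
  expect_equal(sum(with(w$truth_segments, (end - start)[voiced])), 1.0)
  w2 <- generate_waveform(data.frame(duration = c(0.5, 0.4, 0.5),
                                     voiced = c(TRUE, FALSE, TRUE)))
  expect_equal(sum(with(w2$truth_segments, (end - start)[voiced])), 1.0,
               tolerance = 1e-4)
  expect_equal(waveform_duration(w2), 1.4, tolerance = 1e-4)
  # truth segments tile the duration without overlap
  expect_equal(w2$truth_segments$start[-1],
               w2$truth_segments$end[-nrow(w2$truth_segments)])
  expect_error(generate_waveform(data.frame(duration = numeric(0),
                                            voiced = logical(0))),
               "at least one span")
  expect_error(generate_waveform(data.frame(duration = c(1, 0.5),
                                            voiced = c(TRUE, FALSE),
                                            amplitude = c(0.001, 0.0005))),
               "10x")
})

test_that("alignment tiers reproduce phrase structure and reject overlap", {
  coh <- generate_cohort(tiny_plan(n_families = 2), vowel_inventory(),
                         effect_config(seed = 5))
  ph <- coh$phrases[coh$phrases$recording_id == coh$phrases$recording_id[1], ]
  ali <- generate_alignment(ph, seed = 1)
  expect_true(all(table(ali$phones$parent_word) >= 1))
  expect_equal(sum(ali$phones$is_target_vowel), sum(ph$n_syllables))
  expect_true(all(ali$phones$label[ali$phones$is_target_vowel] %in%
                    vowel_inventory()$categories))
  # segmentation of the generated word tier recovers the phrases
  seg <- build_phrases(ali$words)
  expect_equal(nrow(seg), nrow(ph))
  expect_equal(seg$onset, sort(ph$onset))
  bad <- ph
  bad$onset[2] <- bad$onset[1]
  bad$offset[2] <- bad$offset[1] + 0.1
  expect_error(generate_alignment(bad), "overlap")
})

test_that("a planned 600 ms gap yields exactly two phrases downstream", {
  phrases <- tibble::tibble(onset = c(0.2, 1.8), offset = c(1.2, 2.8),
                            n_syllables = c(3L, 2L))
  ali <- generate_alignment(phrases, seed = 2)
  seg <- build_phrases(ali$words)
  expect_equal(nrow(seg), 2L)
  seg1 <- build_phrases(word_tier_from_layout(c(1, 1), c(0, 0)))
  expect_equal(nrow(seg1), 1L)
})
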