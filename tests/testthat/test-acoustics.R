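test_that("the semitone map hits its reference points and octave identity", {
  expect_equal(hz_to_semitones(10), 0)
  expect_equal(hz_to_semitones(20), 12)
  expect_equal(hz_to_semitones(440), 12 * log2(44), tolerance = 1e-12)
  expect_equal(hz_to_semitones(440), 65.513, tolerance = 1e-3)
  f <- c(75, 123.4, 200, 317)
  expect_equal(hz_to_semitones(2 * f) - hz_to_semitones(f), rep(12, 4),
               tolerance = 1e-12)
  expect_true(all(diff(hz_to_semitones(seq(50, 500, by = 1))) > 0))
  expect_equal(semitones_to_hz(hz_to_semitones(163.2)), 163.2,
               tolerance = 1e-12)
  expect_error(hz_to_semitones(0), "positive")
})

test_that("phrase pitch and range come from the F0 summaries", {
  ph <- tibble::tibble(f0_min = c(150, 200, NA), f0_mean = c(160, 200, 180),
                       f0_max = c(180, 200, 210))
  expect_message(out <- add_pitch_measures(ph), "excluded")
  expect_equal(out$pitch_st[1], 12 * log2(16), tolerance = 1e-12)
  expect_equal(out$pitch_range_st[2], 0)
  expect_true(is.na(out$pitch_st[3]))
  # doubling all F0 adds 12 semitones to pitch, leaves range unchanged
  doubled <- suppressMessages(add_pitch_measures(
    tibble::tibble(f0_min = 300, f0_mean = 320, f0_max = 360)))
  base <- suppressMessages(add_pitch_measures(
    tibble::tibble(f0_min = 150, f0_mean = 160, f0_max = 180)))
  expect_equal(doubled$pitch_st - base$pitch_st, 12, tolerance = 1e-12)
  expect_equal(doubled$pitch_range_st, base$pitch_range_st,
               tolerance = 1e-12)
})

test_that("articulation rate is syllables per second of phonation", {
  expect_equal(articulation_rate(5, 1.0), 5)
  expect_equal(articulation_rate(6, 1.2), 5)
  expect_error(articulation_rate(0, 1), "n_syllables")
  expect_error(articulation_rate(3, 0), "phonation_time")
})

test_that("polygon_area matches hand values and the fan oracle", {
  expect_equal(polygon_area(c(0, 2, 0), c(0, 0, 2)), 2)
  expect_equal(polygon_area(c(0, 1, 2), c(0, 1, 2)), 0)  # collinear
  expect_error(polygon_area(c(0, 1), c(0, 1)), ">= 3")
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:7, 1)
    f1 <- stats::rnorm(n, 500, 200)
    f2 <- stats::rnorm(n, 1500, 400)
    a <- polygon_area(f1, f2)
    expect_equal(a, fan_area(f1, f2), tolerance = 1e-12)
    # invariant under cyclic rotation and reversal
    k <- sample(n, 1)
    rot <- c(k:n, seq_len(k - 1))
    expect_equal(polygon_area(f1[rot], f2[rot]), a, tolerance = 1e-9)
    expect_equal(polygon_area(rev(f1), rev(f2)), a, tolerance = 1e-9)
    # quadratic homogeneity under uniform formant rescaling
    expect_equal(polygon_area(3 * f1, 3 * f2), 9 * a, tolerance = 1e-9)
  }
})

test_that("vowel_space uses category means in the fixed border order", {
  inv <- vowel_inventory()
  tok <- tibble::tibble(
    category = rep(c("i:", "ae:", "u:"), each = 2),
    f1 = c(290, 310, 690, 710, 340, 360),
    f2 = c(2190, 2210, 1590, 1610, 690, 710)
  )
  got <- vowel_space(tok, "corner", inv)
  expect_equal(got, fan_area(c(300, 700, 350), c(2200, 1600, 700)))
  # all means identical: degenerate polygon, zero area
  same <- tibble::tibble(category = c("i:", "ae:", "u:"),
                         f1 = c(500, 500, 500), f2 = c(1500, 1500, 1500))
  expect_equal(vowel_space(same, "corner", inv), 0)
  # missing category: cell skipped
  expect_message(res <- vowel_space(tok[tok$category != "u:", ], "corner",
                                    inv),
                 "missing category")
  expect_true(is.na(res))
  # full version needs the seven border vowels
  full_tok <- tibble::tibble(category = inv$border_order,
                             f1 = unname(inv$mean_f1[inv$border_order]),
                             f2 = unname(inv$mean_f2[inv$border_order]))
  expect_equal(vowel_space(full_tok, "full", inv),
               fan_area(full_tok$f1, full_tok$f2))
})

test_that("vowel variability is the pi-sd-sd ellipse area", {
  expect_equal(vowel_variability(c(-100, 0, 100) + 500,
                                 c(-200, 0, 200) + 1500),
               pi * 100 * 200)
  expect_equal(pi * 100 * 200, 62831.85, tolerance = 1e-2)
  expect_equal(vowel_variability(rep(400, 5), rep(1200, 5)), 0)
  expect_message(res <- vowel_variability(400, 1200), "fewer than 2")
  expect_true(is.na(res))
  # doubling the spread quadruples the area
  set.seed(3)
  f1 <- stats::rnorm(40, 500, 60)
  f2 <- stats::rnorm(40, 1500, 100)
  expect_equal(vowel_variability(2 * f1, 2 * f2),
               4 * vowel_variability(f1, f2), tolerance = 1e-9)
})

test_that("distinctiveness matches the hand example and the ANOVA oracle", {
  tok <- tibble::tibble(category = c("A", "A", "B", "B"),
                        f1 = c(0, 0, 10, 10), f2 = c(0, 2, 0, 2))
  expect_equal(vowel_distinctiveness(tok, exclude = character(0)), 100 / 104)
  expect_equal(100 / 104, 0.9615, tolerance = 1e-4)
  # tokens exactly at distinct centroids: quotient 1
  exact <- tibble::tibble(category = c("A", "A", "B", "B"),
                          f1 = c(1, 1, 5, 5), f2 = c(2, 2, 9, 9))
  expect_equal(vowel_distinctiveness(exact, exclude = character(0)), 1)
  # equal centroids with dispersed tokens: quotient 0
  null <- tibble::tibble(category = c("A", "A", "B", "B"),
                         f1 = c(-1, 1, -2, 2), f2 = c(1, -1, 2, -2))
  expect_equal(vowel_distinctiveness(null, exclude = character(0)), 0)
  # excluded category does not influence the result
  inv <- vowel_inventory()
  set.seed(5)
  base <- tibble::tibble(
    category = rep(c("i:", "a:", "u:"), each = 8),
    f1 = stats::rnorm(24, rep(c(280, 680, 320), each = 8), 50),
    f2 = stats::rnorm(24, rep(c(2250, 1100, 700), each = 8), 90))
  with_y <- dplyr::bind_rows(base, tibble::tibble(
    category = "y:", f1 = stats::rnorm(8, 290, 50),
    f2 = stats::rnorm(8, 2200, 90)))
  expect_equal(vowel_distinctiveness(with_y), vowel_distinctiveness(base))
  # identical tokens: undefined
  flat <- tibble::tibble(category = c("A", "B"), f1 = c(1, 1), f2 = c(2, 2))
  expect_message(res <- vowel_distinctiveness(flat, exclude = character(0)),
                 "zero total")
  expect_true(is.na(res))
})

test_that("session summaries have one row per speaker-register-session", {
  coh <- generate_cohort(tiny_plan(n_families = 1), vowel_inventory(),
                         effect_config(seed = 12))
  m <- suppressMessages(summarize_sessions(coh$tokens, coh$phrases))
  one <- m$sessions[m$sessions$session == coh$roster$session[1], ]
  expect_equal(nrow(one), 2L)
  expect_setequal(one$register, c("ADS", "IDS"))
  expect_true(all(m$sessions$distinctiveness >= 0 &
                    m$sessions$distinctiveness <= 1, na.rm = TRUE))
  expect_true(all(m$sessions$vowel_space_corner >= 0, na.rm = TRUE))
  expect_true(all(m$phrases$articulation_rate > 0 |
                    is.na(m$phrases$articulation_rate)))
})

test_that("doubling within-category spread quadruples measured variability", {
  coh <- generate_cohort(cohort_plan(n_families = 30,
                                     phrases_per_recording = 2,
                                     tokens_per_category_per_session = 6),
                         vowel_inventory(),
                         effect_config(variability_inflation_ids = 2,
                                       seed = 17))
  m <- suppressMessages(summarize_sessions(coh$tokens, coh$phrases))
  v <- m$variability
  ratio <- mean(v$variability[v$register == "IDS"], na.rm = TRUE) /
    mean(v$variability[v$register == "ADS"], na.rm = TRUE)
  expect_equal(ratio, 4, tolerance = 0.2)
})
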