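test_that("the four Hudgins features match their definitions", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(0, 10)), 0)
  expect_error(mav(numeric(0)), "empty")

  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(1:10), 0)
  expect_error(zero_crossings(1), "2 samples")

  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0)), 3)
  expect_equal(slope_sign_changes(seq(0, 1, length.out = 10)), 0)
  expect_error(slope_sign_changes(c(1, 2)), "3 samples")

  expect_equal(waveform_length(c(0, 1, 3, 2)), 4)
  expect_equal(waveform_length(rep(7, 5)), 0)
  expect_error(waveform_length(3), "2 samples")
})

test_that("ZC and SSC agree with brute-force enumeration on random input", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- sample(c(-1, 1), 50, replace = TRUE) * runif(50, 0.5, 2)
    zc_brute <- 0
    for (t in 1:49)
      if (x[t] * x[t + 1] < 0 && abs(x[t] - x[t + 1]) > 0)
        zc_brute <- zc_brute + 1
    expect_equal(zero_crossings(x), zc_brute)
    ssc_brute <- 0
    for (t in 2:49)
      if ((x[t] - x[t - 1]) * (x[t] - x[t + 1]) > 0)
        ssc_brute <- ssc_brute + 1
    expect_equal(slope_sign_changes(x), ssc_brute)
  }
})

test_that("feature properties: scaling, reversal, deadbands", {
  set.seed(3)
  x <- rnorm(100)
  k <- 3.7
  expect_equal(mav(k * x), k * mav(x))
  expect_equal(waveform_length(k * x), k * waveform_length(x))
  ## counts invariant under positive rescaling at zero deadband
  expect_equal(zero_crossings(k * x), zero_crossings(x))
  expect_equal(slope_sign_changes(k * x), slope_sign_changes(x))
  expect_equal(waveform_length(rev(x)), waveform_length(x))
  ## a deadband larger than every step suppresses all counts
  expect_equal(zero_crossings(0.001 * x, zc_eps = 1), 0)
  expect_equal(slope_sign_changes(0.001 * x, ssc_eps = 1), 0)
})

test_that("extract_features lays out channels in 4-feature blocks", {
  set.seed(4)
  one <- rnorm(64)
  w <- matrix(rep(one, each = 16), 16, 64)
  v <- extract_features(w)
  expect_length(v, 64)
  expect_equal(unname(v), rep(unname(v[1:4]), 16))   # identical channels

  expect_equal(extract_features(matrix(0, 16, 30)), rep(0, 64),
               ignore_attr = TRUE)

  w2 <- matrix(rnorm(16 * 40), 16, 40)
  v2 <- extract_features(w2)
  for (c in c(1, 7, 16)) {
    expect_equal(unname(v2[(c - 1) * 4 + 1]), mav(w2[c, ]))
    expect_equal(unname(v2[(c - 1) * 4 + 2]), zero_crossings(w2[c, ]))
    expect_equal(unname(v2[(c - 1) * 4 + 3]), slope_sign_changes(w2[c, ]))
    expect_equal(unname(v2[(c - 1) * 4 + 4]), waveform_length(w2[c, ]))
  }
  expect_error(extract_features(matrix(0, 15, 30), n_channels = 16),
               "15 channels")
  expect_identical(extract_features(w2), extract_features(w2))  # pure
})

test_that("vectorised trial features equal the per-window path", {
  set.seed(5)
  x <- matrix(rnorm(4 * 700), 4, 700)
  ws <- window_spec(50, 25)    # 100 / 50 samples at 2 kHz
  fast <- trial_features(x, ws, 2000)
  wins <- slide_windows(x, ws, 2000)
  expect_equal(nrow(fast), length(wins))
  slow <- t(vapply(wins, extract_features, numeric(16)))
  expect_equal(fast, slow, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("session_features carries labels and provenance per window", {
  f <- day1_features()
  expect_true(all(c("participant", "day", "session", "position", "grasp",
                    "trial_id", "window_start") %in% names(f)))
  expect_length(grep("^ch[0-9]+_", names(f)), 64)
  ## 0.5 s trials at 2 kHz: floor((1000 - 256) / 100) + 1 = 8 windows each
  expect_equal(unname(table(f$trial_id)[1]), 8)
  expect_equal(sort(unique(f$position)), c(2, 4, 5, 6, 8))
  expect_equal(sort(unique(f$grasp)), 1:6)
  ## all windows of a trial share the trial's grasp label
  per_trial <- tapply(f$grasp, f$trial_id, function(g) length(unique(g)))
  expect_true(all(per_trial == 1))
})
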