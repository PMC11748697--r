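test_that("simulated trials have the contracted shapes", {
  sp <- sim_params()
  tr <- simulate_trial(sp, position = 5, grasp = 2, seed = 1)
  expect_equal(dim(tr$emg), c(16, 10000))   # 16 x (2 kHz * 5 s)
  expect_equal(dim(tr$glove), c(18, 10000))
  short <- simulate_trial(sp, 5, 2, seed = 1, trial_length = 0.25)
  expect_equal(dim(short$emg), c(16, 500))
  expect_error(simulate_trial(sp, position = 12, grasp = 1, seed = 1),
               "position")
  expect_error(simulate_trial(sp, position = 5, grasp = 9, seed = 1), "grasp")
})

test_that("with all stochastic terms off the EMG is the DC offset", {
  dc <- seq(-0.2, 0.3, length.out = 16)
  sp <- suppressWarnings(sim_params(
    amp_profile = matrix(0, 6, 16), shift_magnitude = 0,
    powerline_amp = 0, dc_offset = dc))
  tr <- simulate_trial(sp, 5, 1, seed = 3, trial_length = 0.1)
  expect_equal(tr$emg, matrix(dc, 16, 200), tolerance = 1e-12)
})

test_that("trial simulation is bitwise deterministic in the seed", {
  sp <- sim_params()
  a <- simulate_trial(sp, 4, 3, seed = 99, trial_length = 0.25)
  b <- simulate_trial(sp, 4, 3, seed = 99, trial_length = 0.25)
  expect_identical(a$emg, b$emg)
  expect_identical(a$glove, b$glove)
  c <- simulate_trial(sp, 4, 3, seed = 100, trial_length = 0.25)
  expect_false(identical(a$emg, c$emg))
})

test_that("position shift scales per-channel RMS by 1 + delta * u", {
  u <- default_shift_pattern()
  for (seed in 1:5) {
    sp0 <- quiet_params(delta = 0)
    sp5 <- quiet_params(delta = 0.5)
    t0 <- simulate_trial(sp0, 3, 1, seed = seed, trial_length = 0.25)
    t5 <- simulate_trial(sp5, 3, 1, seed = seed, trial_length = 0.25)
    rms <- function(m) sqrt(rowMeans(m^2))
    ratio <- rms(t5$emg) / rms(t0$emg)
    expect_equal(ratio, 1 + 0.5 * u[3, ], tolerance = 0.05,
                 ignore_attr = TRUE)
  }
})

test_that("powerline interference dominates the 50 Hz periodogram bin", {
  sp <- sim_params(powerline_amp = 0.5)
  tr <- simulate_trial(sp, 5, 6, seed = 2, trial_length = 1)
  x <- tr$emg[1, ]
  p <- abs(fft(x))^2
  hz <- function(f) f * length(x) / 2000 + 1
  expect_gt(p[hz(50)], 10 * p[hz(40)])
  expect_gt(p[hz(50)], 10 * p[hz(60)])
})

test_that("position centroid separation grows with the shift magnitude", {
  deltas <- c(0, 0.2, 0.5, 1.0)
  cfg <- protocol_config(trial_length = 0.25, trials_per_grasp = 2,
                         grasps = c(1, 4), sessions_per_day = 1)
  fs <- filter_spec()
  mean_sep <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    seps <- vapply(1:10, function(seed) {
      sp <- quiet_params(delta = deltas[i], seed = seed)
      recs <- simulate_session_records(cfg, sp, 1, day = 1, session = 1)
      f <- session_features(recs, fs)
      fm <- as.matrix(f[, grep("^ch", names(f))])
      cent <- rowsum(fm, f$position) / as.vector(table(f$position))
      mean(dist(cent))
    }, numeric(1))
    mean_sep[i] <- mean(seps)
  }
  expect_true(all(diff(mean_sep) >= 0))
})

test_that("participants receive distinct but reproducible amplitude jitter", {
  sp <- sim_params()
  cfg <- protocol_config(trial_length = 0.1, trials_per_grasp = 1,
                         grasps = 1:2, positions_day1 = 5,
                         sessions_per_day = 1)
  r1 <- simulate_session_records(cfg, sp, 1, 1, 1, jitter = TRUE)
  r1b <- simulate_session_records(cfg, sp, 1, 1, 1, jitter = TRUE)
  r2 <- simulate_session_records(cfg, sp, 2, 1, 1, jitter = TRUE)
  expect_identical(r1[[1]]$emg, r1b[[1]]$emg)
  expect_false(identical(r1[[1]]$emg, r2[[1]]$emg))
})
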