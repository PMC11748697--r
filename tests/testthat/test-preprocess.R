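rms <- function(x) sqrt(mean(x^2))
tone <- function(freq, T = 10000, fs = 2000) sin(2 * pi * freq * (0:(T - 1)) / fs)

test_that("band-pass passes the band and rejects out-of-band tones", {
  fs <- filter_spec()
  steady <- 1001:10000          # skip the causal-filter transient
  y5 <- bandpass(tone(5), fs)
  expect_lt(rms(y5[steady]), 0.1 * rms(tone(5)[steady]))
  y100 <- bandpass(tone(100), fs)
  ratio_db <- 20 * log10(rms(y100[steady]) / rms(tone(100)[steady]))
  expect_gt(ratio_db, -3)
  expect_equal(bandpass(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass(rep(0, 10), fs), "short")
  expect_error(filter_spec(low_cutoff = 500, high_cutoff = 450), "cutoff")
  expect_error(filter_spec(high_cutoff = 1200), "Nyquist")
})

test_that("notch attenuates 50 Hz by 20 dB and spares 100 Hz", {
  fs <- filter_spec()
  steady <- 2001:10000
  power <- function(x) mean(x^2)
  y50 <- notch(tone(50), fs)
  att50_db <- 10 * log10(power(tone(50)[steady]) / power(y50[steady]))
  expect_gt(att50_db, 20)
  y100 <- notch(tone(100), fs)
  att100_db <- 10 * log10(power(tone(100)[steady]) / power(y100[steady]))
  expect_lt(att100_db, 3)
  expect_equal(notch(rep(0, 1000), fs), rep(0, 1000))
})

test_that("filtering is per-channel independent", {
  fs <- filter_spec()
  x <- matrix(rnorm(8 * 2000), 8, 2000)
  perm <- sample(8)
  expect_equal(bandpass(x, fs)[perm, ], bandpass(x[perm, ], fs))
  expect_equal(notch(x, fs)[perm, ], notch(x[perm, ], fs))
})

test_that("offset removal zeroes channel means and is idempotent", {
  x <- matrix(3.7, 4, 100)
  expect_equal(remove_offset(x), matrix(0, 4, 100))
  y <- matrix(rnorm(4 * 100), 4, 100)
  y0 <- remove_offset(y)
  expect_lt(max(abs(rowMeans(y0))), 1e-9)
  expect_equal(remove_offset(y0), y0)
})

test_that("window extraction matches the count formula and tiles correctly", {
  ws <- window_spec()            # 128 ms / 50 ms
  x <- matrix(rnorm(2 * 10000), 2, 10000)
  wins <- slide_windows(x, ws, 2000)
  expect_length(wins, floor((10000 - 256) / 100) + 1)  # 98
  expect_length(wins, 98)
  starts <- vapply(wins, attr, 0L, "start")
  ## brute-force enumeration of valid start offsets
  brute <- Filter(function(s) s + 256 <= 10000, (0:10000))
  brute <- brute[brute %% 100 == 0]
  expect_equal(starts, brute)
  expect_equal(wins[[3]], x[, 201:456], ignore_attr = TRUE)

  ## generic (T, w, s) combinations against the same brute force
  for (i in 1:10) {
    T <- sample(300:1200, 1)
    w_ms <- sample(c(50, 100, 128, 150), 1)
    s_ms <- sample(c(25, 50, 75), 1)
    v <- rnorm(T)
    wn <- slide_windows(v, window_spec(w_ms, s_ms), 2000)
    w <- w_ms * 2; s <- s_ms * 2
    expect_length(wn, floor((T - w) / s) + 1)
  }
  expect_length(slide_windows(rnorm(256), ws, 2000), 1)  # T == w
  expect_error(slide_windows(rnorm(100), ws, 2000), "shorter")
  expect_error(slide_windows(rnorm(1000), window_spec(128.3, 50), 2000),
               "whole samples")
})

test_that("majority vote picks the mode with smallest-label tie-break", {
  expect_equal(majority_label(c(1, 1, 2)), 1)
  expect_equal(majority_label(c(2, 2, 3, 3)), 2)
  expect_equal(majority_label(rep(4, 10)), 4)
  expect_equal(majority_label(c("b", "b", "a", "a")), "a")
  expect_error(majority_label(numeric(0)), "no labels")
})

test_that("z-score statistics come from training data only", {
  train <- matrix(c(-1, 1), 2, 3)
  zs <- zscore_fit(train)
  expect_equal(unname(zs$center), rep(0, 3))
  expect_equal(unname(zs$scale), rep(1, 3))
  expect_equal(zscore_apply(matrix(0.5, 1, 3), zs), matrix(0.5, 1, 3))

  x <- matrix(rnorm(50 * 4), 50, 4)
  zs <- zscore_fit(x)
  z <- zscore_apply(x, zs)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, function(v) sqrt(mean(v^2))), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)

  const <- cbind(rnorm(10), rep(2, 10))
  expect_warning(zs <- zscore_fit(const), "constant")
  expect_equal(zscore_apply(const, zs)[, 2], rep(0, 10))
  expect_error(zscore_fit(matrix(1, 1, 2)), "at least 2")
})

test_that("per-sensor pooled z-scoring shares stats within channel blocks", {
  x <- matrix(rnorm(40 * 8, mean = rep(c(0, 5), each = 4 * 40)), 40, 8)
  zs <- zscore_fit(x, by = "sensor", n_features_per_channel = 4)
  expect_equal(zs$center[1:4], rep(zs$center[1], 4), ignore_attr = TRUE)
  expect_equal(zs$scale[5:8], rep(zs$scale[5], 4), ignore_attr = TRUE)
})
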