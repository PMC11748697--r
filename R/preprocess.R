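#' Filter specification for EMG preprocessing
#'
#' Fourth-order Butterworth band-pass (20-450 Hz by default) plus a notch
#' for powerline interference. The notch frequency is not part of the
#' published parameter set; 50 Hz matches a UK mains supply and is
#' configurable for 60 Hz recordings.
#'
#' @param order Butterworth design order.
#' @param low_cutoff,high_cutoff band edges in Hz.
#' @param notch_freq powerline frequency in Hz.
#' @param notch_q quality factor of the notch (centre frequency divided by
#'   -3 dB bandwidth).
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, low_cutoff = 20, high_cutoff = 450,
                        notch_freq = 50, notch_q = 30, sampling_rate = 2000) {
  if (!is_count(order)) stopf("order must be a positive integer")
  if (!is_number(low_cutoff) || !is_number(high_cutoff) ||
      low_cutoff <= 0 || low_cutoff >= high_cutoff)
    stopf("need 0 < low_cutoff < high_cutoff")
  if (high_cutoff >= sampling_rate / 2)
    stopf("high_cutoff must be below the Nyquist frequency (%g Hz)",
          sampling_rate / 2)
  if (notch_freq >= sampling_rate / 2)
    stopf("notch_freq must be below the Nyquist frequency")
  if (!is_number(notch_q) || notch_q <= 0) stopf("notch_q must be positive")
  structure(
    list(order = as.integer(order), low_cutoff = low_cutoff,
         high_cutoff = high_cutoff, notch_freq = notch_freq,
         notch_q = notch_q, sampling_rate = sampling_rate),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "Butterworth order %d, band %g-%g Hz; notch %g Hz (Q = %g) at %g Hz\n",
    x$order, x$low_cutoff, x$high_cutoff, x$notch_freq, x$notch_q,
    x$sampling_rate))
  invisible(x)
}

butter_coefs <- function(spec) {
  bt <- signal::butter(spec$order,
                       c(spec$low_cutoff, spec$high_cutoff) /
                         (spec$sampling_rate / 2),
                       type = "pass")
  list(b = bt$b, a = bt$a)
}

## biquad notch (constant-Q design): b = [1, -2cos w0, 1],
## a = [1 + alpha, -2cos w0, 1 - alpha], alpha = sin(w0) / (2 Q)
notch_coefs <- function(spec) {
  w0 <- 2 * pi * spec$notch_freq / spec$sampling_rate
  alpha <- sin(w0) / (2 * spec$notch_q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1 + alpha, -2 * cos(w0), 1 - alpha) / (1 + alpha))
}

## common applicator: signals are channel x time; the compiled kernel
## filters columns, so transpose in and out. zero_phase runs the filter
## forwards then backwards (filtfilt-style, squared magnitude response).
apply_iir <- function(x, coefs, zero_phase = FALSE) {
  vec <- is.null(dim(x))
  xt <- if (vec) matrix(x, ncol = 1) else t(x)
  y <- iir_filter_cols(coefs$b, coefs$a, xt)
  if (zero_phase) {
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    y <- iir_filter_cols(coefs$b, coefs$a, y)
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  }
  if (vec) as.numeric(y) else {
    out <- t(y)
    dimnames(out) <- dimnames(x)
    out
  }
}

#' Band-pass filter a signal
#'
#' Applies the Butterworth band-pass of `spec` independently to each
#' channel (row). Filtering is causal (forward-only) by default, matching
#' signals processed upon recording; set `zero_phase = TRUE` for a
#' forward-backward pass.
#'
#' @param x numeric vector or channels x time matrix.
#' @param spec a [filter_spec()].
#' @param zero_phase use forward-backward filtering.
#' @return filtered signal of the same shape.
#' @export
#' @examples
#' t <- (0:9999) / 2000
#' tone <- sin(2 * pi * 100 * t)
#' y <- bandpass(tone, filter_spec())
bandpass <- function(x, spec, zero_phase = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  T <- if (is.null(dim(x))) length(x) else ncol(x)
  if (T <= 3 * spec$order)
    stopf("signal too short to filter (%d samples)", T)
  apply_iir(x, butter_coefs(spec), zero_phase)
}

#' Notch-filter a signal
#'
#' Removes powerline interference with a biquad notch centred at
#' `spec$notch_freq`, applied independently per channel.
#'
#' @inheritParams bandpass
#' @return filtered signal of the same shape.
#' @export
notch <- function(x, spec, zero_phase = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  T <- if (is.null(dim(x))) length(x) else ncol(x)
  if (T <= 6L) stopf("signal too short to filter (%d samples)", T)
  apply_iir(x, notch_coefs(spec), zero_phase)
}

#' Remove per-channel DC offset
#'
#' Subtracts each channel's mean so every output row has mean zero.
#'
#' @param x numeric vector or channels x time matrix.
#' @return same-shape signal with zero-mean channels.
#' @export
remove_offset <- function(x) {
  if (is.null(dim(x))) x - mean(x) else x - rowMeans(x)
}

#' Sliding-window specification
#'
#' @param length window length in ms (default 128, as used by the
#'   validation experiments).
#' @param stride hop between consecutive windows in ms.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 128, stride = 50) {
  if (!is_number(length) || length <= 0) stopf("length must be positive")
  if (!is_number(stride) || stride <= 0) stopf("stride must be positive")
  structure(list(length = length, stride = stride), class = "window_spec")
}

window_samples <- function(wspec, sampling_rate) {
  w <- wspec$length * sampling_rate / 1000
  s <- wspec$stride * sampling_rate / 1000
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9)
    stopf("window length/stride must convert to whole samples at %g Hz",
          sampling_rate)
  list(w = as.integer(round(w)), s = as.integer(round(s)))
}

## 0-based start offsets of the floor((T - w) / s) + 1 windows
window_starts <- function(T, w, s) {
  if (T < w) stopf("signal (%d samples) shorter than one window (%d)", T, w)
  seq.int(0L, T - w, by = s)
}

#' Extract sliding windows from a signal
#'
#' Cuts a channels x time signal into `floor((T - w) / s) + 1` windows of
#' `w` samples hopped by `s` samples; any trailing remainder shorter than
#' one window is dropped, and windows never cross trial boundaries because
#' trials are windowed independently.
#'
#' @param x numeric vector or channels x time matrix.
#' @param wspec a [window_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @return a list of same-type segments, each carrying its 0-based sample
#'   offset in attribute `"start"`.
#' @export
#' @examples
#' length(slide_windows(matrix(rnorm(16 * 10000), 16), window_spec(), 2000))
slide_windows <- function(x, wspec, sampling_rate = 2000) {
  stopifnot(inherits(wspec, "window_spec"))
  ws <- window_samples(wspec, sampling_rate)
  vec <- is.null(dim(x))
  T <- if (vec) length(x) else ncol(x)
  starts <- window_starts(T, ws$w, ws$s)
  lapply(starts, function(s0) {
    seg <- if (vec) x[(s0 + 1):(s0 + ws$w)] else
      x[, (s0 + 1):(s0 + ws$w), drop = FALSE]
    attr(seg, "start") <- s0
    seg
  })
}

#' Majority-vote label of a window
#'
#' Returns the modal label of the per-sample labels covered by a window;
#' ties are broken towards the smallest label value.
#'
#' @param labels non-empty vector of labels.
#' @return the winning label, of the same type as the input.
#' @export
#' @examples
#' majority_label(c(2, 2, 3, 3))  # tie -> 2
majority_label <- function(labels) {
  if (length(labels) == 0L) stopf("cannot take a majority of no labels")
  tt <- table(labels)
  winners <- names(tt)[tt == max(tt)]
  win <- if (!anyNA(suppressWarnings(as.numeric(winners))))
    winners[which.min(as.numeric(winners))] else sort(winners)[1]
  if (is.numeric(labels)) as.numeric(win)
  else if (is.factor(labels)) factor(win, levels = levels(labels))
  else win
}

#' Per-dimension z-score normalisation
#'
#' `zscore_fit()` estimates per-dimension means and standard deviations on
#' training features only; `zscore_apply()` reuses them on any feature
#' matrix, so no test-set statistics ever leak into the normalisation.
#' Dimensions that are constant in training are flagged with a warning and
#' mapped to zero. With `by = "sensor"` the four Hudgins features of each
#' channel share pooled statistics instead of per-dimension ones — an
#' alternative reading of per-sensor normalisation, off by default because
#' the four features live on very different scales.
#'
#' @param x numeric training matrix, samples x dimensions.
#' @param by `"dimension"` (default) or `"sensor"`.
#' @param n_features_per_channel block size used when `by = "sensor"`.
#' @return `zscore_fit()` returns an object of class `zscore_stats`;
#'   `zscore_apply()` returns the normalised matrix.
#' @export
zscore_fit <- function(x, by = c("dimension", "sensor"),
                       n_features_per_channel = 4L) {
  by <- match.arg(by)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 training samples to z-score")
  pop_sd <- function(v) sqrt(mean(v^2) - mean(v)^2)  # population sd, as usual for z-scoring
  if (by == "dimension") {
    center <- colMeans(x)
    scale <- apply(x, 2, pop_sd)
  } else {
    d <- ncol(x)
    if (d %% n_features_per_channel != 0L)
      stopf("dimension %d is not a multiple of the per-channel block", d)
    block <- rep(seq_len(d %/% n_features_per_channel),
                 each = n_features_per_channel)
    center <- ave(colMeans(x), block)
    pooled_sd <- vapply(split(seq_len(d), block),
                        function(j) pop_sd(as.numeric(x[, j])), numeric(1))
    scale <- pooled_sd[block]
  }
  constant <- !is.finite(scale) | scale == 0
  if (any(constant))
    warnf("%d constant feature dimension(s) in training data; mapped to 0",
          sum(constant))
  structure(list(center = center, scale = scale, constant = constant),
            class = "zscore_stats")
}

#' @rdname zscore_fit
#' @param stats a `zscore_stats` object from `zscore_fit()`.
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$center))
    stopf("feature dimension mismatch: %d vs %d", ncol(x),
          length(stats$center))
  scl <- ifelse(stats$constant, 1, stats$scale)
  out <- sweep(sweep(x, 2, stats$center, "-"), 2, scl, "/")
  if (any(stats$constant)) out[, stats$constant] <- 0
  out
}
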