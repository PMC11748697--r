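#' Hudgins time-domain features
#'
#' The classic four-feature descriptor of one single-channel window:
#' mean absolute value (MAV), zero crossings (ZC), slope sign changes
#' (SSC) and waveform length (WL). The optional amplitude/slope deadbands
#' default to zero because the reference processing states none; classic
#' formulations often use small positive thresholds, so both are exposed.
#'
#' @param x numeric vector, one channel of one window.
#' @param zc_eps amplitude deadband: a sign change only counts when the
#'   two samples differ by more than `zc_eps`.
#' @param ssc_eps slope deadband: an extremum only counts when the product
#'   of adjacent slope differences exceeds `ssc_eps`.
#' @return a scalar (`mav`, `waveform_length`) or integer count
#'   (`zero_crossings`, `slope_sign_changes`).
#' @name hudgins
#' @examples
#' mav(c(1, -1, 2, -2))              # 1.5
#' zero_crossings(c(1, -1, 1, -1))   # 3
#' slope_sign_changes(c(0, 1, 0, 1, 0))  # 3
#' waveform_length(c(0, 1, 3, 2))    # 4
NULL

#' @rdname hudgins
#' @export
mav <- function(x) {
  if (length(x) == 0L) stopf("empty window")
  mean(abs(x))
}

#' @rdname hudgins
#' @export
zero_crossings <- function(x, zc_eps = 0) {
  n <- length(x)
  if (n < 2L) stopf("zero crossings need at least 2 samples")
  sum(x[-n] * x[-1] < 0 & abs(x[-n] - x[-1]) > zc_eps)
}

#' @rdname hudgins
#' @export
slope_sign_changes <- function(x, ssc_eps = 0) {
  n <- length(x)
  if (n < 3L) stopf("slope sign changes need at least 3 samples")
  mid <- x[2:(n - 1)]
  sum((mid - x[1:(n - 2)]) * (mid - x[3:n]) > ssc_eps)
}

#' @rdname hudgins
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stopf("waveform length needs at least 2 samples")
  sum(abs(diff(x)))
}

feature_names <- function(n_channels) {
  as.vector(t(outer(sprintf("ch%02d", seq_len(n_channels)),
                    c("mav", "zc", "ssc", "wl"), paste, sep = "_")))
}

#' Extract the Hudgins feature vector of one multi-channel window
#'
#' Concatenates the four features channel-major —
#' `ch1: MAV, ZC, SSC, WL, ch2: ...` — yielding a `4 * n_channels` vector
#' (64 at the default 16 channels). The channel-major layout keeps all
#' features of one sensor in a contiguous block, which is what per-sensor
#' normalisation operates on; the layout is fixed and encoded in the
#' element names.
#'
#' @param window numeric matrix, channels x samples.
#' @param zc_eps,ssc_eps deadbands, see [zero_crossings()].
#' @param n_channels expected channel count.
#' @return a named numeric vector of length `4 * n_channels`.
#' @export
extract_features <- function(window, zc_eps = 0, ssc_eps = 0,
                             n_channels = nrow(window)) {
  if (!is.matrix(window)) stopf("window must be a channels x samples matrix")
  if (nrow(window) != n_channels)
    stopf("window has %d channels; expected %d", nrow(window), n_channels)
  out <- vapply(seq_len(nrow(window)), function(c) {
    v <- window[c, ]
    c(mav(v), zero_crossings(v, zc_eps), slope_sign_changes(v, ssc_eps),
      waveform_length(v))
  }, numeric(4))
  setNames(as.vector(out), feature_names(nrow(window)))
}

#' Hudgins features of every sliding window of a trial
#'
#' Vectorised equivalent of applying [extract_features()] to each window
#' of [slide_windows()]: per-sample indicator series are accumulated with
#' cumulative sums so the cost is linear in the trial length regardless of
#' window overlap. Agrees with the per-window path to machine precision.
#'
#' @param x channels x time matrix (one trial, already filtered).
#' @param wspec a [window_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @param zc_eps,ssc_eps deadbands, see [zero_crossings()].
#' @return a windows x `4 * n_channels` matrix with named columns and the
#'   0-based window offsets in attribute `"starts"`.
#' @export
trial_features <- function(x, wspec = window_spec(), sampling_rate = 2000,
                           zc_eps = 0, ssc_eps = 0) {
  stopifnot(is.matrix(x), inherits(wspec, "window_spec"))
  ws <- window_samples(wspec, sampling_rate)
  w <- ws$w
  T <- ncol(x)
  starts <- window_starts(T, w, ws$s)
  nwin <- length(starts)
  nch <- nrow(x)
  out <- matrix(0, nwin, 4L * nch,
                dimnames = list(NULL, feature_names(nch)))
  for (c in seq_len(nch)) {
    v <- x[c, ]
    ca <- c(0, cumsum(abs(v)))
    dv <- v[-1] - v[-T]
    zi <- as.numeric(v[-T] * v[-1] < 0 & abs(dv) > zc_eps)
    cz <- c(0, cumsum(zi))
    mid <- v[2:(T - 1)]
    si <- as.numeric((mid - v[1:(T - 2)]) * (mid - v[3:T]) > ssc_eps)
    cs <- c(0, cumsum(si))
    cw <- c(0, cumsum(abs(dv)))
    j <- (c - 1L) * 4L
    out[, j + 1L] <- (ca[starts + w + 1L] - ca[starts + 1L]) / w
    out[, j + 2L] <- cz[starts + w] - cz[starts + 1L]
    out[, j + 3L] <- cs[starts + w - 1L] - cs[starts + 1L]
    out[, j + 4L] <- cw[starts + w] - cw[starts + 1L]
  }
  attr(out, "starts") <- starts
  out
}

#' Preprocess a set of trials and extract labelled feature samples
#'
#' Runs the full per-trial chain — band-pass, notch, offset removal,
#' sliding windows, Hudgins features — and stacks the result into one
#' data.frame of labelled feature samples. All windows of a trial inherit
#' the trial's grasp label (recordings contain only the hold phase, so the
#' majority vote over a window is the trial label).
#'
#' @param records list of [trial_record()]s, e.g. from [read_session()] or
#'   [simulate_session_records()].
#' @param fspec a [filter_spec()]; its `sampling_rate` governs windowing.
#' @param wspec a [window_spec()].
#' @param zc_eps,ssc_eps deadbands, see [zero_crossings()].
#' @param zero_phase use forward-backward filtering.
#' @return a data.frame with label columns `participant`, `day`,
#'   `session`, `position`, `grasp`, `trial_id`, `window_start` and one
#'   `chXX_*` column per feature dimension.
#' @export
session_features <- function(records, fspec = filter_spec(),
                             wspec = window_spec(), zc_eps = 0, ssc_eps = 0,
                             zero_phase = FALSE) {
  stopifnot(length(records) > 0)
  feats <- vector("list", length(records))
  labs <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    y <- remove_offset(notch(bandpass(r$emg, fspec, zero_phase), fspec,
                             zero_phase))
    f <- trial_features(y, wspec, fspec$sampling_rate, zc_eps, ssc_eps)
    feats[[i]] <- f
    labs[[i]] <- data.frame(
      participant = r$participant, day = r$day, session = r$session,
      position = r$position, grasp = r$grasp, trial_id = r$trial_id,
      window_start = attr(f, "starts"))
  }
  cbind(do.call(rbind, labs), as.data.frame(do.call(rbind, feats)))
}
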