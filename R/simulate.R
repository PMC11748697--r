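#' Default grasp amplitude profiles
#'
#' Per-grasp, per-channel gain of the band-limited activity. Each of the
#' five active grasps raises a different sector of the 16-electrode
#' forearm ring — a smooth circular bump on a shared activity pedestal —
#' so the six classes are cleanly separable against the within-window
#' estimation noise of the Hudgins features. The bump-to-pedestal ratio is
#' kept moderate on purpose: it sets how strongly grasp identity competes
#' with the position effect, and with very large bumps the nine position
#' classes become wide grasp mixtures that no linear position encoder can
#' carve up. The rest gesture (label 6) is a uniform low-amplitude
#' profile: rest is one of the six classified gestures, not an absence of
#' signal.
#'
#' @param n_channels number of electrodes on the ring.
#' @param pedestal shared baseline gain of all active grasps.
#' @param bump peak height of the grasp-specific bump above the pedestal.
#' @return a 6 x `n_channels` non-negative matrix; rows named by grasp.
#' @export
default_amp_profile <- function(n_channels = 16L, pedestal = 0.6,
                                bump = 0.15) {
  ring_dist <- function(c, center) {
    d <- abs(c - center)
    pmin(d, n_channels - d)
  }
  ch <- seq_len(n_channels) - 1
  centers <- c(0, 3, 6, 9, 12) * n_channels / 16
  widths <- c(1.8, 2.4, 2.0, 2.8, 2.1)
  peaks <- bump * c(1.00, 0.90, 1.10, 0.95, 1.05)
  prof <- t(vapply(1:5, function(g) {
    pedestal + peaks[g] * exp(-0.5 * (ring_dist(ch, centers[g]) / widths[g])^2)
  }, numeric(n_channels)))
  prof <- rbind(prof, rep(0.55 * pedestal, n_channels))
  rownames(prof) <- c("power", "lateral", "pointer", "tripod", "open", "rest")
  prof
}

#' Default position shift pattern
#'
#' Per-position channel-gain modulation emulating the apparent displacement
#' of muscle bellies under the electrode ring when the forearm moves on the
#' 3 x 3 position grid. The pattern is one smooth zero-mean cosine bump
#' over the ring, circularly shifted by `16 * k / 9` channels with
#' `k = 3 * (row - 1) + (col - 1)` indexing the position's grid
#' row/column, so the nine modulations are spread evenly around the ring
#' and no two positions are privileged. The amplitude is capped at 0.9 so
#' channel gains `1 + delta * u` stay strictly positive up to
#' `delta = 1`: arm rotation attenuates a channel, it does not kill it.
#' No physiological fidelity is claimed.
#'
#' @param n_channels number of electrodes on the ring.
#' @return a 9 x `n_channels` matrix with entries in `[-0.9, 0.9]`.
#' @export
default_shift_pattern <- function(n_channels = 16L) {
  u <- matrix(0, 9, n_channels)
  theta <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  for (p in 1:9) {
    row <- (p - 1) %/% 3
    col <- (p - 1) %% 3
    k <- 3 * row + col
    u[p, ] <- 0.9 * cos(theta - 2 * pi * k / 9)
  }
  rownames(u) <- paste0("P", 1:9)
  u
}

#' Default glove posture targets
#'
#' Target values of the 18 uncalibrated glove sensors for each grasp; the
#' simulated glove signal relaxes exponentially from rest towards the
#' row of the prompted grasp. The rest gesture targets the origin.
#'
#' @return a 6 x 18 matrix.
#' @export
default_glove_posture <- function() {
  g <- outer(1:5, 1:18, function(g, s) 0.9 * sin(0.8 * g + 0.37 * s) + 0.1 * g)
  g <- rbind(g, rep(0, 18))
  rownames(g) <- c("power", "lateral", "pointer", "tripod", "open", "rest")
  g
}

#' Simulation parameters for the synthetic EMG generator
#'
#' The signal model for channel c during a hold of grasp y at position z is
#'
#' \deqn{emg_c(t) = (1 + \delta u_{z,c}) A_{y,c} n_c(t)
#'   + a_{pl} \sin(2\pi f_{pl} t + \phi) + dc_c}
#'
#' where `n_c(t)` is unit-variance Gaussian noise band-limited to
#' `noise_band` (filtered with the same Butterworth design used by the
#' preprocessing module), `A` is the grasp amplitude profile, `u` the
#' position shift pattern scaled by the shift magnitude `delta`, and the
#' remaining terms are powerline interference with random phase and a
#' per-channel DC offset. With `shift_magnitude = 0` every position shares
#' one signal distribution per grasp.
#'
#' @param amp_profile grasp x channel non-negative gain matrix with
#'   pairwise-distinct rows.
#' @param shift_magnitude non-negative scalar `delta` scaling the
#'   position effect. The default 0.3 is an arbitrary moderate value: the
#'   magnitude of the real-world position effect is not quantified
#'   anywhere, so this dial only spans qualitative regimes (0 = none,
#'   1 = strong).
#' @param shift_pattern position x channel modulation matrix `u`.
#' @param noise_band two-element Hz vector bounding the EMG noise band.
#' @param powerline_freq powerline frequency in Hz.
#' @param powerline_amp powerline amplitude (same arbitrary units as the
#'   EMG).
#' @param dc_offset per-channel DC offset, recycled to the channel count.
#' @param glove_posture grasp x 18 matrix of glove sensor targets.
#' @param seed integer seed governing all signal randomness.
#' @return an object of class `sim_params`.
#' @export
#' @examples
#' sp <- sim_params(shift_magnitude = 0.5)
#' tr <- simulate_trial(sp, position = 5, grasp = 2, seed = 1)
#' dim(tr$emg)
sim_params <- function(amp_profile = default_amp_profile(),
                       shift_magnitude = 0.3,
                       shift_pattern = default_shift_pattern(),
                       noise_band = c(20, 450),
                       powerline_freq = 50, powerline_amp = 0.1,
                       dc_offset = seq(-0.1, 0.1, length.out = 16),
                       glove_posture = default_glove_posture(),
                       seed = 1L) {
  if (!is.matrix(amp_profile) || any(amp_profile < 0))
    stopf("amp_profile must be a non-negative matrix")
  if (anyDuplicated(amp_profile) > 0)
    warnf("amp_profile has duplicated rows: those grasps are not separable")
  if (!is_number(shift_magnitude) || shift_magnitude < 0)
    stopf("shift_magnitude must be a non-negative number")
  if (!is.matrix(shift_pattern) || ncol(shift_pattern) != ncol(amp_profile))
    stopf("shift_pattern must be a matrix with one column per channel")
  if (length(noise_band) != 2L || noise_band[1] <= 0 ||
      noise_band[1] >= noise_band[2])
    stopf("noise_band must be (low, high) with 0 < low < high")
  if (!is_number(powerline_amp) || powerline_amp < 0)
    stopf("powerline_amp must be non-negative")
  nch <- ncol(amp_profile)
  dc_offset <- rep_len(as.numeric(dc_offset), nch)
  structure(
    list(amp_profile = amp_profile, shift_magnitude = shift_magnitude,
         shift_pattern = shift_pattern, noise_band = as.numeric(noise_band),
         powerline_freq = powerline_freq, powerline_amp = powerline_amp,
         dc_offset = dc_offset, glove_posture = glove_posture,
         n_channels = nch, seed = as.integer(seed)),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("EMG simulation parameters\n")
  cat(sprintf("  %d channels, %d grasp profiles, shift magnitude delta = %g\n",
              x$n_channels, nrow(x$amp_profile), x$shift_magnitude))
  cat(sprintf("  noise band %g-%g Hz; powerline %g Hz (amp %g)\n",
              x$noise_band[1], x$noise_band[2], x$powerline_freq,
              x$powerline_amp))
  invisible(x)
}

## unit-variance band-limited Gaussian noise, T x nch; reuses the
## preprocessing Butterworth so the simulator and the pipeline share one
## filter implementation
band_limited_noise <- function(T, nch, band, sampling_rate, order = 4L) {
  n <- matrix(rnorm(T * nch), T, nch)
  fs <- filter_spec(order = order, low_cutoff = band[1], high_cutoff = band[2],
                    sampling_rate = sampling_rate)
  cf <- butter_coefs(fs)
  n <- iir_filter_cols(cf$b, cf$a, n)
  sds <- sqrt(colMeans(n^2) - colMeans(n)^2)
  list(noise = n, sd = pmax(sds, .Machine$double.eps))
}

#' Simulate one grasp-hold trial
#'
#' Draws the EMG and glove matrices for a single 5 s hold of `grasp` at
#' `position` from the signal model in [sim_params()]. The glove relaxes
#' exponentially (time constant 0.25 s) from rest towards the grasp's
#' posture target, with low-rate sensor noise upsampled to the EMG rate,
#' mirroring how a data glove's native rate is upsampled in the published
#' recordings.
#'
#' @param sp a [sim_params()] object.
#' @param position position label present in `sp$shift_pattern`.
#' @param grasp grasp label present in `sp$amp_profile`.
#' @param seed integer seed; the same seed reproduces the trial bitwise.
#' @param sampling_rate,trial_length recording geometry (Hz, seconds).
#' @return a list with elements `emg` (channels x samples) and `glove`
#'   (18 x samples).
#' @export
simulate_trial <- function(sp, position, grasp, seed,
                           sampling_rate = 2000, trial_length = 5) {
  stopifnot(inherits(sp, "sim_params"))
  if (!is_count(position) || position > nrow(sp$shift_pattern))
    stopf("unknown position label: %s", format(position))
  if (!is_count(grasp) || grasp > nrow(sp$amp_profile))
    stopf("unknown grasp label: %s", format(grasp))
  if (sp$noise_band[2] >= sampling_rate / 2)
    stopf("noise_band upper edge must be below the Nyquist frequency")
  T <- round(sampling_rate * trial_length)
  nch <- sp$n_channels
  withr::with_seed(seed, {
    n <- band_limited_noise(T, nch, sp$noise_band, sampling_rate)
    gain <- (1 + sp$shift_magnitude * sp$shift_pattern[position, ]) *
      sp$amp_profile[grasp, ]
    ## fold the unit-variance normalisation into the channel gains; columns
    ## are channels, so the powerline vector recycles down the time axis
    emg <- sweep(n$noise, 2, gain / n$sd, "*")
    tt <- (seq_len(T) - 1) / sampling_rate
    if (sp$powerline_amp > 0) {
      phi <- runif(1, 0, 2 * pi)
      emg <- emg + sp$powerline_amp * sin(2 * pi * sp$powerline_freq * tt + phi)
    }
    emg <- sweep(emg, 2, sp$dc_offset, "+")

    target <- sp$glove_posture[grasp, ]
    base <- outer(1 - exp(-tt / 0.25), target)
    ## glove sensor noise is drawn at the glove's native rate and linearly
    ## upsampled to the EMG rate, as in the published recordings
    glove_rate <- 100
    nlow <- max(2L, ceiling(trial_length * glove_rate) + 1L)
    gnoise <- matrix(rnorm(nlow * 18L, sd = 0.02), nlow, 18L)
    pos_low <- tt * glove_rate * (nlow - 1) / (trial_length * glove_rate)
    i0 <- pmin(floor(pos_low) + 1L, nlow - 1L)
    frac <- pos_low - (i0 - 1L)
    up <- gnoise[i0, , drop = FALSE] * (1 - frac) +
      gnoise[i0 + 1L, , drop = FALSE] * frac
    list(emg = t(emg), glove = t(base + up))
  })
}

#' Simulate and write all sessions of one participant
#'
#' Runs the full two-day protocol for one synthetic participant: a seeded
#' pseudorandomised schedule per session, per-trial signal draws, and a
#' small seeded multiplicative jitter of the grasp amplitude profiles so
#' participants differ from one another. Each session is written to
#' `out_dir/participantX_dayY_sessionZ` in the published layout via
#' [write_session()].
#'
#' @param config a [protocol_config()].
#' @param sp a [sim_params()] object.
#' @param participant_id positive integer participant label.
#' @param out_dir writable output directory.
#' @param write_glove write `glove_data.hdf5` alongside the EMG.
#' @return invisibly, the session folder paths.
#' @export
simulate_participant <- function(config, sp, participant_id, out_dir,
                                 write_glove = TRUE) {
  stopifnot(inherits(config, "protocol_config"), inherits(sp, "sim_params"))
  if (!is_count(participant_id)) stopf("participant_id must be a positive integer")
  spp <- participant_params(sp, participant_id)
  paths <- character(0)
  for (day in 1:2) {
    for (session in seq_len(config$sessions_per_day)) {
      recs <- simulate_session_records(config, spp, participant_id, day, session)
      params <- recording_parameters(
        trial_length = config$trial_length,
        trials_number = config$trials_per_grasp,
        n_channels = spp$n_channels,
        sampling_rate = config$sampling_rate,
        configuration = if (day == 1) "+" else "x",
        grasp_sequence = unique(paste0(vapply(recs, `[[`, 0L, "grasp"), "@",
                                       vapply(recs, `[[`, 0L, "position"))))
      path <- file.path(out_dir, sprintf("participant%d_day%d_session%d",
                                         participant_id, day, session))
      write_session(path, recs, params, write_glove = write_glove)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

## per-participant amplitude jitter: small seeded multiplicative
## perturbation, clipped at zero
participant_params <- function(sp, participant_id, jitter_sd = 0.05) {
  pseed <- seed_child(sp$seed, 104729L, participant_id)
  amp <- withr::with_seed(pseed, {
    pmax(sp$amp_profile *
           (1 + matrix(rnorm(length(sp$amp_profile), sd = jitter_sd),
                       nrow(sp$amp_profile))), 0)
  })
  spp <- sp
  spp$amp_profile <- amp
  spp
}

#' Simulate one session in memory
#'
#' Generates the full list of [trial_record()]s for one session without
#' touching the disk; used by [simulate_participant()] and convenient for
#' in-memory pipelines.
#'
#' @inheritParams simulate_participant
#' @param day,session session coordinates.
#' @param jitter apply the per-participant amplitude jitter (disable to use
#'   `sp` exactly as given).
#' @return a list of [trial_record()]s.
#' @export
simulate_session_records <- function(config, sp, participant_id, day, session,
                                     jitter = FALSE) {
  if (jitter) sp <- participant_params(sp, participant_id)
  sched <- make_schedule(config, day,
                         seed = seed_child(config$seed, participant_id, day, session))
  recs <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    tr <- simulate_trial(sp, sched$position[i], sched$grasp[i],
                         seed = seed_child(sp$seed, participant_id, day, session, i),
                         sampling_rate = config$sampling_rate,
                         trial_length = config$trial_length)
    recs[[i]] <- trial_record(participant_id, day, session, i,
                              sched$position[i], sched$grasp[i],
                              sched$trial_no[i], sched$block_no[i],
                              tr$emg, tr$glove, n_channels = sp$n_channels)
  }
  recs
}
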