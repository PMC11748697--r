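#' Acquisition-protocol configuration
#'
#' Describes one recording campaign: 5 s grasp holds sampled at 2 kHz, five
#' repetitions (trials) of each of six grasps (power, lateral, pointer,
#' tripod, open, rest) at each scheduled forearm position, two sessions per
#' day over two days. Day 1 uses the plus-shaped position set
#' `{2, 4, 5, 6, 8}` and day 2 the cross-shaped set `{1, 3, 5, 7, 9}` on the
#' 3 x 3 position grid; the neutral position 5 is the only one shared
#' between days.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param trial_length length of the recorded grasp hold in seconds.
#' @param trials_per_grasp repetitions of each (grasp, position) pair.
#' @param grasps integer grasp labels, a subset of `1:6`.
#' @param positions_day1,positions_day2 integer position labels for each
#'   day, subsets of `1:9`.
#' @param sessions_per_day number of recording sessions per day.
#' @param seed integer seed governing schedule permutations.
#' @return an object of class `protocol_config`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' cfg
protocol_config <- function(sampling_rate = 2000, trial_length = 5,
                            trials_per_grasp = 5, grasps = 1:6,
                            positions_day1 = c(2, 4, 5, 6, 8),
                            positions_day2 = c(1, 3, 5, 7, 9),
                            sessions_per_day = 2, seed = 1L) {
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be a positive number")
  if (!is_number(trial_length) || trial_length <= 0)
    stopf("trial_length must be a positive number")
  if (!is_count(trials_per_grasp)) stopf("trials_per_grasp must be a positive integer")
  if (!is_count(sessions_per_day)) stopf("sessions_per_day must be a positive integer")
  grasps <- as.integer(grasps)
  if (length(grasps) == 0L || anyDuplicated(grasps) || !all(grasps %in% 1:6))
    stopf("grasps must be a non-empty subset of 1:6 without duplicates")
  for (nm in c("positions_day1", "positions_day2")) {
    p <- as.integer(get(nm))
    if (length(p) == 0L || anyDuplicated(p) || !all(p %in% 1:9))
      stopf("%s must be a non-empty subset of 1:9 without duplicates", nm)
    assign(nm, p)
  }
  structure(
    list(sampling_rate = sampling_rate, trial_length = trial_length,
         trials_per_grasp = as.integer(trials_per_grasp), grasps = sort(grasps),
         positions_day1 = sort(positions_day1),
         positions_day2 = sort(positions_day2),
         sessions_per_day = as.integer(sessions_per_day),
         seed = as.integer(seed)),
    class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Acquisition protocol\n")
  cat(sprintf("  %g Hz, %g s trials, %d trials per (grasp, position)\n",
              x$sampling_rate, x$trial_length, x$trials_per_grasp))
  cat(sprintf("  grasps: {%s}\n", paste(x$grasps, collapse = ", ")))
  cat(sprintf("  day 1 positions: {%s}   day 2 positions: {%s}\n",
              paste(x$positions_day1, collapse = ", "),
              paste(x$positions_day2, collapse = ", ")))
  cat(sprintf("  %d session(s) per day; %d trials per session\n",
              x$sessions_per_day,
              length(x$positions_day1) * length(x$grasps) * x$trials_per_grasp))
  invisible(x)
}

protocol_positions <- function(config, day) {
  if (!is_count(day) || !(day %in% c(1L, 2L))) stopf("day must be 1 or 2")
  if (day == 1) config$positions_day1 else config$positions_day2
}

#' Build a pseudorandomised trial schedule for one session
#'
#' Trials are organised in blocks of `trials_per_grasp` consecutive
#' repetitions of one (position, grasp) pair; every pair of the day's
#' position set with every grasp occupies exactly one block, and the order
#' of blocks is a seeded permutation, mimicking the pseudorandomised grasp
#' sequence used between subjects.
#'
#' @param config a [protocol_config()].
#' @param day recording day, 1 or 2.
#' @param seed integer seed for the block permutation.
#' @return a data.frame with columns `position`, `grasp`, `trial_no`
#'   (0-based repetition within the block) and `block_no` (0-based block
#'   index).
#' @export
#' @examples
#' sched <- make_schedule(protocol_config(), day = 1, seed = 7)
#' nrow(sched)      # 150
#' table(sched$position, sched$grasp)
make_schedule <- function(config, day, seed = config$seed) {
  stopifnot(inherits(config, "protocol_config"))
  positions <- protocol_positions(config, day)
  blocks <- expand.grid(grasp = config$grasps, position = positions,
                        KEEP.OUT.ATTRS = FALSE)
  ord <- withr::with_seed(seed, sample.int(nrow(blocks)))
  blocks <- blocks[ord, , drop = FALSE]
  tpg <- config$trials_per_grasp
  data.frame(
    position = rep(blocks$position, each = tpg),
    grasp = rep(blocks$grasp, each = tpg),
    trial_no = rep.int(seq_len(tpg) - 1L, nrow(blocks)),
    block_no = rep(seq_len(nrow(blocks)) - 1L, each = tpg))
}

#' Construct a single-trial record
#'
#' One record holds the raw signals and labels of one 5 s grasp hold: a
#' 16 x T EMG matrix, an optional 18 x T data-glove matrix, and the
#' provenance labels used throughout the experiments.
#'
#' @param participant,day,session,trial_id,position,grasp,trial_no,block_no
#'   integer labels; `trial_id` is 1-based within the session, `trial_no`
#'   and `block_no` are 0-based as in the published labelling files.
#' @param emg numeric matrix, channels x samples.
#' @param glove numeric matrix with 18 rows, or `NULL` when glove data are
#'   absent.
#' @param n_channels expected number of EMG rows.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(participant, day, session, trial_id, position,
                         grasp, trial_no, block_no, emg, glove = NULL,
                         n_channels = 16L) {
  if (!is.matrix(emg) || !is.numeric(emg))
    stopf("trial %s: emg must be a numeric matrix", trial_id)
  if (nrow(emg) != n_channels)
    stopf("trial %s: EMG matrix has %d rows; expected %d channels",
          trial_id, nrow(emg), n_channels)
  if (!is.null(glove)) {
    if (!is.matrix(glove) || nrow(glove) != 18L)
      stopf("trial %s: glove matrix must have 18 rows", trial_id)
  }
  structure(
    list(participant = as.integer(participant), day = as.integer(day),
         session = as.integer(session), trial_id = as.integer(trial_id),
         position = as.integer(position), grasp = as.integer(grasp),
         trial_no = as.integer(trial_no), block_no = as.integer(block_no),
         emg = emg, glove = glove),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "Trial %d (participant %d, day %d, session %d): grasp %d at position %d\n",
    x$trial_id, x$participant, x$day, x$session, x$grasp, x$position))
  cat(sprintf("  emg %d x %d; glove %s\n", nrow(x$emg), ncol(x$emg),
              if (is.null(x$glove)) "absent"
              else sprintf("%d x %d", nrow(x$glove), ncol(x$glove))))
  invisible(x)
}
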