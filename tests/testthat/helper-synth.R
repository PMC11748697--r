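# Shared synthetic fixtures, generated once per test run and cached.
# Trial lengths are far below the protocol's 5 s so the suite stays fast;
# the windowing geometry (128 ms / 50 ms at 2 kHz) is unchanged, so every
# pipeline property is exercised on the real window count formula.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_config <- function(trial_length = 0.5, sessions_per_day = 1, seed = 1L) {
  protocol_config(trial_length = trial_length,
                  sessions_per_day = sessions_per_day, seed = seed)
}

## quiet simulation params: no powerline, no offset, so tests that reason
## about amplitudes alone are not confounded
quiet_params <- function(delta = 0.3, seed = 1L) {
  sim_params(shift_magnitude = delta, powerline_amp = 0, dc_offset = 0,
             seed = seed)
}

## features of one or more participants for the given days
synth_features <- function(participants = 1L, days = 1L, delta = 0.3,
                           trial_length = 0.5, sessions_per_day = 1,
                           seed = 1L, sp = NULL, jitter = TRUE) {
  cfg <- small_config(trial_length, sessions_per_day, seed = seed)
  if (is.null(sp)) sp <- quiet_params(delta, seed = seed)
  fs <- filter_spec(sampling_rate = cfg$sampling_rate)
  out <- list()
  for (p in participants) {
    spp <- sp
    for (d in days) {
      for (s in seq_len(cfg$sessions_per_day)) {
        recs <- simulate_session_records(cfg, spp, p, day = d, session = s,
                                         jitter = jitter)
        out[[length(out) + 1L]] <- session_features(recs, fs)
      }
    }
  }
  do.call(rbind, out)
}

## one small day-1 feature table reused across experiment tests
day1_features <- function() {
  cached("day1_features",
         synth_features(participants = 1L, days = 1L, delta = 0.3, seed = 11L))
}

## a tiny session of full-shape records for IO tests
tiny_session_records <- function(seed = 5L, participant = 1L, day = 1L,
                                 session = 1L) {
  cfg <- protocol_config(trial_length = 0.1, trials_per_grasp = 1,
                         grasps = 1:3,
                         positions_day1 = c(2, 5), positions_day2 = c(1, 5),
                         seed = seed)
  simulate_session_records(cfg, quiet_params(seed = seed), participant,
                           day = day, session = session)
}
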