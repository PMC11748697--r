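# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Derive a reproducible child seed
#'
#' Folds a sequence of small integers (participant, day, session, trial
#' indices and the like) into a base seed with a Lehmer-style step, so every
#' unit of the simulation gets its own stable RNG stream while the whole run
#' is governed by a single user-facing seed. All arithmetic stays below
#' 2^53, so results are exact in double precision, and the returned value is
#' a valid 32-bit seed.
#'
#' @param seed integer base seed.
#' @param ... integers identifying the child stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' seed_child(1, 3, 2, 1)
seed_child <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed %% m)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

## feature-column bookkeeping: session feature tables carry label columns
## next to the 4 * n_channels feature columns named chXX_<feat>
feature_cols <- function(df) grep("^ch[0-9]+_", names(df), value = TRUE)

feature_matrix <- function(df) {
  cols <- feature_cols(df)
  if (length(cols) == 0L) stopf("no feature columns (chXX_*) found")
  as.matrix(df[, cols, drop = FALSE])
}
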