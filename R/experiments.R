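#' Stratified trial-wise cross-validation folds
#'
#' Splits whole trials — never individual windows — into `n_folds` folds,
#' stratified so every stratum (typically the grasp label) is spread as
#' evenly as possible across folds. With the protocol's five repetitions
#' per (grasp, position) and the default five folds, each fold tests
#' exactly one trial per stratum, i.e. an 80:20 trial split per fold.
#' Keeping all windows of a trial on one side of the split is the leakage
#' guard: windows of one hold are strongly correlated.
#'
#' @param trial_ids vector of unique trial identifiers.
#' @param strata stratification label per trial (same length).
#' @param n_folds number of folds, at least 2.
#' @param seed integer seed for the shuffling.
#' @return a list of `n_folds` lists with elements `train` and `test`;
#'   the test sets partition `trial_ids`.
#' @export
#' @examples
#' folds <- trial_cv_split(1:30, rep(1:6, each = 5), n_folds = 5, seed = 1)
#' lengths(lapply(folds, `[[`, "test"))  # 6 trials per fold, one per grasp
trial_cv_split <- function(trial_ids, strata, n_folds = 5L, seed = 1L) {
  if (!is_count(n_folds, min = 2L)) stopf("n_folds must be an integer >= 2")
  if (anyDuplicated(trial_ids)) stopf("trial_ids must be unique")
  if (length(trial_ids) != length(strata))
    stopf("trial_ids and strata disagree in length")
  counts <- table(strata)
  if (any(counts < n_folds))
    stopf("every stratum needs at least %d trials (smallest has %d)",
          n_folds, min(counts))
  ## canonical order first, so the assignment is invariant to how the
  ## caller happened to order the trials
  ord <- order(trial_ids)
  trial_ids <- trial_ids[ord]
  strata <- strata[ord]
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(trial_ids))
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  lapply(seq_len(n_folds), function(k) {
    list(train = trial_ids[fold_of != k], test = trial_ids[fold_of == k])
  })
}

## shared train/test evaluation: z-score fitted on the training windows
## only, LDA on the normalised features, accuracy on the test windows
fit_eval <- function(train_x, train_y, test_x, test_y, ridge = NULL) {
  zs <- zscore_fit(train_x)
  fit <- emg_lda(zscore_apply(train_x, zs), train_y, ridge = ridge)
  pred <- predict(fit, zscore_apply(test_x, zs))
  mean(pred == test_y)
}

split_sessions <- function(features) {
  key <- interaction(features$participant, features$day, features$session,
                     drop = TRUE)
  split(seq_len(nrow(features)), key)
}

experiment_result <- function(scenario, per_subject, extras = list()) {
  structure(
    list(scenario = scenario, per_subject = per_subject,
         mean = mean(per_subject), sd = sd(per_subject), extras = extras),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %s\n", x$scenario))
  cat(sprintf("  accuracy %.3f (sd %.3f across %d subject(s))\n",
              x$mean, x$sd, length(x$per_subject)))
  if (!is.null(x$extras$matrix)) {
    cat("  source x target accuracy matrix:\n")
    print(round(x$extras$matrix, 3))
    cat("  OVR (train one position, test pooled rest):\n")
    print(round(x$extras$ovr, 3))
  }
  if (!is.null(x$extras$per_grasp)) {
    cat("  per-grasp position-classification accuracy:\n")
    print(round(x$extras$per_grasp, 3))
  }
  invisible(x)
}

#' Within-position grasp classification
#'
#' The standard decoding scenario: for one arm position, an independent
#' classifier decodes the six grasps with stratified 5-fold trial-wise
#' cross-validation, separately per subject and session; session
#' accuracies are averaged into one value per subject and then across
#' subjects.
#'
#' @param features a labelled feature data.frame from
#'   [session_features()], possibly spanning several subjects/sessions.
#' @param position the position label to evaluate.
#' @param n_folds folds for [trial_cv_split()].
#' @param seed integer seed; fold assignment is derived per
#'   (subject, session, position) so results do not depend on row order.
#' @param ridge LDA regulariser, see [emg_lda()].
#' @return an `experiment_result` with per-subject accuracies.
#' @export
within_position <- function(features, position, n_folds = 5L, seed = 1L,
                            ridge = NULL) {
  sub <- features[features$position == position, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("no data at position %s", format(position))
  x <- feature_matrix(sub)
  acc <- data.frame(participant = integer(), acc = numeric())
  for (idx in split_sessions(sub)) {
    p <- sub$participant[idx[1]]; d <- sub$day[idx[1]]; s <- sub$session[idx[1]]
    tid <- sub$trial_id[idx]
    trials <- !duplicated(tid)
    if (length(unique(sub$grasp[idx])) < 2L)
      stopf("need at least 2 grasp classes at position %s", format(position))
    folds <- trial_cv_split(tid[trials], sub$grasp[idx][trials], n_folds,
                            seed = seed_child(seed, p, d, s, position))
    fold_acc <- vapply(folds, function(f) {
      tr <- idx[tid %in% f$train]; te <- idx[tid %in% f$test]
      fit_eval(x[tr, , drop = FALSE], sub$grasp[tr],
               x[te, , drop = FALSE], sub$grasp[te], ridge)
    }, numeric(1))
    acc <- rbind(acc, data.frame(participant = p, acc = mean(fold_acc)))
  }
  per_subject <- tapply(acc$acc, acc$participant, mean)
  experiment_result("within_position", per_subject,
                    extras = list(position = position, per_session = acc))
}

#' Cross-position transfer matrix
#'
#' Naive transfer: for every ordered pair of positions in one
#' configuration, an LDA is trained on the source position's training
#' trials (its 80% portion, so the diagonal is comparable to the
#' off-diagonal cells) and tested on the target position's held-out
#' trials. The diagonal therefore reproduces [within_position()] on the
#' same folds. The OVR column trains on one position and tests on the
#' pooled held-out windows of the remaining positions of the configuration
#' (micro average). Cells are averaged over folds, sessions and subjects.
#'
#' @inheritParams within_position
#' @param positions position labels of the configuration; defaults to all
#'   positions present in `features`. Every session must contain them all.
#' @return an `experiment_result`; `extras$matrix` holds the mean source x
#'   target accuracy matrix, `extras$matrix_sd` its across-subject spread,
#'   `extras$ovr`/`extras$ovr_sd` the OVR column, and
#'   `extras$per_subject_matrix` the per-subject matrices.
#' @export
transfer_matrix <- function(features, positions = NULL, n_folds = 5L,
                            seed = 1L, ridge = NULL) {
  if (is.null(positions)) positions <- sort(unique(features$position))
  np <- length(positions)
  if (np < 2L) stopf("need at least 2 positions for a transfer matrix")
  features <- features[features$position %in% positions, , drop = FALSE]
  x <- feature_matrix(features)
  pn <- paste0("P", positions)
  sess_mats <- list(); sess_ovr <- list(); sess_part <- integer(0)

  for (idx in split_sessions(features)) {
    p <- features$participant[idx[1]]; d <- features$day[idx[1]]
    s <- features$session[idx[1]]
    if (!all(positions %in% features$position[idx]))
      stopf("subject %d day %d session %d lacks some of the positions",
            p, d, s)
    ## per-position fold assignment, stratified by grasp
    fold_rows <- lapply(positions, function(pos) {
      pid <- idx[features$position[idx] == pos]
      tid <- features$trial_id[pid]
      trials <- !duplicated(tid)
      folds <- trial_cv_split(tid[trials], features$grasp[pid][trials],
                              n_folds, seed = seed_child(seed, p, d, s, pos))
      lapply(folds, function(f)
        list(train = pid[tid %in% f$train], test = pid[tid %in% f$test]))
    })
    mat <- matrix(0, np, np, dimnames = list(pn, pn))
    ovr <- setNames(numeric(np), pn)
    for (k in seq_len(n_folds)) {
      for (si in seq_len(np)) {
        tr <- fold_rows[[si]][[k]]$train
        zs <- zscore_fit(x[tr, , drop = FALSE])
        fit <- emg_lda(zscore_apply(x[tr, , drop = FALSE], zs),
                       features$grasp[tr], ridge = ridge)
        pooled_ok <- 0; pooled_n <- 0
        for (ti in seq_len(np)) {
          te <- fold_rows[[ti]][[k]]$test
          pred <- predict(fit, zscore_apply(x[te, , drop = FALSE], zs))
          ok <- sum(pred == features$grasp[te])
          mat[si, ti] <- mat[si, ti] + ok / length(te)
          if (ti != si) {
            pooled_ok <- pooled_ok + ok
            pooled_n <- pooled_n + length(te)
          }
        }
        ovr[si] <- ovr[si] + pooled_ok / pooled_n
      }
    }
    sess_mats <- c(sess_mats, list(mat / n_folds))
    sess_ovr <- c(sess_ovr, list(ovr / n_folds))
    sess_part <- c(sess_part, p)
  }

  subjects <- sort(unique(sess_part))
  subj_mats <- lapply(subjects, function(pp)
    Reduce(`+`, sess_mats[sess_part == pp]) / sum(sess_part == pp))
  subj_ovr <- lapply(subjects, function(pp)
    Reduce(`+`, sess_ovr[sess_part == pp]) / sum(sess_part == pp))
  mean_mat <- Reduce(`+`, subj_mats) / length(subjects)
  sd_mat <- apply(simplify2array(subj_mats), c(1, 2), sd)
  mean_ovr <- Reduce(`+`, subj_ovr) / length(subjects)
  sd_ovr <- apply(do.call(rbind, subj_ovr), 2, sd)
  per_subject <- setNames(vapply(subj_mats, mean, numeric(1)), subjects)
  experiment_result(
    "transfer_matrix", per_subject,
    extras = list(matrix = mean_mat, matrix_sd = sd_mat, ovr = mean_ovr,
                  ovr_sd = sd_ovr, positions = positions,
                  per_subject_matrix = setNames(subj_mats, subjects),
                  per_subject_ovr = setNames(subj_ovr, subjects)))
}

#' Position classification within each grasp
#'
#' Turns the question around: holding the grasp fixed, how classifiable is
#' the arm position from the EMG features alone? For every grasp an LDA
#' decodes the configuration's positions with stratified trial-wise
#' cross-validation, per subject and session; accuracies are averaged as
#' in the other scenarios.
#'
#' @inheritParams within_position
#' @param grasps the grasp labels that must all be present.
#' @return an `experiment_result`; `extras$per_grasp` is the named
#'   per-grasp accuracy vector, `extras$per_grasp_sd` its across-subject
#'   spread, `extras$per_subject_grasp` the subject x grasp matrix.
#' @export
position_per_grasp <- function(features, grasps = 1:6, n_folds = 5L,
                               seed = 1L, ridge = NULL) {
  missing_g <- setdiff(grasps, unique(features$grasp))
  if (length(missing_g) > 0L)
    stopf("grasp %s missing from the feature set",
          paste(missing_g, collapse = ", "))
  x <- feature_matrix(features)
  rows <- data.frame(participant = integer(), grasp = integer(),
                     acc = numeric())
  for (idx in split_sessions(features)) {
    p <- features$participant[idx[1]]; d <- features$day[idx[1]]
    s <- features$session[idx[1]]
    for (g in grasps) {
      gid <- idx[features$grasp[idx] == g]
      if (length(gid) == 0L)
        stopf("grasp %s missing from subject %d day %d session %d",
              format(g), p, d, s)
      if (length(unique(features$position[gid])) < 2L)
        stopf("need at least 2 positions to classify (grasp %s)", format(g))
      tid <- features$trial_id[gid]
      trials <- !duplicated(tid)
      folds <- trial_cv_split(tid[trials], features$position[gid][trials],
                              n_folds, seed = seed_child(seed, p, d, s, g))
      fold_acc <- vapply(folds, function(f) {
        tr <- gid[tid %in% f$train]; te <- gid[tid %in% f$test]
        fit_eval(x[tr, , drop = FALSE], features$position[tr],
                 x[te, , drop = FALSE], features$position[te], ridge)
      }, numeric(1))
      rows <- rbind(rows, data.frame(participant = p, grasp = g,
                                     acc = mean(fold_acc)))
    }
  }
  subj_grasp <- tapply(rows$acc, list(rows$participant, rows$grasp), mean)
  per_grasp <- colMeans(subj_grasp)
  per_grasp_sd <- apply(subj_grasp, 2, sd)
  experiment_result(
    "position_per_grasp", rowMeans(subj_grasp),
    extras = list(per_grasp = per_grasp, per_grasp_sd = per_grasp_sd,
                  per_subject_grasp = subj_grasp))
}
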