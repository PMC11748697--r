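#' Merge both configurations into the nine-position dataset
#'
#' The hierarchical classifier is trained on data from all nine positions
#' across both configurations. The neutral position 5 is recorded on both
#' days; it is taken from only one configuration (`"+"` = day 1 by
#' default, since that is the first time it is recorded) so no position is
#' represented twice.
#'
#' @param features labelled feature data.frame spanning both days.
#' @param position5_source configuration whose position-5 trials are kept:
#'   `"+"` (day 1) or `"x"` (day 2).
#' @return the filtered feature data.frame, carrying the choice in
#'   attribute `"position5_source"`.
#' @export
assemble_hmc_dataset <- function(features, position5_source = c("+", "x")) {
  position5_source <- match.arg(position5_source)
  keep_day <- if (position5_source == "+") 1L else 2L
  drop <- features$position == 5L & features$day != keep_day
  out <- features[!drop, , drop = FALSE]
  missing <- setdiff(1:9, unique(out$position))
  if (length(missing) > 0L)
    stopf("positions missing from the merged dataset: %s",
          paste(missing, collapse = ", "))
  attr(out, "position5_source") <- position5_source
  out
}

z_feature <- function(z, encoding, positions = 1:9) {
  if (encoding == "scalar") {
    matrix((z - 1) / 8, ncol = 1, dimnames = list(NULL, "z_norm"))
  } else {
    m <- matrix(0, length(z), length(positions),
                dimnames = list(NULL, paste0("z", positions)))
    m[cbind(seq_along(z), match(z, positions))] <- 1
    m
  }
}

#' Fit the hierarchical multi-label classifier
#'
#' Two-level hierarchy: a position encoder `E_p` (parent node) is fitted
#' on `(x, z)` pairs over all nine positions, and nine grasp encoders
#' `E_g:n` (leaf nodes) are fitted on position-augmented features
#' `x + norm(z)` grouped by the ground-truth position `z = n`, so each
#' leaf sees only its own position's samples during training. The
#' augmentation `norm(z) = (z - 1) / 8` is a scalar min-max mapping of the
#' position label to `[0, 1]` (the default); a one-hot encoding is
#' available via `z_encoding = "onehot"`. All encoders share the LDA
#' engine and ridge of [emg_lda()], and the z-score statistics are fitted
#' on the training windows only.
#'
#' @param x numeric feature matrix, samples x dimensions (raw, not yet
#'   normalised).
#' @param y grasp labels.
#' @param z position labels.
#' @param positions,grasps the label sets that must all be present in the
#'   training data.
#' @param z_encoding `"scalar"` or `"onehot"` position augmentation.
#' @param ridge LDA regulariser, see [emg_lda()].
#' @return an object of class `hmc` with the position encoder, one grasp
#'   encoder per position, and the shared normalisation statistics.
#' @export
hmc <- function(x, y, z, positions = 1:9, grasps = 1:6,
                z_encoding = c("scalar", "onehot"), ridge = NULL) {
  z_encoding <- match.arg(z_encoding)
  x <- as.matrix(x)
  if (nrow(x) != length(y) || nrow(x) != length(z))
    stopf("x, y and z disagree on the sample count")
  mp <- setdiff(positions, unique(z))
  if (length(mp) > 0L)
    stopf("positions missing from training data: %s",
          paste(mp, collapse = ", "))
  mg <- setdiff(grasps, unique(y))
  if (length(mg) > 0L)
    stopf("grasps missing from training data: %s", paste(mg, collapse = ", "))
  zstats <- zscore_fit(x)
  xn <- zscore_apply(x, zstats)
  position_encoder <- emg_lda(xn, z, ridge = ridge)
  grasp_encoders <- setNames(vector("list", length(positions)),
                             as.character(positions))
  for (n in positions) {
    idx <- which(z == n)
    gm <- setdiff(grasps, unique(y[idx]))
    if (length(gm) > 0L)
      stopf("position %d lacks grasps: %s", n, paste(gm, collapse = ", "))
    aug <- cbind(xn[idx, , drop = FALSE],
                 z_feature(rep(n, length(idx)), z_encoding, positions))
    grasp_encoders[[as.character(n)]] <- emg_lda(aug, y[idx], ridge = ridge)
  }
  structure(
    list(position_encoder = position_encoder,
         grasp_encoders = grasp_encoders, zstats = zstats,
         positions = positions, grasps = grasps, z_encoding = z_encoding,
         input_dim = ncol(x)),
    class = "hmc")
}

#' @export
print.hmc <- function(x, ...) {
  cat("Hierarchical multi-label classifier\n")
  cat(sprintf(
    "  position encoder over {%s}; %d grasp encoders over {%s}\n",
    paste(x$positions, collapse = ","), length(x$grasp_encoders),
    paste(x$grasps, collapse = ",")))
  cat(sprintf("  input dim %d; augmentation: %s (leaf input dim %d)\n",
              x$input_dim, x$z_encoding,
              nrow(x$grasp_encoders[[1]]$weights)))
  invisible(x)
}

#' @export
summary.hmc <- function(object, ...) {
  print(object)
  cat("  position encoder:\n")
  print(object$position_encoder)
  invisible(object)
}

#' Predict grasp and position through the hierarchy
#'
#' Inference follows the hierarchy constraint: the position encoder first
#' predicts `z'`, the sample is augmented with `norm(z')` and routed to
#' the grasp encoder of its predicted parent, `E_g:z'`, which produces
#' `y'`. The encoder that produced each grasp prediction is recorded so
#' hierarchy coherence can be audited. `route = "true"` is an oracle
#' variant that routes by the ground-truth position instead (the metric in
#' the soft evaluation does not change the routing; this flag exists for
#' comparison only).
#'
#' @param object an [hmc()] fit.
#' @param newdata numeric feature matrix (raw, samples x dimensions).
#' @param route `"predicted"` (default, hierarchy-coherent) or `"true"`.
#' @param z ground-truth positions, required when `route = "true"`.
#' @param ... unused.
#' @return a data.frame with columns `y_pred`, `z_pred` and `encoder`
#'   (the position label of the grasp encoder that produced `y_pred`).
#' @export
predict.hmc <- function(object, newdata, route = c("predicted", "true"),
                        z = NULL, ...) {
  route <- match.arg(route)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stopf("newdata has %d dimensions; model expects %d", ncol(newdata),
          object$input_dim)
  xn <- zscore_apply(newdata, object$zstats)
  z_pred <- predict(object$position_encoder, xn)
  zr <- if (route == "true") {
    if (is.null(z)) stopf("route = \"true\" needs the ground-truth z")
    z
  } else z_pred
  y_pred <- rep(object$grasps[1], nrow(xn))
  encoder <- integer(nrow(xn))
  for (n in unique(zr)) {
    idx <- which(zr == n)
    aug <- cbind(xn[idx, , drop = FALSE],
                 z_feature(rep(n, length(idx)), object$z_encoding,
                           object$positions))
    y_pred[idx] <- predict(object$grasp_encoders[[as.character(n)]], aug)
    encoder[idx] <- n
  }
  data.frame(y_pred = y_pred, z_pred = z_pred, encoder = encoder)
}

#' Strict and soft multi-label accuracy
#'
#' Strict accuracy counts a sample as correct only when both the grasp and
#' the position prediction match the truth; soft accuracy freezes the
#' position constraint and counts grasp correctness alone, on the same
#' predictions. Consequently `strict <= soft` and `strict <=` the position
#' encoder's accuracy, always.
#'
#' @param predictions a data.frame from [predict.hmc()].
#' @param y,z ground-truth grasp and position labels.
#' @return a single accuracy in `[0, 1]`.
#' @export
hmc_accuracy <- function(predictions, y, z) {
  if (nrow(predictions) == 0L) stopf("empty prediction set")
  mean(predictions$y_pred == y & predictions$z_pred == z)
}

#' @rdname hmc_accuracy
#' @export
soft_accuracy <- function(predictions, y) {
  if (nrow(predictions) == 0L) stopf("empty prediction set")
  mean(predictions$y_pred == y)
}

#' Run the full hierarchical-classification experiment
#'
#' Per subject, the merged nine-position dataset is split by whole trials
#' into stratified cross-validation folds (stratum = position x grasp, so
#' every fold's training part contains all 54 strata); per fold an [hmc()]
#' is fitted on the training trials and evaluated on the held-out trials.
#' Reported are per-true-position strict and soft accuracies, the overall
#' strict/soft accuracies, and the position-encoder accuracy — fold means
#' per subject, then mean and across-subject spread. Hierarchy coherence
#' (every grasp prediction produced by the encoder of its predicted
#' parent) is audited on every prediction.
#'
#' @param features labelled feature data.frame spanning both days (it is
#'   passed through [assemble_hmc_dataset()]).
#' @param position5_source see [assemble_hmc_dataset()].
#' @param n_folds cross-validation folds.
#' @param seed integer seed.
#' @param z_encoding,ridge passed to [hmc()].
#' @return an object of class `hmc_report`.
#' @export
hmc_report <- function(features, position5_source = "+", n_folds = 5L,
                       seed = 1L, z_encoding = "scalar", ridge = NULL) {
  merged <- assemble_hmc_dataset(features, position5_source)
  x <- feature_matrix(merged)
  subjects <- sort(unique(merged$participant))
  positions <- 1:9
  subj <- list()
  routing_violations <- 0L
  for (p in subjects) {
    idx <- which(merged$participant == p)
    uid <- paste(merged$day[idx], merged$session[idx], merged$trial_id[idx],
                 sep = "/")
    trials <- !duplicated(uid)
    strat <- paste(merged$position[idx], merged$grasp[idx])
    folds <- trial_cv_split(uid[trials], strat[trials], n_folds,
                            seed = seed_child(seed, p))
    fold_stats <- vector("list", n_folds)
    for (k in seq_len(n_folds)) {
      tr <- idx[uid %in% folds[[k]]$train]
      te <- idx[uid %in% folds[[k]]$test]
      fit <- hmc(x[tr, , drop = FALSE], merged$grasp[tr],
                 merged$position[tr], positions = positions,
                 z_encoding = z_encoding, ridge = ridge)
      pred <- predict(fit, x[te, , drop = FALSE])
      routing_violations <- routing_violations +
        sum(pred$encoder != pred$z_pred)
      yt <- merged$grasp[te]; zt <- merged$position[te]
      per_pos <- t(vapply(positions, function(n) {
        sel <- zt == n
        c(strict = mean(pred$y_pred[sel] == yt[sel] &
                          pred$z_pred[sel] == zt[sel]),
          soft = mean(pred$y_pred[sel] == yt[sel]))
      }, numeric(2)))
      fold_stats[[k]] <- list(
        per_pos = per_pos,
        strict = hmc_accuracy(pred, yt, zt),
        soft = soft_accuracy(pred, yt),
        ep = mean(pred$z_pred == zt))
    }
    subj[[as.character(p)]] <- list(
      per_pos = Reduce(`+`, lapply(fold_stats, `[[`, "per_pos")) / n_folds,
      strict = mean(vapply(fold_stats, `[[`, 0, "strict")),
      soft = mean(vapply(fold_stats, `[[`, 0, "soft")),
      ep = mean(vapply(fold_stats, `[[`, 0, "ep")))
  }
  agg <- function(field) {
    v <- vapply(subj, `[[`, 0, field)
    c(mean = mean(v), sd = sd(v))
  }
  pos_arr <- simplify2array(lapply(subj, `[[`, "per_pos"))
  per_position <- data.frame(
    position = positions,
    strict = apply(pos_arr[, "strict", , drop = FALSE], 1, mean),
    strict_sd = apply(pos_arr[, "strict", , drop = FALSE], 1, sd),
    soft = apply(pos_arr[, "soft", , drop = FALSE], 1, mean),
    soft_sd = apply(pos_arr[, "soft", , drop = FALSE], 1, sd))
  structure(
    list(per_position = per_position,
         strict_overall = agg("strict"), soft_overall = agg("soft"),
         ep_accuracy = agg("ep"),
         per_subject = subj, routing_violations = routing_violations,
         position5_source = attr(merged, "position5_source"),
         n_folds = n_folds, subjects = subjects),
    class = "hmc_report")
}

#' @export
print.hmc_report <- function(x, ...) {
  cat("Hierarchical multi-label classification\n")
  cat(sprintf(
    "  %d subject(s), %d folds; position 5 drawn from configuration %s\n",
    length(x$subjects), x$n_folds, x$position5_source))
  cat(sprintf("  position encoder accuracy: %.3f (sd %.3f)\n",
              x$ep_accuracy["mean"], x$ep_accuracy["sd"]))
  cat(sprintf("  strict accuracy: %.3f (sd %.3f)   soft accuracy: %.3f (sd %.3f)\n",
              x$strict_overall["mean"], x$strict_overall["sd"],
              x$soft_overall["mean"], x$soft_overall["sd"]))
  cat(sprintf("  hierarchy-coherence violations: %d\n", x$routing_violations))
  cat("  per true position (strict | soft):\n")
  p <- x$per_position
  for (i in seq_len(nrow(p)))
    cat(sprintf("    P%d: %.2f (sd %.2f) | %.2f (sd %.2f)\n", p$position[i],
                p$strict[i], p$strict_sd[i], p$soft[i], p$soft_sd[i]))
  invisible(x)
}
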