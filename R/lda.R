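#' Regularised linear discriminant classifier
#'
#' Fits the Gaussian equal-covariance linear discriminant used by every
#' decoding experiment in the package: class means, pooled within-class
#' covariance `S_w / (n - k)`, empirical class priors, and discriminant
#' scores
#' \deqn{\delta_k(x) = x^T \Sigma^{-1} \mu_k
#'   - \tfrac12 \mu_k^T \Sigma^{-1} \mu_k + \log \pi_k}
#' with \eqn{\Sigma} the pooled covariance plus `ridge` times the
#' identity. The default ridge, `1e-6 * trace(Sigma) / dim`, keeps the
#' 64-dimensional feature covariance invertible when a class has few
#' windows; at `ridge = 0` a singular covariance raises an error rather
#' than silently regularising.
#'
#' @param x numeric matrix, samples x dimensions.
#' @param y class labels, one per row of `x`; at least two classes with at
#'   least two samples each.
#' @param ridge non-negative regulariser added to the covariance diagonal,
#'   or `NULL` for the trace-scaled default.
#' @return an object of class `emg_lda` with components `classes`,
#'   `means`, `pooled_cov`, `priors`, `ridge` and the precomputed
#'   discriminant weights.
#' @seealso [predict.emg_lda()]
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, -5), 20, 2), matrix(rnorm(40, 5), 20, 2))
#' y <- rep(1:2, each = 20)
#' fit <- emg_lda(x, y)
#' predict(fit, matrix(c(4.9, 4.9), 1))
emg_lda <- function(x, y, ridge = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stopf("x must be a numeric matrix without NA")
  if (nrow(x) != length(y)) stopf("x and y disagree on the sample count")
  classes <- sort(unique(y))
  k <- length(classes)
  if (k < 2L) stopf("need at least 2 classes; got %d", k)
  counts <- as.numeric(table(factor(y, levels = classes)))
  if (any(counts < 2L))
    stopf("every class needs at least 2 samples (class %s has %d)",
          classes[which.min(counts)], min(counts))
  n <- nrow(x); d <- ncol(x)
  means <- matrix(0, k, d, dimnames = list(as.character(classes), colnames(x)))
  sw <- matrix(0, d, d)
  for (i in seq_len(k)) {
    xi <- x[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    sw <- sw + crossprod(sweep(xi, 2, means[i, ], "-"))
  }
  pooled <- sw / (n - k)
  if (is.null(ridge)) ridge <- 1e-6 * mean(diag(pooled))
  if (!is_number(ridge) || ridge < 0) stopf("ridge must be non-negative")
  sigma <- pooled + diag(ridge, d)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stopf(paste("pooled covariance is singular; increase `ridge` or supply",
                "more samples per class"))
  W <- backsolve(ch, forwardsolve(t(ch), t(means)))     # d x k: Sigma^-1 mu_k
  const <- -0.5 * colSums(t(means) * W) + log(counts / n)
  structure(
    list(classes = classes, means = means, pooled_cov = pooled,
         priors = counts / n, ridge = ridge, weights = W, const = const),
    class = "emg_lda")
}

#' Predict classes or discriminant scores
#'
#' @param object an [emg_lda()] fit.
#' @param newdata numeric matrix, samples x dimensions.
#' @param type `"class"` for hard labels (argmax of the discriminants,
#'   ties broken towards the smallest class label) or `"scores"` for the
#'   samples x classes discriminant matrix.
#' @param ... unused.
#' @return a label vector or a score matrix.
#' @export
predict.emg_lda <- function(object, newdata, type = c("class", "scores"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$weights))
    stopf("newdata has %d dimensions; model expects %d", ncol(newdata),
          nrow(object$weights))
  scores <- newdata %*% object$weights
  scores <- sweep(scores, 2, object$const, "+")
  colnames(scores) <- as.character(object$classes)
  if (type == "scores") return(scores)
  ## classes are sorted ascending, so first-tie argmax is the smallest label
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.emg_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant classifier: %d classes, %d dimensions\n",
              length(x$classes), ncol(x$means)))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  priors:  %s\n",
              paste(sprintf("%.3f", x$priors), collapse = ", ")))
  cat(sprintf("  ridge:   %.3g\n", x$ridge))
  invisible(x)
}

#' @export
coef.emg_lda <- function(object, ...) {
  rbind(`(intercept)` = object$const, object$weights)
}
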