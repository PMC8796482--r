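#' Logistic (sigmoid) function
#'
#' Numerically stable `1/(1 + exp(-z))`, the class-membership link of the
#' logistic-regression classifier.
#'
#' @param z Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(z) stats::plogis(z)

#' Regularized cross-entropy cost and gradient
#'
#' Mean-form binary cross-entropy with an L2 penalty on the weights (the
#' bias is never regularized):
#' \deqn{J = \frac{1}{m}\sum_i \left[-y_i \ln g_i - (1-y_i)\ln(1-g_i)\right]
#'   + \frac{\lambda}{2m}\|\theta\|^2,\quad g_i = g(\theta^\top x_i + \theta_0).}
#' The returned gradient is the exact derivative of the returned cost:
#' `(1/m) X'(g - y)` plus `lambda/m * theta` on the weight entries.
#'
#' @param theta Weight vector (length `ncol(X)`).
#' @param theta0 Bias scalar.
#' @param X Numeric matrix, `m x d`.
#' @param y Binary response vector in `{0, 1}`.
#' @param lambda Non-negative regularization strength.
#' @return `list(cost, grad, grad0)`.
#' @examples
#' X <- matrix(rnorm(20), 10, 2)
#' lr_cost_grad(c(0, 0), 0, X, rep(c(0, 1), 5), lambda = 0)$cost # log(2)
#' @export
lr_cost_grad <- function(theta, theta0, X, y, lambda = 0) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (length(theta) != ncol(X)) abort("`theta` length must equal ncol(X).")
  if (length(y) != m) abort("`y` length must equal nrow(X).")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary in {0, 1}.")
  if (lambda < 0) abort("`lambda` must be non-negative.")
  z <- drop(X %*% theta) + theta0
  # -y*log(g) - (1-y)*log(1-g) computed without forming g near 0/1
  ce <- ifelse(z > 0, log1p(exp(-z)) + (1 - y) * z, log1p(exp(z)) - y * z)
  cost <- mean(ce) + lambda / (2 * m) * sum(theta^2)
  r <- sigmoid(z) - y
  list(
    cost = cost,
    grad = drop(crossprod(X, r)) / m + (lambda / m) * theta,
    grad0 = sum(r) / m
  )
}

#' Binary decision rule for a logistic classifier
#'
#' Compares the class-membership probability with the decision threshold:
#' `p >= th` maps to 1, otherwise 0 (the boundary goes to class 1).
#'
#' @param p Probability vector.
#' @param th Threshold in (0, 1), default 0.5.
#' @return Integer vector of 0/1 decisions.
#' @export
lr_decide_binary <- function(p, th = 0.5) {
  if (th <= 0 || th >= 1) abort("`th` must lie strictly in (0, 1).")
  as.integer(p >= th)
}

.standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1 # constant feature carries no signal
  list(center = center, scale = scale)
}

.standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

.as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, .feature_cols(x), drop = FALSE])
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("Features must be numeric.")
  if (!all(is.finite(x))) abort("Features contain non-finite values.")
  x
}

.check_classes <- function(y) {
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("Training needs at least 2 classes.")
  classes
}

#' Train one-vs-all regularized logistic regression
#'
#' Fits one binary logistic classifier per class (that class versus the
#' rest) by Polack-Ribiere conjugate gradients (see [cg_minimize()]),
#' capped at `max_iter` line searches per class. Features are z-scored with
#' training-set statistics stored in the model; weights start at zero, so
#' training is deterministic.
#'
#' @param x Feature matrix or feature tibble (non-feature columns such as
#'   `label`/`timestamp_s` are dropped automatically).
#' @param y Class labels, one per row of `x`.
#' @param lambda L2 regularization strength (default 1).
#' @param max_iter Conjugate-gradient iteration cap per class (default 150).
#' @param th Decision threshold for explicit binary use (default 0.5);
#'   multi-class prediction uses the arg-max of the per-class scores and
#'   ignores it.
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`).
#' @return An object of class `emg_lr` with per-class weight vectors, bias
#'   terms, the standardization parameters and final training costs.
#' @seealso [predict.emg_lr()]
#' @export
train_lr_ova <- function(x, y, lambda = 1, max_iter = 150, th = 0.5,
                         standardize = TRUE) {
  X <- .as_feature_matrix(x)
  y <- as.vector(y)
  if (length(y) != nrow(X)) abort("`y` must have one label per row of `x`.")
  classes <- .check_classes(y)
  if (lambda < 0) abort("`lambda` must be non-negative.")
  std <- if (standardize) .standardize_fit(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- .standardize_apply(X, std)
  d <- ncol(Xs)

  fits <- lapply(classes, function(cl) {
    yb <- as.numeric(y == cl)
    obj <- function(par) {
      cg <- lr_cost_grad(par[-1], par[1], Xs, yb, lambda)
      list(cost = cg$cost, grad = c(cg$grad0, cg$grad))
    }
    cg_minimize(rep(0, d + 1), obj, max_iter = max_iter)
  })

  structure(
    list(
      classes = classes,
      theta = vapply(fits, function(f) f$par[-1], numeric(d)),
      theta0 = vapply(fits, function(f) f$par[1], numeric(1)),
      costs = vapply(fits, function(f) f$cost, numeric(1)),
      n_iter = vapply(fits, function(f) f$n_iter, numeric(1)),
      lambda = lambda, th = th, max_iter = max_iter,
      center = std$center, scale = std$scale,
      feature_names = colnames(X)
    ),
    class = "emg_lr"
  )
}

.predict_scores <- function(object, newdata) {
  X <- .as_feature_matrix(newdata)
  if (ncol(X) != length(object$center)) {
    abort(sprintf(
      "Feature dimension mismatch: model expects %d, got %d.",
      length(object$center), ncol(X)
    ))
  }
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  .standardize_apply(X, list(center = object$center, scale = object$scale))
}

#' Predict from a one-vs-all logistic model
#'
#' Per-class membership probabilities are the raw sigmoid scores of each
#' binary classifier; the predicted label is their arg-max, ties broken
#' toward the lowest class index.
#'
#' @param object `emg_lr` model.
#' @param newdata Feature matrix or tibble.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return A label vector, or an `n x n_classes` probability matrix.
#' @export
predict.emg_lr <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xs <- .predict_scores(object, newdata)
  P <- sigmoid(sweep(Xs %*% object$theta, 2, object$theta0, "+"))
  colnames(P) <- as.character(object$classes)
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}
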