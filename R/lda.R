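# Closed-form linear discriminant analysis with a pooled within-class
# covariance. One-vs-all parameterization per class c:
#   beta_c  = Sigma^{-1} mu_c
#   beta0_c = -beta_c' (mu_c / 2) + log(Pi_c)
# and the binary two-class form:
#   beta  = Sigma^{-1} (mu_1 - mu_2)
#   beta0 = -beta' (mu_1 + mu_2)/2 + log(Pi_1/Pi_2),  score >= 0 -> class 1.

#' Binary LDA parameters in closed form
#'
#' @param mu1,mu2 Class mean vectors.
#' @param sigma Pooled covariance matrix.
#' @param prior1,prior2 Class prior probabilities (default equal).
#' @return `list(beta, beta0)`; the decision is
#'   [lda_decide_binary()]`(beta %*% x + beta0)`.
#' @export
lda_binary_params <- function(mu1, mu2, sigma, prior1 = 0.5, prior2 = 0.5) {
  beta <- drop(solve(sigma, mu1 - mu2))
  beta0 <- -sum(beta * (mu1 + mu2) / 2) + log(prior1 / prior2)
  list(beta = beta, beta0 = beta0)
}

#' Binary LDA decision rule
#'
#' A non-negative discriminant score maps to class 1, a negative score to
#' class 2 (the boundary goes to class 1).
#'
#' @param score Numeric vector of discriminant scores.
#' @return Integer vector of 1/2 decisions.
#' @export
lda_decide_binary <- function(score) ifelse(score >= 0, 1L, 2L)

#' Train one-vs-all linear discriminant analysis
#'
#' Closed-form training: class means, empirical class-frequency priors and
#' the pooled within-class covariance (unbiased `m - C` denominator) plus a
#' shrinkage ridge on the diagonal. Per-class discriminant parameters are
#' `beta_c = solve(Sigma, mu_c)` and
#' `beta0_c = -beta_c' mu_c / 2 + log(Pi_c)`.
#'
#' @inheritParams train_lr_ova
#' @param shrinkage Non-negative diagonal loading added to the pooled
#'   covariance; `NULL` (default) uses `1e-6 * mean(diag(Sigma))`. With
#'   `shrinkage = 0` a singular pooled covariance is an error.
#' @return An object of class `emg_lda` with means, priors, the (shrunk)
#'   pooled covariance, per-class `beta`/`beta0` and standardization
#'   parameters.
#' @seealso [predict.emg_lda()]
#' @export
train_lda_ova <- function(x, y, shrinkage = NULL, standardize = TRUE) {
  X <- .as_feature_matrix(x)
  y <- as.vector(y)
  if (length(y) != nrow(X)) abort("`y` must have one label per row of `x`.")
  classes <- .check_classes(y)
  std <- if (standardize) .standardize_fit(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- .standardize_apply(X, std)
  m <- nrow(Xs); d <- ncol(Xs); C <- length(classes)
  if (m <= C) abort("Need more samples than classes for a pooled covariance.")

  means <- t(vapply(classes, function(cl) colMeans(Xs[y == cl, , drop = FALSE]), numeric(d)))
  priors <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  scatter <- matrix(0, d, d)
  for (k in seq_len(C)) {
    Xc <- Xs[y == classes[k], , drop = FALSE]
    Xc <- sweep(Xc, 2, means[k, ], "-")
    scatter <- scatter + crossprod(Xc)
  }
  sigma <- scatter / (m - C)
  if (is.null(shrinkage)) shrinkage <- 1e-6 * mean(diag(sigma))
  if (shrinkage < 0) abort("`shrinkage` must be non-negative.")
  sigma <- sigma + diag(shrinkage, d)

  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    abort(paste(
      "Pooled covariance is singular (collinear or constant features);",
      "set a positive `shrinkage` to regularize it."
    ))
  }

  beta <- solve(sigma, t(means)) # d x C
  beta0 <- -colSums(beta * t(means)) / 2 + log(priors)

  structure(
    list(
      classes = classes, means = means, priors = priors,
      pooled_covariance = sigma, shrinkage = shrinkage,
      beta = beta, beta0 = beta0,
      center = std$center, scale = std$scale,
      feature_names = colnames(X)
    ),
    class = "emg_lda"
  )
}

#' Predict from a one-vs-all LDA model
#'
#' The label is the arg-max of the per-class linear discriminant scores,
#' ties broken toward the lowest class index.
#'
#' @param object `emg_lda` model.
#' @param newdata Feature matrix or tibble.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Unused.
#' @return A label vector, or an `n x n_classes` score matrix.
#' @export
predict.emg_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  Xs <- .predict_scores(object, newdata)
  S <- sweep(Xs %*% object$beta, 2, object$beta0, "+")
  colnames(S) <- as.character(object$classes)
  if (type == "score") return(S)
  object$classes[max.col(S, ties.method = "first")]
}
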