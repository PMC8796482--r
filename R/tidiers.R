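# broom-style tidiers for the fitted classifier objects

#' @export
tidy.emg_lr <- function(x, ...) {
  terms <- c("(bias)", x$feature_names %||% paste0("x", seq_along(x$center)))
  purrr::map_dfr(seq_along(x$classes), function(k) {
    tibble::tibble(
      class = as.character(x$classes[k]),
      term = terms,
      estimate = c(x$theta0[k], x$theta[, k])
    )
  })
}

#' @export
glance.emg_lr <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$center),
    lambda = x$lambda,
    max_iter = x$max_iter,
    mean_final_cost = if (is.null(x$costs)) NA_real_ else mean(x$costs)
  )
}

#' @export
tidy.emg_lda <- function(x, ...) {
  terms <- c("(bias)", x$feature_names %||% paste0("x", seq_along(x$center)))
  purrr::map_dfr(seq_along(x$classes), function(k) {
    tibble::tibble(
      class = as.character(x$classes[k]),
      term = terms,
      estimate = c(x$beta0[k], x$beta[, k])
    )
  })
}

#' @export
glance.emg_lda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$center),
    shrinkage = x$shrinkage
  )
}

#' @export
tidy.emg_parallel <- function(x, ...) {
  purrr::imap_dfr(
    list(elbow = x$elbow, wrist = x$wrist, hand = x$hand),
    function(clf, j) dplyr::mutate(tidy(clf), joint = j, .before = 1)
  )
}

#' @export
glance.emg_parallel <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_features = length(x$feature_names),
    n_joint_classifiers = 3L,
    n_motion_classes = 27L
  )
}
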