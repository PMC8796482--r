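#' Build the three per-joint training sets
#'
#' The parallel strategy trains one 3-output classifier per joint on the
#' same feature rows, with the 27-class labels remapped per joint (Class 1
#' and 2 the joint's active states, Class 3 "other motions"); see
#' [remap_label()].
#'
#' @param features Feature tibble with a `label` column of taxonomy codes.
#' @return Named list (`elbow`, `wrist`, `hand`) of tibbles sharing the
#'   feature rows, each with an integer `output_class` column.
#' @export
build_joint_training_sets <- function(features) {
  if (!nrow(features)) abort("`features` is empty.")
  if (!"label" %in% names(features)) abort("`features` must have a `label` column.")
  .check_codes(features$label)
  out <- lapply(.JOINTS, function(j) {
    ts <- features
    ts$output_class <- remap_label(features$label, j)
    ts
  })
  stats::setNames(out, .JOINTS)
}

#' Train the parallel three-classifier model
#'
#' Trains three independent 3-output classifiers (elbow, wrist, hand) on
#' per-joint remapped labels, with either the conjugate-gradient logistic
#' regression or the closed-form LDA backend. Classes absent from the
#' training data raise a warning, not an error: the fusion rule can still
#' emit any of the 27 classes from per-joint outputs, including
#' combinations never seen during training.
#'
#' @param features Feature tibble ([extract_features()] output).
#' @param algorithm `"lr"` or `"lda"`.
#' @param lambda L2 strength for the LR backend (default 1).
#' @param max_iter Conjugate-gradient cap for the LR backend (default 150).
#' @param shrinkage Covariance shrinkage for the LDA backend
#'   (default `NULL` = automatic, see [train_lda_ova()]).
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`; shared policy across the three classifiers).
#' @return An object of class `emg_parallel` holding the three fitted joint
#'   classifiers, the algorithm tag and the feature-column names.
#' @examples
#' \donttest{
#' rec <- generate_protocol_dataset(repetitions = 1, hold_s = 1, seed = 1)
#' feats <- rec |> segment_windows() |> extract_features()
#' model <- train_parallel(feats, algorithm = "lda")
#' }
#' @export
train_parallel <- function(features, algorithm = c("lr", "lda"), lambda = 1,
                           max_iter = 150, shrinkage = NULL,
                           standardize = TRUE) {
  algorithm <- match.arg(algorithm)
  sets <- build_joint_training_sets(features)
  missing <- setdiff(.MOTION_CODES, unique(features$label))
  if (length(missing)) {
    warn(paste0(
      "Training data lacks ", length(missing), " of the 27 motion classes (",
      paste(missing, collapse = ", "),
      "); the fused model can still emit them from per-joint outputs."
    ))
  }
  X <- .as_feature_matrix(features)
  clfs <- lapply(sets, function(ts) {
    if (algorithm == "lr") {
      train_lr_ova(X, ts$output_class, lambda = lambda, max_iter = max_iter,
                   standardize = standardize)
    } else {
      train_lda_ova(X, ts$output_class, shrinkage = shrinkage,
                    standardize = standardize)
    }
  })
  structure(
    list(
      algorithm = algorithm,
      elbow = clfs$elbow, wrist = clfs$wrist, hand = clfs$hand,
      feature_names = colnames(X)
    ),
    class = "emg_parallel"
  )
}

#' Predict fused motion classes from the parallel model
#'
#' Runs the three joint classifiers on each feature row and fuses their
#' output triple into a 27-class decision (see [fuse_outputs()]). The fused
#' label is a pure function of the three per-joint outputs.
#'
#' @param model `emg_parallel` model.
#' @param features Feature tibble or matrix.
#' @return A tibble with `timestamp_s` (when present in `features`),
#'   `elbow_out`, `wrist_out`, `hand_out` and `fused_label`.
#' @export
predict_parallel <- function(model, features) {
  if (!inherits(model, "emg_parallel")) abort("`model` must be an `emg_parallel` object.")
  X <- .as_feature_matrix(features)
  e <- predict(model$elbow, X)
  w <- predict(model$wrist, X)
  h <- predict(model$hand, X)
  out <- tibble::tibble(
    elbow_out = as.integer(e),
    wrist_out = as.integer(w),
    hand_out = as.integer(h),
    fused_label = fuse_outputs(e, w, h)
  )
  if (is.data.frame(features) && "timestamp_s" %in% names(features)) {
    out <- tibble::add_column(out, timestamp_s = features$timestamp_s, .before = 1)
  }
  out
}

# --- JSON serialization ------------------------------------------------------

.clf_to_list <- function(clf) {
  if (inherits(clf, "emg_lr")) {
    list(
      type = "lr", classes = clf$classes,
      theta = as.data.frame(clf$theta), theta0 = clf$theta0,
      lambda = clf$lambda, th = clf$th, max_iter = clf$max_iter,
      center = clf$center, scale = clf$scale,
      feature_names = clf$feature_names
    )
  } else {
    list(
      type = "lda", classes = clf$classes,
      means = as.data.frame(clf$means), priors = clf$priors,
      pooled_covariance = as.data.frame(clf$pooled_covariance),
      shrinkage = clf$shrinkage,
      beta = as.data.frame(clf$beta), beta0 = clf$beta0,
      center = clf$center, scale = clf$scale,
      feature_names = clf$feature_names
    )
  }
}

.clf_from_list <- function(l) {
  mat <- function(df) unname(as.matrix(as.data.frame(df)))
  if (l$type == "lr") {
    structure(
      list(
        classes = unlist(l$classes), theta = mat(l$theta),
        theta0 = unlist(l$theta0), lambda = l$lambda, th = l$th,
        max_iter = l$max_iter, center = unlist(l$center),
        scale = unlist(l$scale), feature_names = unlist(l$feature_names)
      ),
      class = "emg_lr"
    )
  } else {
    structure(
      list(
        classes = unlist(l$classes), means = mat(l$means),
        priors = unlist(l$priors), pooled_covariance = mat(l$pooled_covariance),
        shrinkage = l$shrinkage, beta = mat(l$beta), beta0 = unlist(l$beta0),
        center = unlist(l$center), scale = unlist(l$scale),
        feature_names = unlist(l$feature_names)
      ),
      class = "emg_lda"
    )
  }
}

#' Save / load a parallel model as JSON
#'
#' Serializes the full parameter set (per-class weight vectors, biases,
#' covariance, priors, standardization vectors, hyper-parameters and a
#' format-version tag) at full numeric precision, so reloaded models make
#' identical decisions. Joint ordering in the file is fixed as
#' elbow, wrist, hand.
#'
#' @param model `emg_parallel` model.
#' @param path JSON file path.
#' @export
write_parallel_model <- function(model, path) {
  if (!inherits(model, "emg_parallel")) abort("`model` must be an `emg_parallel` object.")
  payload <- list(
    format = "emgfuse-parallel-model", format_version = 1L,
    algorithm = model$algorithm,
    feature_names = model$feature_names,
    elbow = .clf_to_list(model$elbow),
    wrist = .clf_to_list(model$wrist),
    hand = .clf_to_list(model$hand)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parallel_model
#' @export
read_parallel_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$format, "emgfuse-parallel-model")) {
    abort("Not an emgfuse parallel model file.")
  }
  structure(
    list(
      algorithm = l$algorithm,
      elbow = .clf_from_list(l$elbow),
      wrist = .clf_from_list(l$wrist),
      hand = .clf_from_list(l$hand),
      feature_names = unlist(l$feature_names)
    ),
    class = "emg_parallel"
  )
}

#' @export
print.emg_parallel <- function(x, ...) {
  cat("Parallel sEMG intent decoder (", toupper(x$algorithm), " backend)\n", sep = "")
  cat("  joints: elbow, wrist, hand (3 output classes each)\n")
  cat("  features:", length(x$feature_names), "per window\n")
  invisible(x)
}
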