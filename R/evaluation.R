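#' Per-class train/test split
#'
#' Splits a feature table into training and test partitions class by class,
#' reserving `train_fraction` of each class for training (train size =
#' `floor(train_fraction * n)`). The default `"contiguous"` policy assigns
#' each class's chronologically first windows to training, which keeps
#' overlapping windows from straddling the split and leaking between
#' partitions; `"shuffled"` samples rows under `seed`.
#'
#' @param features Feature tibble with a `label` column.
#' @param train_fraction Fraction per class reserved for training, in
#'   (0, 1); default 0.7.
#' @param policy `"contiguous"` (default) or `"shuffled"`.
#' @param seed Integer seed for the shuffled policy.
#' @return `list(train = <tibble>, test = <tibble>)`.
#' @export
split_train_test <- function(features, train_fraction = 0.7,
                             policy = c("contiguous", "shuffled"),
                             seed = NULL) {
  policy <- match.arg(policy)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly in (0, 1).")
  }
  if (!"label" %in% names(features)) abort("`features` must have a `label` column.")
  counts <- table(features$label)
  if (any(counts < 2)) {
    abort(paste0(
      "Each class needs at least 2 windows to split; too few for: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  idx_by_class <- split(seq_len(nrow(features)), features$label)
  if ("timestamp_s" %in% names(features)) {
    idx_by_class <- lapply(idx_by_class, function(i) i[order(features$timestamp_s[i])])
  }
  pick_train <- function(i) {
    n_train <- floor(train_fraction * length(i))
    if (policy == "shuffled") i <- sample(i)
    i[seq_len(n_train)]
  }
  train_idx <- if (policy == "shuffled" && !is.null(seed)) {
    withr::with_seed(seed, unlist(lapply(idx_by_class, pick_train)))
  } else {
    unlist(lapply(idx_by_class, pick_train))
  }
  list(
    train = features[sort(train_idx), , drop = FALSE],
    test = features[setdiff(seq_len(nrow(features)), train_idx), , drop = FALSE]
  )
}

#' Confusion matrix (true classes in rows)
#'
#' @param truth,predicted Label vectors of equal length.
#' @param levels Class ordering; defaults to the sorted union of observed
#'   labels. For fused 27-class matrices pass `motion_classes()$code`.
#' @return An integer matrix of class `emg_confusion`, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  levels <- levels %||% sort(unique(c(truth, predicted)))
  cm <- table(
    factor(truth, levels = levels),
    factor(predicted, levels = levels)
  )
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = levels, predicted = levels)
  structure(cm, class = c("emg_confusion", class(cm)))
}

#' Per-class F1 scores
#'
#' For class c: precision = `cm[c,c]/colsum`, recall = `cm[c,c]/rowsum`,
#' `F1 = 2pr/(p + r)`; a class with `p + r = 0` scores 0. The macro F1 is
#' the unweighted mean over classes (see [macro_f1()]).
#'
#' @param cm Confusion matrix ([confusion_matrix()] output).
#' @return A tibble with `class`, `precision`, `recall`, `f1`.
#' @export
f1_per_class <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) abort("Confusion matrix is all zeros.")
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble::tibble(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    precision = unname(precision), recall = unname(recall), f1 = unname(f1)
  )
}

#' @rdname f1_per_class
#' @export
macro_f1 <- function(cm) mean(f1_per_class(cm)$f1)

#' Misclassification error
#'
#' `1 - trace/total`, i.e. one minus accuracy.
#'
#' @param cm Confusion matrix.
#' @return A proportion in \[0, 1\].
#' @export
misclassification_error <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) abort("Confusion matrix is all zeros.")
  1 - sum(diag(cm)) / sum(cm)
}

#' Row-normalize a confusion matrix
#'
#' Divides each row by its true-class support so rows sum to one. Zero
#' rows (classes without test examples) are emitted as zeros with a
#' warning.
#'
#' @param cm Confusion matrix.
#' @return A row-stochastic matrix of class `emg_confusion`.
#' @export
normalize_confusion <- function(cm) {
  m <- as.matrix(cm)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn(paste0(
      "Zero-support row(s) left as zeros: ",
      paste(rownames(m)[rs == 0] %||% which(rs == 0), collapse = ", ")
    ))
  }
  out <- m / ifelse(rs == 0, 1, rs)
  structure(out, dimnames = dimnames(m), class = c("emg_confusion", "matrix", "array"))
}

#' Offline evaluation of a parallel model
#'
#' Convenience wrapper: predicts on a labeled feature table and reports the
#' per-joint 3-class F1 tables, per-joint and fused confusion matrices, the
#' fused 27-class macro F1 and the misclassification errors.
#'
#' @param model `emg_parallel` model.
#' @param features Labeled feature tibble (test partition).
#' @return A list with `joint_f1` (tibble: joint, class, precision, recall,
#'   f1), `joint_confusion` (list of 3x3 `emg_confusion`), `fused_confusion`
#'   (27x27), `fused_f1` (tibble) and `summary` (one-row tibble).
#' @export
evaluate_parallel <- function(model, features) {
  pred <- predict_parallel(model, features)
  truth_joint <- lapply(stats::setNames(.JOINTS, .JOINTS),
                        function(j) remap_label(features$label, j))
  pred_joint <- list(elbow = pred$elbow_out, wrist = pred$wrist_out, hand = pred$hand_out)
  joint_cm <- purrr::map2(truth_joint, pred_joint, confusion_matrix, levels = 1:3)
  joint_f1 <- purrr::imap_dfr(joint_cm, function(cm, j) {
    dplyr::mutate(f1_per_class(cm), joint = j, .before = 1)
  })
  fused_cm <- confusion_matrix(features$label, pred$fused_label,
                               levels = motion_classes()$code)
  list(
    joint_f1 = joint_f1,
    joint_confusion = joint_cm,
    fused_confusion = fused_cm,
    fused_f1 = f1_per_class(fused_cm),
    summary = tibble::tibble(
      algorithm = model$algorithm,
      elbow_macro_f1 = macro_f1(joint_cm$elbow),
      wrist_macro_f1 = macro_f1(joint_cm$wrist),
      hand_macro_f1 = macro_f1(joint_cm$hand),
      fused_macro_f1 = macro_f1(fused_cm),
      fused_error = misclassification_error(fused_cm),
      n_windows = nrow(features)
    )
  )
}

# --- Real-time metrics -------------------------------------------------------

#' Selection/completion metrics from a prediction stream
#'
#' Given the correctness and timestamps of a stream of decisions during one
#' motion attempt, computes the motion selection time (MST: time from onset
#' to the first correct decision), the motion completion time (MCT: time to
#' the `completion_required`-th correct decision, counted cumulatively by
#' default or over consecutive runs with `counting = "consecutive"`), and
#' the completion flag (MCT within `timeout_s`). An attempt whose required
#' correct count never arrives inside the timeout is failed and its MCT is
#' undefined (`NA`).
#'
#' @param correct Logical vector, one entry per emitted decision.
#' @param times Decision timestamps in seconds from motion onset.
#' @param completion_required Correct decisions needed to complete
#'   (default 10).
#' @param timeout_s Completion deadline in seconds (default 5).
#' @param counting `"cumulative"` (default) or `"consecutive"`.
#' @return One-row tibble: `mst_s`, `mct_s`, `completed`, `n_predictions`,
#'   `n_correct`.
#' @export
attempt_metrics <- function(correct, times, completion_required = 10,
                            timeout_s = 5,
                            counting = c("cumulative", "consecutive")) {
  counting <- match.arg(counting)
  if (length(correct) != length(times)) {
    abort("`correct` and `times` must have equal length.")
  }
  if (completion_required < 1) abort("`completion_required` must be >= 1.")
  hits <- which(correct)
  mst <- if (length(hits)) times[hits[1]] else NA_real_
  mct <- NA_real_
  if (counting == "cumulative") {
    if (length(hits) >= completion_required) mct <- times[hits[completion_required]]
  } else {
    r <- rle(as.logical(correct))
    ends <- cumsum(r$lengths)
    run <- which(r$values & r$lengths >= completion_required)
    if (length(run)) {
      k <- run[1]
      mct <- times[ends[k] - r$lengths[k] + completion_required]
    }
  }
  completed <- !is.na(mct) && mct <= timeout_s
  if (!completed) mct <- NA_real_
  tibble::tibble(
    mst_s = mst, mct_s = mct, completed = completed,
    n_predictions = length(correct), n_correct = length(hits)
  )
}

#' Replay one motion attempt through the decoder
#'
#' Simulates the on-line decision loop on a recorded (or generated) attempt
#' whose intended class is known: decisions are emitted every
#' `decision_period_ms`, each computed from the most recent full analysis
#' window, so decision k falls at `W + (k-1)*delta` seconds after onset
#' (W = window duration — no decision can exist before one full window).
#' A decision is correct iff the fused 27-class output equals `target`.
#' Onset is the start of the attempt segment (cue-aligned replay).
#'
#' @param model `emg_parallel` model.
#' @param attempt Recording tibble covering one attempt (>= one window).
#' @param target Intended motion class code.
#' @param window_ms,decision_period_ms Window length and decision period in
#'   milliseconds (defaults 150 and 90).
#' @param sampling_rate_hz Optional; inferred from `time_s` when omitted.
#' @inheritParams attempt_metrics
#' @inheritParams extract_features
#' @return One-row tibble: `target` plus the [attempt_metrics()] columns.
#' @export
simulate_realtime <- function(model, attempt, target, window_ms = 150,
                              decision_period_ms = 90,
                              completion_required = 10, timeout_s = 5,
                              counting = c("cumulative", "consecutive"),
                              sampling_rate_hz = NULL, ssc_threshold = 0) {
  counting <- match.arg(counting)
  .check_codes(target)
  fs <- .infer_fs(attempt, sampling_rate_hz)
  L <- round(window_ms * fs / 1000)
  n <- nrow(attempt)
  if (n < L) abort("Attempt shorter than one analysis window.")
  chans <- .channel_cols(attempt)
  sig <- as.matrix(attempt[, chans, drop = FALSE])

  k <- seq_len(floor((n - L) * 1000 / (decision_period_ms * fs)) + 1)
  ends <- L + round((k - 1) * decision_period_ms * fs / 1000) # last sample (1-based)
  ends <- ends[ends <= n]
  times <- ends / fs

  windows <- tibble::tibble(
    window_id = seq_along(ends),
    start_sample = as.integer(ends - L),
    end_time_s = times,
    label = target,
    signal = lapply(ends, function(e) sig[(e - L + 1):e, , drop = FALSE])
  )
  feats <- extract_features(windows, ssc_threshold = ssc_threshold)
  pred <- predict_parallel(model, feats)
  res <- attempt_metrics(pred$fused_label == target, times,
                         completion_required = completion_required,
                         timeout_s = timeout_s, counting = counting)
  tibble::add_column(res, target = target, .before = 1)
}

#' Motion completion rate
#'
#' Percentage of attempts completed within the timeout.
#'
#' @param results Tibble of attempt results with a `completed` column.
#' @return Percentage in \[0, 100\].
#' @export
motion_completion_rate <- function(results) {
  if (!nrow(results)) abort("No attempts to aggregate.")
  100 * mean(results$completed)
}

#' Run the full real-time test protocol on synthetic attempts
#'
#' Generates `repetitions` fresh attempts per motion class with the
#' synthetic sEMG generator (27 classes x 2 repetitions = 54 attempts at
#' the defaults) and replays each through [simulate_realtime()].
#'
#' @param model `emg_parallel` model.
#' @param repetitions Attempts per class (default 2).
#' @param attempt_s Attempt duration in seconds (default 5, the completion
#'   timeout).
#' @param seed Integer seed; attempt i uses `seed + i`.
#' @inheritParams simulate_realtime
#' @inheritParams generate_recording
#' @return A tibble of class `emg_rt`: one row per attempt with `class`,
#'   `repetition`, `dof` and the [attempt_metrics()] columns.
#' @export
run_realtime_protocol <- function(model, repetitions = 2, attempt_s = 5,
                                  seed = 1, sampling_rate_hz = 1000,
                                  baseline_std = 0.05, snr_scale = 1,
                                  activation = default_activation_matrix(),
                                  window_ms = 150, decision_period_ms = 90,
                                  completion_required = 10, timeout_s = 5,
                                  counting = c("cumulative", "consecutive")) {
  counting <- match.arg(counting)
  tax <- motion_classes()
  grid <- tidyr::expand_grid(class = tax$code, repetition = seq_len(repetitions))
  res <- purrr::pmap_dfr(
    list(grid$class, grid$repetition, seq_len(nrow(grid))),
    function(cl, rep_i, i) {
      rec <- generate_recording(
        cl, hold_s = attempt_s, rest_s = 0,
        sampling_rate_hz = sampling_rate_hz, baseline_std = baseline_std,
        snr_scale = snr_scale, activation = activation, seed = seed + i
      )
      out <- simulate_realtime(
        model, rec, cl, window_ms = window_ms,
        decision_period_ms = decision_period_ms,
        completion_required = completion_required, timeout_s = timeout_s,
        counting = counting, sampling_rate_hz = sampling_rate_hz
      )
      tibble::add_column(out, repetition = rep_i, .after = 1)
    }
  )
  res <- dplyr::rename(res, class = "target")
  res$dof <- tax$dof[match(res$class, tax$code)]
  class(res) <- c("emg_rt", class(res))
  res
}

#' Summarize real-time protocol results
#'
#' Mean MST/MCT over completed-or-selected attempts (failed attempts do not
#' contribute to the MCT mean; the `n` columns report how many attempts
#' entered each mean) and the MCR, overall or grouped by DoF count.
#'
#' @param results `emg_rt` tibble from [run_realtime_protocol()].
#' @param by `"overall"` (default) or `"dof"`.
#' @return A tibble of aggregate metrics.
#' @export
summarize_realtime <- function(results, by = c("overall", "dof")) {
  by <- match.arg(by)
  grouped <- if (by == "dof") dplyr::group_by(results, .data$dof) else results
  dplyr::summarise(
    grouped,
    mean_mst_s = mean(.data$mst_s, na.rm = TRUE),
    sd_mst_s = sd(.data$mst_s, na.rm = TRUE),
    n_mst = sum(!is.na(.data$mst_s)),
    mean_mct_s = mean(.data$mct_s, na.rm = TRUE),
    sd_mct_s = sd(.data$mct_s, na.rm = TRUE),
    n_mct = sum(!is.na(.data$mct_s)),
    mcr_percent = 100 * mean(.data$completed),
    n_attempts = dplyr::n()
  )
}

# --- Statistics --------------------------------------------------------------

#' Mann-Whitney U test with eta-squared effect size
#'
#' Two-sided rank-sum test via the normal approximation with tie
#' correction; the effect size is \eqn{\eta^2 = Z^2/N} with N the combined
#' sample size. The U statistic reported is that of sample `a`
#' (rank-sum of `a` minus `n_a(n_a+1)/2`, the same convention as
#' `wilcox.test`'s W). By default no continuity correction is applied to
#' Z; set `continuity = TRUE` for the corrected p-value.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param continuity Apply the 0.5 continuity correction (default `FALSE`).
#' @return One-row tibble: `u`, `z`, `p_value`, `eta_squared`, `n_a`, `n_b`.
#' @examples
#' mann_whitney_eta2(1:15, 16:30)
#' @export
mann_whitney_eta2 <- function(a, b, continuity = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("Each sample needs at least 2 values.")
  N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
  } else {
    num <- u - mu
    if (continuity) num <- num - sign(num) * 0.5
    z <- num / sqrt(sigma2)
  }
  tibble::tibble(
    u = u, z = z,
    p_value = min(1, 2 * pnorm(-abs(z))),
    eta_squared = z^2 / N,
    n_a = n1, n_b = n2
  )
}
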