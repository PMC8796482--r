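#' Assemble a labeled multi-channel sEMG recording
#'
#' A recording is a plain tibble: a `time_s` column, one numeric column per
#' channel and a `label` column of motion class codes (rest periods carry the
#' first-class `"NM"` label). All pipeline functions accept this layout, so
#' recordings read from CSV or built by the synthetic generator are
#' interchangeable.
#'
#' @param signals Numeric matrix, `n_samples x n_channels`.
#' @param labels Character vector of per-sample motion class codes
#'   (length `n_samples`), or a single code recycled to all samples.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @param channel_names Optional channel column names; defaults to
#'   `ch1, ch2, ...`.
#' @return A tibble with columns `time_s`, channels, `label`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(20), 10, 2), "F", sampling_rate_hz = 100)
#' @export
emg_recording <- function(signals, labels, sampling_rate_hz = 1000,
                          channel_names = NULL) {
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (n < 1 || ncol(signals) < 1) abort("`signals` must have >= 1 sample and >= 1 channel.")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive number.")
  }
  labels <- rep_len(as.character(labels), if (length(labels) == 1) n else length(labels))
  if (length(labels) != n) abort("`labels` must have one entry per sample.")
  channel_names <- channel_names %||% paste0("ch", seq_len(ncol(signals)))
  if (length(channel_names) != ncol(signals)) {
    abort("`channel_names` length must match the number of channels.")
  }
  colnames(signals) <- channel_names
  out <- tibble::as_tibble(signals)
  out <- tibble::add_column(out, time_s = (seq_len(n) - 1) / sampling_rate_hz, .before = 1)
  out$label <- labels
  out
}

.channel_cols <- function(rec) {
  setdiff(names(rec)[vapply(rec, is.numeric, logical(1))], "time_s")
}

.infer_fs <- function(rec, sampling_rate_hz = NULL) {
  if (!is.null(sampling_rate_hz)) return(sampling_rate_hz)
  if (!"time_s" %in% names(rec) || nrow(rec) < 2) {
    abort("Cannot infer the sampling rate; supply `sampling_rate_hz`.")
  }
  dt <- stats::median(diff(rec$time_s))
  if (!is.finite(dt) || dt <= 0) abort("Non-increasing `time_s`; supply `sampling_rate_hz`.")
  1 / dt
}

#' Read / write labeled sEMG recordings as CSV
#'
#' Layout: a header row, column 1 `time_s`, one column per channel
#' (`ch1..ch6` for the 6-sensor setup) and a final `label` column holding
#' taxonomy codes (`F`, `E`, `C`, `O`, `S`, `P`, `FO`, ..., `NM`).
#'
#' @param path File path.
#' @return `read_emg_csv()` returns the recording tibble.
#' @export
read_emg_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "label")
  if (!all(need %in% names(rec))) {
    abort("Recording CSV must contain `time_s` and `label` columns.")
  }
  rec$label <- as.character(rec$label)
  if (!length(.channel_cols(rec))) abort("Recording CSV has no channel columns.")
  rec
}

#' @rdname read_emg_csv
#' @param rec Recording tibble.
#' @export
write_emg_csv <- function(rec, path) {
  readr::write_csv(rec, path, progress = FALSE)
  invisible(path)
}

# modal label of a window; ties go to the label appearing earliest in it
.modal_label <- function(labels) {
  counts <- table(labels)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1) return(winners)
  winners[which.min(match(winners, labels))]
}

#' Segment a recording into overlapping analysis windows
#'
#' Slides a fixed-length window over the recording (default 150 ms with
#' 100 ms overlap, i.e. a 50 ms step). Window k covers the half-open sample
#' interval `[k*step, k*step + L)` (0-based); trailing samples that do not
#' fill a full window are dropped, so the count is
#' `floor((n_samples - L)/step) + 1`. A window spanning a class transition
#' takes the modal per-sample label, ties broken toward the label that
#' appears earliest in the window.
#'
#' @param rec Recording tibble (see [emg_recording()]).
#' @param window_ms Window length in milliseconds (default 150).
#' @param overlap_ms Overlap between consecutive windows in milliseconds
#'   (default 100); must be non-negative and smaller than `window_ms`.
#' @param sampling_rate_hz Optional sampling rate; inferred from `time_s`
#'   when omitted.
#' @return A tibble with one row per window: `window_id`, `start_sample`
#'   (0-based), `end_time_s` (time of the window's last sample, used as the
#'   prediction timestamp), `label`, and a `signal` list-column of
#'   `L x n_channels` matrices.
#' @examples
#' rec <- emg_recording(matrix(rnorm(600), 300, 2), "F", sampling_rate_hz = 1000)
#' segment_windows(rec)
#' @export
segment_windows <- function(rec, window_ms = 150, overlap_ms = 100,
                            sampling_rate_hz = NULL) {
  fs <- .infer_fs(rec, sampling_rate_hz)
  if (overlap_ms < 0 || overlap_ms >= window_ms) {
    abort("`overlap_ms` must satisfy 0 <= overlap_ms < window_ms.")
  }
  L <- round(window_ms * fs / 1000)
  step <- round((window_ms - overlap_ms) * fs / 1000)
  if (L < 2) abort("Window shorter than 2 samples; increase `window_ms`.")
  if (step < 1) abort("Window step rounds to 0 samples; reduce `overlap_ms`.")
  n <- nrow(rec)
  if (n < L) {
    abort(sprintf("Insufficient data: recording has %d samples but one window needs %d.", n, L))
  }
  chans <- .channel_cols(rec)
  sig <- as.matrix(rec[, chans, drop = FALSE])
  labels <- if ("label" %in% names(rec)) as.character(rec$label) else rep(NA_character_, n)
  times <- if ("time_s" %in% names(rec)) rec$time_s else (seq_len(n) - 1) / fs

  n_win <- floor((n - L) / step) + 1
  starts <- (seq_len(n_win) - 1L) * step # 0-based
  win <- lapply(starts, function(s) sig[(s + 1):(s + L), , drop = FALSE])
  lab <- vapply(starts, function(s) .modal_label(labels[(s + 1):(s + L)]), character(1))
  tibble::tibble(
    window_id = seq_len(n_win),
    start_sample = as.integer(starts),
    end_time_s = times[starts + L],
    label = lab,
    signal = win
  )
}
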