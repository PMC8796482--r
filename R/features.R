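# Five time-domain sEMG features. EMAV and EWL use a position-dependent
# exponent that up-weights the middle 60% of the window:
#   p(i) = 0.75 for 0.2*L <= i <= 0.8*L (1-based i, real-valued bounds,
#   inclusive), 0.50 otherwise.
# Fractional powers of signed samples are read as |x|^p, the only
# real-valued interpretation.

.p_exponents <- function(L) {
  i <- seq_len(L)
  ifelse(i >= 0.2 * L & i <= 0.8 * L, 0.75, 0.50)
}

#' Time-domain sEMG features
#'
#' The five per-window, per-channel features of the decoding pipeline:
#'
#' * `emav(x)` — enhanced mean absolute value,
#'   \eqn{(1/L)\sum_i |x_i|^{p(i)}}.
#' * `ewl(x)` — enhanced waveform length,
#'   \eqn{\sum_{i=2}^{L} |x_i - x_{i-1}|^{p(i)}}.
#' * `ssc(x)` — slope sign change: the count of interior samples where
#'   \eqn{(x_i-x_{i-1})(x_i-x_{i+1}) \ge} `threshold`, divided by `L`
#'   (set `normalize = FALSE` for the conventional raw count). With the
#'   default zero threshold, flat triplets (product exactly 0) count as
#'   sign changes.
#' * `rms(x)` — root mean square, \eqn{\sqrt{(1/L)\sum_i x_i^2}}.
#' * `var_td(x)` — \eqn{(1/(L-1))\sum_i x_i^2}; no mean subtraction by
#'   default (the zero-mean EMG convention), `center = TRUE` subtracts it.
#'
#' `p(i)` is 0.75 for \eqn{0.2L \le i \le 0.8L} and 0.50 otherwise.
#'
#' @param x Numeric vector (one channel of one window).
#' @param threshold Non-negative slope-product threshold for `ssc`
#'   (default 0).
#' @param normalize Divide the `ssc` count by `L` (default `TRUE`).
#' @param center Subtract the mean in `var_td` (default `FALSE`).
#' @return A single numeric value.
#' @examples
#' emav(c(2, 2))
#' ssc(c(0, 1, 0, 1, 0))
#' @name td_features
NULL

#' @rdname td_features
#' @export
emav <- function(x) {
  L <- length(x)
  if (L < 1) abort("`emav()` needs a non-empty vector.")
  mean(abs(x)^.p_exponents(L))
}

#' @rdname td_features
#' @export
ewl <- function(x) {
  L <- length(x)
  if (L < 2) abort("`ewl()` needs at least 2 samples.")
  sum(abs(diff(x))^.p_exponents(L)[-1])
}

#' @rdname td_features
#' @export
ssc <- function(x, threshold = 0, normalize = TRUE) {
  L <- length(x)
  if (L < 3) abort("`ssc()` needs at least 3 samples.")
  if (threshold < 0) abort("`threshold` must be non-negative.")
  mid <- x[2:(L - 1)]
  prod <- (mid - x[1:(L - 2)]) * (mid - x[3:L])
  count <- sum(prod >= threshold)
  if (normalize) count / L else count
}

#' @rdname td_features
#' @export
rms <- function(x) {
  if (length(x) < 1) abort("`rms()` needs a non-empty vector.")
  sqrt(mean(x^2))
}

#' @rdname td_features
#' @export
var_td <- function(x, center = FALSE) {
  L <- length(x)
  if (L < 2) abort("`var_td()` needs at least 2 samples.")
  if (center) x <- x - mean(x)
  sum(x^2) / (L - 1)
}

.FEATURE_NAMES <- c("emav", "ewl", "ssc", "rms", "var")

.window_features <- function(m, threshold, normalize_ssc, center_var) {
  vals <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    c(
      emav(x), ewl(x), ssc(x, threshold, normalize_ssc),
      rms(x), var_td(x, center_var)
    )
  })
  unlist(vals, use.names = FALSE)
}

#' Extract per-window feature vectors
#'
#' Applies the five time-domain extractors (see [td_features]) to every
#' channel of every window, producing one feature row per window: values are
#' ordered channel-major (all five features of channel 1, then channel 2,
#' ...), giving 30 columns for the 6-channel setup. The window label and
#' end-time are carried through.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param ssc_threshold Slope-product threshold for SSC (default 0).
#' @param normalize_ssc Divide SSC by the window length (default `TRUE`).
#' @param center_var Mean-subtract in the variance feature (default `FALSE`).
#' @return A tibble with columns `<channel>_<feature>` for each channel and
#'   feature in `emav, ewl, ssc, rms, var` order, plus `label` and
#'   `timestamp_s`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(900), 300, 3), "F", sampling_rate_hz = 1000)
#' rec |> segment_windows() |> extract_features()
#' @export
extract_features <- function(windows, ssc_threshold = 0, normalize_ssc = TRUE,
                             center_var = FALSE) {
  if (!nrow(windows)) abort("No windows to extract features from.")
  chans <- colnames(windows$signal[[1]])
  cols <- as.vector(t(outer(chans, .FEATURE_NAMES, paste, sep = "_")))
  vals <- vapply(
    windows$signal,
    .window_features,
    numeric(length(cols)),
    threshold = ssc_threshold, normalize_ssc = normalize_ssc,
    center_var = center_var
  )
  out <- tibble::as_tibble(stats::setNames(as.data.frame(t(vals)), cols))
  out$label <- windows$label
  out$timestamp_s <- windows$end_time_s
  out
}

.feature_cols <- function(features) {
  setdiff(
    names(features)[vapply(features, is.numeric, logical(1))],
    c("timestamp_s", "window_id", "start_sample")
  )
}

#' Read / write feature matrices as CSV
#'
#' One row per window: the channel-major feature columns, the `label`
#' column and the `timestamp_s` column.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path File path.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"label" %in% names(out)) abort("Feature CSV must contain a `label` column.")
  out$label <- as.character(out$label)
  out
}
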