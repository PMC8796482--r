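# Synthetic sEMG: amplitude-modulated Gaussian noise, the standard
# stochastic surrogate for surface EMG. Each motion class sets a
# per-channel contraction level; samples during a hold are zero-mean
# Gaussian with sd = baseline_std + snr_scale * activation.

.PRIMITIVE_CHANNEL <- c(O = 1L, C = 2L, S = 3L, P = 4L, F = 5L, E = 6L)

#' Default per-class per-channel activation matrix
#'
#' Compositional construction mirroring the 6-sensor montage: each of the
#' six primitive states (hand open/close on the bracelet channels 1-2,
#' wrist supination/pronation on channels 3-4, elbow flexion/extension on
#' the biceps/triceps channels 5-6) activates one dominant channel at
#' `amplitude`, with `crosstalk * amplitude` bleeding into the remaining
#' channels. A combined class's row is the element-wise maximum of its
#' primitives' rows, so cross-talk is inherited; the `NM` row is all
#' zeros. All 27 rows are pairwise distinct.
#'
#' @param amplitude Dominant-channel contraction level (default 1).
#' @param crosstalk Fraction of the dominant amplitude reaching the other
#'   channels (default 0.1, a realistic forearm cross-talk level).
#' @param n_channels Number of channels (default 6; must be >= 6 for the
#'   default montage).
#' @return A 27 x `n_channels` matrix, rows named by motion class code.
#' @export
default_activation_matrix <- function(amplitude = 1, crosstalk = 0.1,
                                      n_channels = 6) {
  if (n_channels < 6) abort("The default montage needs at least 6 channels.")
  prim <- vapply(names(.PRIMITIVE_CHANNEL), function(p) {
    row <- rep(crosstalk * amplitude, n_channels)
    row[.PRIMITIVE_CHANNEL[[p]]] <- amplitude
    row
  }, numeric(n_channels))
  prim <- t(prim) # primitive x channel
  tax <- motion_classes()
  A <- t(vapply(tax$code, function(code) {
    if (code == "NM") return(rep(0, n_channels))
    letters <- strsplit(code, "")[[1]]
    do.call(pmax, lapply(letters, function(p) prim[p, ]))
  }, numeric(n_channels)))
  rownames(A) <- tax$code
  colnames(A) <- paste0("ch", seq_len(n_channels))
  A
}

.bandpass_filter <- function(sig, bandpass, fs) {
  ny <- fs / 2
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[2] <= bandpass[1] ||
      bandpass[2] >= ny) {
    abort("`bandpass` must be c(low, high) with 0 < low < high < fs/2.")
  }
  bf <- signal::butter(2, bandpass / ny, type = "pass")
  apply(sig, 2, function(x) signal::filtfilt(bf, x))
}

#' Generate a labeled synthetic sEMG recording
#'
#' Emulates held gestures: for each class in `classes`, `hold_s` seconds of
#' zero-mean Gaussian noise with per-channel standard deviation
#' `baseline_std + snr_scale * activation[class, channel]`, labeled with
#' the class code, followed by `rest_s` seconds of baseline noise labeled
#' `NM`. Optional band-pass shaping (e.g. `c(20, 450)` Hz) imposes an
#' EMG-like spectrum; it is off by default since the decoder's features are
#' amplitude-driven. Fully reproducible from `seed`.
#'
#' @param classes Character vector of motion class codes, one per held
#'   gesture, in order.
#' @param hold_s Hold duration per gesture in seconds (default 3).
#' @param rest_s Rest duration after each gesture in seconds (default 2;
#'   0 suppresses rests).
#' @param sampling_rate_hz Sampling rate (default 1000).
#' @param baseline_std Rest-noise standard deviation (default 0.05).
#' @param snr_scale Multiplier on the activation amplitudes (default 1;
#'   0 makes every class indistinguishable from rest).
#' @param activation Per-class per-channel amplitude matrix
#'   (default [default_activation_matrix()]).
#' @param bandpass Optional `c(low, high)` corner frequencies in Hz.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A recording tibble (`time_s`, channels, `label`).
#' @export
generate_recording <- function(classes, hold_s = 3, rest_s = 2,
                               sampling_rate_hz = 1000, baseline_std = 0.05,
                               snr_scale = 1,
                               activation = default_activation_matrix(),
                               bandpass = NULL, seed = NULL) {
  if (!length(classes)) abort("`classes` must name at least one gesture.")
  .check_codes(classes)
  bad <- setdiff(classes, rownames(activation))
  if (length(bad)) abort(paste0("No activation row for: ", paste(bad, collapse = ", ")))
  if (baseline_std < 0 || snr_scale < 0) {
    abort("`baseline_std` and `snr_scale` must be non-negative.")
  }
  if (hold_s <= 0 || rest_s < 0) abort("`hold_s` must be positive and `rest_s` non-negative.")
  fs <- sampling_rate_hz
  n_hold <- round(hold_s * fs)
  n_rest <- round(rest_s * fs)
  nch <- ncol(activation)

  gen <- function() {
    blocks <- lapply(classes, function(cl) {
      sds <- baseline_std + snr_scale * activation[cl, ]
      hold <- vapply(sds, function(s) rnorm(n_hold, sd = s), numeric(n_hold))
      lab <- rep(cl, n_hold)
      if (n_rest > 0) {
        rest <- matrix(rnorm(n_rest * nch, sd = baseline_std), n_rest, nch)
        hold <- rbind(hold, rest)
        lab <- c(lab, rep("NM", n_rest))
      }
      list(sig = hold, lab = lab)
    })
    sig <- do.call(rbind, lapply(blocks, `[[`, "sig"))
    if (!is.null(bandpass)) sig <- .bandpass_filter(sig, bandpass, fs)
    emg_recording(sig, unlist(lapply(blocks, `[[`, "lab")),
                  sampling_rate_hz = fs, channel_names = colnames(activation))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a full acquisition-protocol dataset
#'
#' All 27 motion classes, `repetitions` held gestures each (3 s hold, 2 s
#' rest between gestures at the defaults), presented in randomized order
#' under `seed`. This emulates the dataset from which the 70/30 split and
#' offline metrics are computed.
#'
#' @param repetitions Holds per class (default 4).
#' @inheritParams generate_recording
#' @return A recording tibble.
#' @examples
#' \donttest{
#' rec <- generate_protocol_dataset(repetitions = 1, hold_s = 1, seed = 1)
#' }
#' @export
generate_protocol_dataset <- function(repetitions = 4, hold_s = 3, rest_s = 2,
                                      sampling_rate_hz = 1000,
                                      baseline_std = 0.05, snr_scale = 1,
                                      activation = default_activation_matrix(),
                                      bandpass = NULL, seed = 1) {
  if (repetitions < 1) abort("`repetitions` must be >= 1.")
  withr::with_seed(seed, {
    sequence <- sample(rep(motion_classes()$code, repetitions))
    generate_recording(
      sequence, hold_s = hold_s, rest_s = rest_s,
      sampling_rate_hz = sampling_rate_hz, baseline_std = baseline_std,
      snr_scale = snr_scale, activation = activation, bandpass = bandpass,
      seed = NULL
    )
  })
}
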