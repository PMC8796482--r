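# Independent literal-loop implementations of the five time-domain
# features, used as oracles against the package's vectorized versions.

oracle_p <- function(i, L) if (i >= 0.2 * L && i <= 0.8 * L) 0.75 else 0.50

oracle_emav <- function(x) {
  L <- length(x)
  s <- 0
  for (i in seq_len(L)) s <- s + abs(x[i])^oracle_p(i, L)
  s / L
}

oracle_ewl <- function(x) {
  L <- length(x)
  s <- 0
  for (i in 2:L) s <- s + abs(x[i] - x[i - 1])^oracle_p(i, L)
  s
}

oracle_ssc <- function(x, threshold = 0) {
  L <- length(x)
  s <- 0
  for (i in 2:(L - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= threshold) s <- s + 1
  }
  s / L
}

oracle_rms <- function(x) {
  L <- length(x)
  s <- 0
  for (i in seq_len(L)) s <- s + x[i]^2
  sqrt(s / L)
}

oracle_var <- function(x) {
  L <- length(x)
  s <- 0
  for (i in seq_len(L)) s <- s + x[i]^2
  s / (L - 1)
}

# Well-separated Gaussian blobs for classifier checks.
make_blobs <- function(n_per_class = 50, centers = list(c(-3, -3), c(3, 3)),
                       sd = 0.5, seed = 42) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(centers, function(mu) {
      cbind(rnorm(n_per_class, mu[1], sd), rnorm(n_per_class, mu[2], sd))
    }))
    colnames(X) <- c("x1", "x2")
    list(X = X, y = rep(seq_along(centers), each = n_per_class))
  })
}

# Two classes whose pooled covariance (m - C denominator) is exactly the
# identity, with means mu1 = (1,0) and mu2 = (0,1) and equal priors.
make_identity_lda_data <- function() {
  a <- sqrt(1.5)
  offsets <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  X <- rbind(
    sweep(offsets, 2, c(1, 0), "+"),
    sweep(offsets, 2, c(0, 1), "+")
  )
  colnames(X) <- c("x1", "x2")
  list(X = X, y = rep(1:2, each = 4))
}

# Small fast generator settings for end-to-end tests.
tiny_protocol <- function(seed, repetitions = 1, hold_s = 1, rest_s = 0.5,
                          snr_scale = 1) {
  generate_protocol_dataset(
    repetitions = repetitions, hold_s = hold_s, rest_s = rest_s,
    snr_scale = snr_scale, seed = seed
  )
}
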