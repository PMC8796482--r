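#' Nonlinear conjugate-gradient minimizer (Polack-Ribiere)
#'
#' Minimizes a differentiable multivariate function by nonlinear conjugate
#' gradients with Polack-Ribiere direction updates, a line search using
#' quadratic and cubic polynomial interpolation/extrapolation with the
#' Wolfe-Powell stopping conditions, and slope-ratio initial step guesses.
#' This is the classic batch trainer used for regularized logistic
#' regression; iterations are counted as completed line searches.
#'
#' @param par Numeric start vector.
#' @param fn Function of the parameter vector returning
#'   `list(cost = <scalar>, grad = <vector>)`.
#' @param max_iter Maximum number of line searches (default 150).
#' @param ... Extra arguments passed on to `fn`.
#' @return `list(par, cost = <final cost>, trace = <cost per iteration>,
#'   n_iter)`.
#' @examples
#' quad <- function(x) list(cost = sum((x - 1:2)^2), grad = 2 * (x - 1:2))
#' cg_minimize(c(0, 0), quad)$par
#' @export
cg_minimize <- function(par, fn, max_iter = 150, ...) {
  INT <- 0.1   # don't reevaluate within 10% of the current bracket
  EXT <- 3     # extrapolate at most 3x the current bracket
  MAXEV <- 20  # max evaluations per line search
  RATIO <- 100 # maximum allowed slope ratio
  SIG <- 0.1   # Wolfe-Powell curvature constant
  RHO <- SIG / 2

  i <- 0
  ls_failed <- FALSE
  ev <- fn(par, ...)
  f1 <- ev$cost; df1 <- ev$grad
  trace <- f1
  s <- -df1
  d1 <- -sum(s * s)
  z1 <- 1 / (1 - d1)

  while (i < max_iter) {
    i <- i + 1
    X0 <- par; f0 <- f1; df0 <- df1
    par <- par + z1 * s
    ev <- fn(par, ...)
    f2 <- ev$cost; df2 <- ev$grad
    d2 <- sum(df2 * s)
    f3 <- f1; d3 <- d1; z3 <- -z1
    M <- MAXEV
    success <- FALSE
    limit <- -1

    repeat {
      while ((f2 > f1 + z1 * RHO * d1 || d2 > -SIG * d1) && M > 0) {
        limit <- z1 # tighten the bracket
        if (f2 > f1) {
          z2 <- z3 - (0.5 * d3 * z3 * z3) / (d3 * z3 + f2 - f3) # quadratic fit
        } else {
          A <- 6 * (f2 - f3) / z3 + 3 * (d2 + d3) # cubic fit
          B <- 3 * (f3 - f2) - z3 * (d3 + 2 * d2)
          disc <- B * B - A * d2 * z3 * z3
          z2 <- if (disc < 0) NaN else (sqrt(disc) - B) / A
        }
        if (!is.finite(z2)) z2 <- z3 / 2 # bisect on numerical trouble
        z2 <- max(min(z2, INT * z3), (1 - INT) * z3)
        z1 <- z1 + z2
        par <- par + z2 * s
        ev <- fn(par, ...)
        f2 <- ev$cost; df2 <- ev$grad
        M <- M - 1
        d2 <- sum(df2 * s)
        z3 <- z3 - z2
      }
      if (f2 > f1 + z1 * RHO * d1 || d2 > -SIG * d1) break # failure
      if (d2 > SIG * d1) { success <- TRUE; break }        # Wolfe-Powell met
      if (M == 0) break
      # cubic extrapolation
      A <- 6 * (f2 - f3) / z3 + 3 * (d2 + d3)
      B <- 3 * (f3 - f2) - z3 * (d3 + 2 * d2)
      disc <- B * B - A * d2 * z3 * z3
      z2 <- if (disc < 0) NaN else -d2 * z3 * z3 / (B + sqrt(disc))
      if (!is.finite(z2) || z2 < 0) {
        z2 <- if (limit < -0.5) z1 * (EXT - 1) else (limit - z1) / 2
      } else if (limit > -0.5 && z2 + z1 > limit) {
        z2 <- (limit - z1) / 2
      } else if (limit < -0.5 && z2 + z1 > z1 * EXT) {
        z2 <- z1 * (EXT - 1)
      } else if (z2 < -z3 * INT) {
        z2 <- -z3 * INT
      } else if (limit > -0.5 && z2 < (limit - z1) * (1 - INT)) {
        z2 <- (limit - z1) * (1 - INT)
      }
      f3 <- f2; d3 <- d2; z3 <- -z2
      z1 <- z1 + z2
      par <- par + z2 * s
      ev <- fn(par, ...)
      f2 <- ev$cost; df2 <- ev$grad
      M <- M - 1
      d2 <- sum(df2 * s)
    }

    if (success) {
      f1 <- f2
      trace <- c(trace, f1)
      # Polack-Ribiere direction update
      s <- (sum(df2 * df2) - sum(df1 * df2)) / sum(df1 * df1) * s - df2
      df1 <- df2
      d2 <- sum(df1 * s)
      if (d2 > 0) { # direction not a descent direction: restart steepest
        s <- -df1
        d2 <- -sum(s * s)
      }
      z1 <- z1 * min(RATIO, d1 / (d2 - .Machine$double.xmin)) # slope ratio
      d1 <- d2
      ls_failed <- FALSE
    } else {
      par <- X0; f1 <- f0; df1 <- df0 # restore best point
      if (ls_failed) break            # two consecutive failures: give up
      s <- -df1                       # retry with steepest descent
      d1 <- -sum(s * s)
      z1 <- 1 / (1 - d1)
      ls_failed <- TRUE
    }
  }

  list(par = par, cost = f1, trace = trace, n_iter = i)
}
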