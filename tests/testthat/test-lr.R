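test_that("sigmoid is symmetric, saturating and stable", {
  expect_equal(sigmoid(0), 0.5)
  expect_lt(abs(sigmoid(50) - 1), 1e-15)
  expect_lt(abs(sigmoid(-50)), 1e-15)
  z <- c(-700, -5, 0.3, 5, 700)
  expect_equal(sigmoid(z) + sigmoid(-z), rep(1, 5))
  expect_true(all(sigmoid(c(-1e308, 1e308)) %in% c(0, 1)))
})

test_that("cost at zero parameters on balanced labels is exactly log(2)", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40), 10, 4)
    y <- rep(c(0, 1), 5)
    out <- lr_cost_grad(rep(0, 4), 0, X, y, lambda = 0)
    expect_equal(out$cost, log(2))
    expect_equal(out$grad0, 0) # balanced residuals cancel
  })
})

test_that("gradient matches central finite differences", {
  withr::with_seed(2, {
    X <- matrix(rnorm(40), 10, 4)
    y <- rbinom(10, 1, 0.5)
    theta <- rnorm(4); theta0 <- rnorm(1); lambda <- 0.7
    out <- lr_cost_grad(theta, theta0, X, y, lambda)
    h <- 1e-6
    num0 <- (lr_cost_grad(theta, theta0 + h, X, y, lambda)$cost -
             lr_cost_grad(theta, theta0 - h, X, y, lambda)$cost) / (2 * h)
    expect_lt(abs(num0 - out$grad0), 1e-6)
    for (j in 1:4) {
      e <- rep(0, 4); e[j] <- h
      num <- (lr_cost_grad(theta + e, theta0, X, y, lambda)$cost -
              lr_cost_grad(theta - e, theta0, X, y, lambda)$cost) / (2 * h)
      expect_lt(abs(num - out$grad[j]), 1e-6)
    }
  })
})

test_that("cost/grad validate inputs", {
  X <- matrix(0, 4, 2)
  expect_error(lr_cost_grad(c(0, 0), 0, X, c(0, 1, 2, 0)), "binary")
  expect_error(lr_cost_grad(c(0, 0, 0), 0, X, rep(0:1, 2)), "length")
  expect_error(lr_cost_grad(c(0, 0), 0, X, rep(0:1, 2), lambda = -1), "non-negative")
})

test_that("conjugate-gradient minimizer solves quadratics and descends monotonically", {
  quad <- function(x) {
    d <- x - c(3, -2, 0.5)
    list(cost = sum(d^2 * c(1, 10, 100)), grad = 2 * d * c(1, 10, 100))
  }
  res <- cg_minimize(c(0, 0, 0), quad, max_iter = 100)
  expect_equal(res$par, c(3, -2, 0.5), tolerance = 1e-6)
  expect_true(all(diff(res$trace) <= 1e-12)) # line search enforces descent
})

test_that("training separates blobs perfectly and matches a reference optimizer", {
  blobs <- make_blobs(n_per_class = 50)
  model <- train_lr_ova(blobs$X, blobs$y, lambda = 0.01, max_iter = 150)
  pred <- predict(model, blobs$X)
  expect_equal(mean(pred == blobs$y), 1.0)

  # final cost within 1e-6 relative of BFGS on the same standardized data
  Xs <- scale(blobs$X)
  for (k in 1:2) {
    yb <- as.numeric(blobs$y == k)
    ref <- optim(
      rep(0, 3),
      fn = function(p) lr_cost_grad(p[-1], p[1], Xs, yb, 0.01)$cost,
      gr = function(p) {
        g <- lr_cost_grad(p[-1], p[1], Xs, yb, 0.01)
        c(g$grad0, g$grad)
      },
      method = "BFGS", control = list(maxit = 1000, reltol = 1e-14)
    )
    expect_lt(abs(model$costs[k] - ref$value) / ref$value, 1e-6)
  }
})

test_that("cost trace over conjugate-gradient iterations is non-increasing", {
  blobs <- make_blobs(n_per_class = 30, sd = 2, seed = 9)
  Xs <- scale(blobs$X)
  yb <- as.numeric(blobs$y == 1)
  obj <- function(p) {
    g <- lr_cost_grad(p[-1], p[1], Xs, yb, 0.5)
    list(cost = g$cost, grad = c(g$grad0, g$grad))
  }
  res <- cg_minimize(rep(0, 3), obj, max_iter = 150)
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("heavy regularization shrinks the weights toward zero", {
  blobs <- make_blobs(n_per_class = 40, seed = 5)
  norms <- vapply(c(0, 0.01, 1, 100, 1e5), function(l) {
    m <- train_lr_ova(blobs$X, blobs$y, lambda = l)
    sqrt(sum(m$theta[, 1]^2))
  }, numeric(1))
  expect_lt(norms[5], 0.05)
  expect_true(all(diff(norms) <= 1e-8)) # non-increasing in lambda
})

test_that("single-class input and non-finite features error", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_lr_ova(X, rep(1, 10)), "at least 2 classes")
  X[1, 1] <- NA
  expect_error(train_lr_ova(X, rep(1:2, 5)), "non-finite")
})

test_that("duplicated features leave regularized predictions unchanged", {
  blobs <- make_blobs(n_per_class = 40, seed = 13)
  m1 <- train_lr_ova(blobs$X, blobs$y, lambda = 1)
  m2 <- train_lr_ova(cbind(blobs$X, blobs$X), blobs$y, lambda = 1)
  expect_equal(
    predict(m2, cbind(blobs$X, blobs$X)),
    predict(m1, blobs$X)
  )
})

test_that("per-class probabilities are invariant to affine feature rescaling", {
  blobs <- make_blobs(n_per_class = 40, seed = 21)
  m1 <- train_lr_ova(blobs$X, blobs$y, lambda = 0.1)
  X2 <- sweep(sweep(blobs$X, 2, c(100, 0.01), "*"), 2, c(-5, 3), "+")
  m2 <- train_lr_ova(X2, blobs$y, lambda = 0.1)
  expect_equal(
    predict(m1, blobs$X, type = "prob"),
    predict(m2, X2, type = "prob"),
    tolerance = 1e-5, ignore_attr = TRUE
  )
})

test_that("binary threshold rule sends the boundary to class 1", {
  expect_equal(lr_decide_binary(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
  expect_equal(lr_decide_binary(0.3, th = 0.3), 1L)
  expect_error(lr_decide_binary(0.5, th = 1), "strictly")
})

test_that("prediction ties break toward the lowest class index", {
  model <- structure(
    list(
      classes = 1:2,
      theta = matrix(0, 2, 2), theta0 = c(0, 0),
      lambda = 0, th = 0.5, center = c(0, 0), scale = c(1, 1),
      feature_names = c("x1", "x2")
    ),
    class = "emg_lr"
  )
  x <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  p <- predict(model, x, type = "prob")
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_equal(predict(model, x), 1L)
  expect_error(predict(model, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("a held-out point deep inside a blob gets high probability", {
  blobs <- make_blobs(n_per_class = 50, seed = 31)
  model <- train_lr_ova(blobs$X, blobs$y, lambda = 0.01)
  x_new <- matrix(c(-3, -3), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(predict(model, x_new), 1L)
  expect_gt(predict(model, x_new, type = "prob")[1, "1"], 0.9)
})
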