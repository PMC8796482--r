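test_that("per-class splitting follows the floor rule and policies", {
  feats <- tibble::tibble(
    f1 = rnorm(100), label = "F", timestamp_s = seq(0.15, by = 0.05, length.out = 100)
  )
  sp <- split_train_test(feats)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  # contiguous: chronologically first 70 go to training
  expect_true(max(sp$train$timestamp_s) < min(sp$test$timestamp_s))

  feats10 <- tibble::tibble(f1 = rnorm(10), label = "E",
                            timestamp_s = seq_len(10) * 0.05)
  sp10 <- split_train_test(feats10, train_fraction = 0.7)
  expect_equal(nrow(sp10$train), 7) # floor(0.7 * 10)
  expect_equal(nrow(sp10$test), 3)

  sh1 <- split_train_test(feats, policy = "shuffled", seed = 7)
  sh2 <- split_train_test(feats, policy = "shuffled", seed = 7)
  expect_identical(sh1$train$f1, sh2$train$f1)

  expect_error(split_train_test(feats, train_fraction = 1), "strictly")
  tiny <- tibble::tibble(f1 = 1, label = "P", timestamp_s = 0.15)
  expect_error(split_train_test(tiny), "at least 2 windows")
})

test_that("F1 arithmetic matches the hand-computed example", {
  cm <- confusion_matrix(rep(1:3, c(10, 10, 10)),
                         c(rep(1, 8), 2, 2, 1, rep(2, 9), rep(3, 10)))
  expect_equal(as.vector(as.matrix(cm)[1, ]), c(8, 2, 0))
  f <- f1_per_class(cm)
  p1 <- 8 / 9; r1 <- 8 / 10
  expect_equal(f$f1[1], 2 * p1 * r1 / (p1 + r1), tolerance = 1e-12) # ~0.8421
  expect_equal(misclassification_error(cm), 1 - 27 / 30)

  diag_cm <- confusion_matrix(rep(1:3, 5), rep(1:3, 5))
  expect_equal(f1_per_class(diag_cm)$f1, rep(1, 3))
  expect_equal(macro_f1(diag_cm), 1)
  expect_equal(misclassification_error(diag_cm), 0)
})

test_that("a class never predicted and never correct scores F1 = 0", {
  cm <- matrix(c(5, 0, 3, 0), 2, 2, dimnames = list(true = 1:2, predicted = 1:2))
  f <- f1_per_class(cm)
  expect_equal(f$f1[2], 0)
  expect_error(f1_per_class(matrix(0, 2, 2)), "all zeros")
})

test_that("confusion normalization is row-stochastic and argmax-preserving", {
  m <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2))
  nm <- normalize_confusion(m)
  expect_equal(unname(rowSums(as.matrix(nm))), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(as.matrix(nm)), rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(
    apply(as.matrix(m), 1, which.max),
    apply(as.matrix(nm), 1, which.max)
  )
  z <- matrix(c(2, 0, 0, 0), 2, 2, dimnames = list(true = 1:2, predicted = 1:2))
  expect_warning(nz <- normalize_confusion(z), "Zero-support")
  expect_equal(unname(as.matrix(nz)[2, ]), c(0, 0))
})

test_that("attempt metrics reproduce hand-computed decision timelines", {
  times <- 0.15 + (0:19) * 0.09
  all_ok <- attempt_metrics(rep(TRUE, 20), times)
  expect_equal(all_ok$mst_s, 0.15)
  expect_equal(all_ok$mct_s, 0.15 + 9 * 0.09) # 0.96
  expect_true(all_ok$completed)

  late <- attempt_metrics(c(FALSE, FALSE, rep(TRUE, 18)), times)
  expect_equal(late$mst_s, 0.33)
  expect_equal(late$mct_s, 1.14)
  expect_true(late$completed)

  only9 <- attempt_metrics(c(rep(TRUE, 9), rep(FALSE, 11)), times)
  expect_false(only9$completed)
  expect_true(is.na(only9$mct_s))
  expect_equal(only9$mst_s, 0.15)

  never <- attempt_metrics(rep(FALSE, 20), times)
  expect_true(is.na(never$mst_s) && is.na(never$mct_s) && !never$completed)

  # a 10th correct after the 5 s deadline fails the attempt
  long_t <- 0.15 + (0:59) * 0.09
  sparse <- rep(c(TRUE, rep(FALSE, 5)), 10)
  res <- attempt_metrics(sparse, long_t)
  expect_false(res$completed)
  expect_true(is.na(res$mct_s))
})

test_that("consecutive counting mode requires an unbroken run", {
  times <- 0.15 + (0:29) * 0.09
  correct <- c(rep(TRUE, 9), FALSE, rep(TRUE, 20))
  cum <- attempt_metrics(correct, times, counting = "cumulative")
  con <- attempt_metrics(correct, times, counting = "consecutive")
  expect_equal(cum$mct_s, times[11]) # 10th correct overall
  expect_equal(con$mct_s, times[20]) # 10th of the unbroken run
  expect_true(con$mst_s <= con$mct_s)
})

test_that("the stream simulator emits decisions at W + (k-1)*delta and scores them", {
  rec <- tiny_protocol(seed = 20, hold_s = 0.8)
  feats <- rec |> segment_windows() |> extract_features()
  model <- train_parallel(feats, algorithm = "lda")

  att <- generate_recording("FOS", hold_s = 2, rest_s = 0, seed = 77)
  res <- simulate_realtime(model, att, "FOS")
  # 2 s at 1 kHz: decisions at 0.15, 0.24, ..., <= 2.0 -> 21 decisions
  expect_equal(res$n_predictions, 21)
  expect_equal(res$mst_s, 0.15)
  expect_equal(res$mct_s, 0.96)
  expect_true(res$completed)

  short <- generate_recording("F", hold_s = 0.1, rest_s = 0, seed = 78)
  expect_error(simulate_realtime(model, short, "F"), "shorter than one")
})

test_that("completion-rate arithmetic", {
  res <- tibble::tibble(completed = rep(c(TRUE, FALSE), c(27, 27)))
  expect_equal(motion_completion_rate(res), 50)
  expect_equal(motion_completion_rate(tibble::tibble(completed = rep(TRUE, 54))), 100)
  expect_equal(motion_completion_rate(tibble::tibble(completed = rep(FALSE, 10))), 0)
  expect_error(motion_completion_rate(tibble::tibble(completed = logical(0))), "No attempts")
})

test_that("Mann-Whitney U with eta-squared matches closed forms and the reference", {
  same <- mann_whitney_eta2(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$z, 0)
  expect_equal(same$eta_squared, 0)
  expect_equal(same$p_value, 1)

  sep <- mann_whitney_eta2(1:15, 101:115)
  expect_equal(sep$u, 0)
  expect_equal(abs(sep$z), 112.5 / sqrt(581.25), tolerance = 1e-12) # ~4.666
  expect_equal(sep$eta_squared, sep$z^2 / 30, tolerance = 1e-12)    # ~0.726

  withr::with_seed(123, {
    for (i in 1:10) {
      a <- rnorm(sample(5:30, 1))
      b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
      ours <- mann_whitney_eta2(a, b)
      ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
      expect_equal(ours$u, unname(ref$statistic))
      ours_cc <- mann_whitney_eta2(a, b, continuity = TRUE)
      ref_cc <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
      expect_equal(ours_cc$p_value, ref_cc$p.value, tolerance = 1e-6)
    }
  })
  expect_error(mann_whitney_eta2(1, 1:5), "at least 2")
})

test_that("eta-squared is invariant under strictly monotone transforms", {
  withr::with_seed(55, {
    a <- rnorm(12, 1); b <- rnorm(18)
    base <- mann_whitney_eta2(a, b)$eta_squared
    expect_equal(mann_whitney_eta2(exp(a), exp(b))$eta_squared, base)
    expect_equal(mann_whitney_eta2(a^3, b^3)$eta_squared, base)
    expect_equal(mann_whitney_eta2(2 * a + 5, 2 * b + 5)$eta_squared, base)
  })
})
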