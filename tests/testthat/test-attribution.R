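linear_model <- function(n_feat = 5, classes = c("A", "B"), seed = 9) {
  X <- matrix(stats::rnorm(3 * n_feat), 3, n_feat)
  coo_net(list(f = X), c("A", "B", "A"),
          hyperparams = list(hyperparams(n_layers = 0, dropout = 0)),
          schedule = training_schedule(epochs = 0), seed = seed)
}

test_that("integrated gradients recover w_j * x_j exactly for a linear scorer", {
  set.seed(21)
  fit <- linear_model()
  X <- matrix(stats::rnorm(20), 4, 5)
  for (steps in c(1L, 7L)) {
    ig <- integrated_gradients(fit, list(f = X), steps = steps)
    ci <- match(ig$target_class, fit$classes)
    exact <- X * t(fit$head$W[, ci])
    expect_equal(ig$attributions$f, exact, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the zero baseline input receives zero attribution", {
  fit <- linear_model(seed = 3)
  ig <- integrated_gradients(fit, list(f = matrix(0, 2, 5)), steps = 20)
  expect_true(all(ig$attributions$f == 0))
})

test_that("attribution completeness improves with more interpolation steps", {
  set.seed(14)
  X <- rbind(matrix(stats::rnorm(40 * 6), ncol = 6),
             matrix(stats::rnorm(40 * 6, 1.5), ncol = 6))
  y <- rep(c("A", "B"), each = 40)
  fit <- coo_net(list(f = X), y,
                 hyperparams = list(hyperparams(n_layers = 2, n_nodes = 10,
                                                dropout = 0.1)),
                 schedule = training_schedule(epochs = 25), seed = 5)
  x1 <- list(f = X[3, , drop = FALSE])
  net <- list(blocks = fit$blocks, head = fit$head)
  errs <- vapply(c(5L, 50L, 300L), function(steps) {
    ig <- integrated_gradients(fit, x1, steps = steps)
    ci <- match(ig$target_class, fit$classes)
    delta <- mutorigin:::net_forward(net, x1)$logits[1, ci] -
      mutorigin:::net_forward(net, list(f = x1$f * 0))$logits[1, ci]
    abs(sum(ig$attributions$f) - delta) / max(abs(delta), 1e-9)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 1e-9)
})

test_that("class means average correctly and ignore sample order", {
  m <- rbind(c(1, 2), c(3, 4), c(-1, -2))
  lab <- c("A", "A", "B")
  cm <- class_mean_attributions(m, lab)
  expect_equal(unname(cm["A", ]), c(2, 3))
  expect_equal(unname(cm["B", ]), c(-1, -2))
  expect_equal(attr(cm, "stage"), "raw_mean")
  perm <- c(3, 1, 2)
  expect_equal(unclass(class_mean_attributions(m[perm, ], lab[perm])),
               unclass(cm))
  # opposite attributions cancel
  cm2 <- class_mean_attributions(rbind(c(5, -3), c(-5, 3)), c("A", "A"))
  expect_equal(unname(cm2["A", ]), c(0, 0))
  # per-fold averaging weighs folds equally
  cm3 <- class_mean_attributions(rbind(1, 2, 6), rep("A", 3),
                                 fold = c(1, 1, 2))
  expect_equal(unname(cm3["A", 1]), mean(c(mean(c(1, 2)), 6)))
  expect_warning(class_mean_attributions(m, lab, classes = c("A", "B", "C")),
                 "no samples")
})

test_that("log-modulus is odd, monotone and hits its closed-form values", {
  expect_equal(log_modulus(0), 0)
  expect_equal(log_modulus(exp(1) - 1), 1)
  expect_equal(log_modulus(-(exp(1) - 1)), -1)
  v <- seq(-10, 10, length.out = 101)
  expect_equal(log_modulus(-v), -log_modulus(v))
  expect_true(all(diff(log_modulus(v)) > 0))
})

test_that("scaling maps extremes to +-1, keeps zeros, and is scale-invariant", {
  m <- matrix(c(2, -4, 0, 1), 2, 2)
  sc <- scale_attributions(m)
  expect_equal(as.numeric(sc), c(1, -1, 0, 0.5))
  expect_equal(attr(sc, "stage"), "scaled")
  sc2 <- scale_attributions(2 * m)
  expect_equal(as.numeric(sc2), as.numeric(sc))
  # all-positive matrices span (0, 1] with max exactly 1
  mp <- matrix(c(0.2, 0.5, 1.7, 3.2), 2, 2)
  scp <- scale_attributions(mp)
  expect_equal(max(scp), 1)
  expect_true(all(scp > 0 & scp <= 1))
  # literal formula mode flips negatives positive
  scl <- scale_attributions(m, formula_literal = TRUE)
  expect_equal(scl[2, 1], 1)
  expect_warning(z <- scale_attributions(matrix(0, 2, 2)), "no non-zero")
  expect_true(all(z == 0))
})

test_that("top features are ranked per class, unioned, and zero-excluded", {
  m <- structure(rbind(A = c(5, 0, 1, -3), B = c(-4, 0, 2, 1)),
                 dimnames = list(c("A", "B"), paste0("f", 1:4)))
  expect_equal(top_features(m, k = 1), "f1")
  expect_equal(top_features(m, k = 2), c("f1", "f3", "f4"))
  # all-zero feature f2 is never selected even with large k
  expect_warning(all_k <- top_features(m, k = 10), "capped")
  expect_false("f2" %in% all_k)
  # a feature top-ranked in both classes appears once
  expect_equal(sum(top_features(m, k = 1) == "f1"), 1L)
})

test_that("display orderings derive from the reference matrix per class", {
  ref <- rbind(A = c(3, 1, 2), B = c(-1, 5, 0))
  colnames(ref) <- c("x", "y", "z")
  ord <- feature_display_order(ref)
  expect_equal(ord$A, c(1L, 3L, 2L))
  expect_equal(ord$B, c(2L, 3L, 1L))
})
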