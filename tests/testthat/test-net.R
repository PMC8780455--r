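gaussian_classes <- function(n_per, means, p = 10, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(means, function(m)
    matrix(stats::rnorm(n_per * p, mean = m), n_per, p)))
  list(x = list(f = X), y = rep(names(means), each = n_per))
}

test_that("architectures wire to the stated widths", {
  dims <- c(bins = 2897L, tri = 96L, drivers = 20L)
  hp1 <- hyperparams(n_layers = 1, n_nodes = 32)
  early <- mutorigin:::build_network(
    integration_spec("early", list(hp1)), dims, 16L)
  expect_equal(nrow(early$blocks$b1$layers[[1]]$W), 3013L)
  expect_equal(ncol(early$head$W), 16L)

  mb <- mutorigin:::build_network(
    integration_spec("multi_branch", list(hp1, hp1, hp1)), dims, 16L)
  expect_length(mb$blocks, 3L)
  expect_equal(nrow(mb$head$W), 96L) # 3 branches x 32 nodes concatenated

  cons <- mutorigin:::build_network(
    integration_spec("consecutive", list(hp1, hp1, hp1)), dims, 16L)
  expect_length(cons$blocks, 3L)
  expect_equal(cons$blocks$b2$in_dim, 32L + 96L)
  expect_equal(cons$blocks$b3$in_dim, 32L + 20L)
  expect_equal(cons$head$inputs, "b3")

  # one feature set degenerates to the single-input architecture
  single <- mutorigin:::build_network(
    integration_spec("early", list(hp1)), c(bins = 2897L), 16L)
  expect_equal(nrow(single$blocks$b1$layers[[1]]$W), 2897L)

  expect_error(mutorigin:::build_network(
    integration_spec("multi_branch", list(hp1)), dims, 16L),
    "hyperparameter set")
})

test_that("backpropagated input gradients match finite differences", {
  set.seed(5)
  x <- list(a = matrix(rnorm(8), 2, 4), b = matrix(rnorm(6), 2, 3))
  fit <- coo_net(x, c("u", "v"), architecture = "consecutive",
                 hyperparams = list(hyperparams(n_layers = 1, n_nodes = 5,
                                                dropout = 0, activation = "tanh"),
                                    hyperparams(n_layers = 1, n_nodes = 4,
                                                dropout = 0, activation = "elu")),
                 schedule = training_schedule(epochs = 0), seed = 2)
  g <- input_gradients(fit, x, class_index = 1)
  eps <- 1e-5
  for (fs in c("a", "b")) {
    for (j in seq_len(ncol(x[[fs]]))) {
      xp <- x; xp[[fs]][1, j] <- xp[[fs]][1, j] + eps
      xm <- x; xm[[fs]][1, j] <- xm[[fs]][1, j] - eps
      net <- list(blocks = fit$blocks, head = fit$head)
      num <- (mutorigin:::net_forward(net, xp)$logits[1, 1] -
                mutorigin:::net_forward(net, xm)$logits[1, 1]) / (2 * eps)
      expect_equal(g[[fs]][1, j], num, tolerance = 1e-6)
    }
  }
})

test_that("a separable two-class problem is learned across seeds", {
  for (seed in 1:5) {
    d <- gaussian_classes(100, c(A = 0, B = 2), seed = seed)
    fit <- coo_net(d$x, d$y,
                   hyperparams = list(hyperparams(n_layers = 1, n_nodes = 16)),
                   seed = seed)
    acc <- mean(predict(fit, d$x, type = "class") == d$y)
    expect_gte(acc, 0.95)
  }
})

test_that("zero epochs returns the initialized model at chance accuracy", {
  d <- gaussian_classes(60, c(A = 0, B = 0, C = 0, D = 0), seed = 3)
  fit <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 0), seed = 4)
  expect_equal(nrow(fit$history), 0L)
  acc <- mean(predict(fit, d$x, type = "class") == d$y)
  expect_lt(abs(acc - 0.25), 0.15)
})

test_that("training is deterministic given the seed", {
  d <- gaussian_classes(50, c(A = 0, B = 1), seed = 9)
  f1 <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 5), seed = 7)
  f2 <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 5), seed = 7)
  expect_identical(f1$head$W, f2$head$W)
  expect_identical(f1$history, f2$history)
  f3 <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 5), seed = 8)
  expect_false(identical(f1$head$W, f3$head$W))
})

test_that("predictions are normalized and top-k ranked with index tie-breaks", {
  d <- gaussian_classes(40, c(A = 0, B = 1, C = 2), seed = 2)
  fit <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 3), seed = 1)
  pr <- predict(fit, d$x, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  tk <- predict(fit, d$x, type = "topk", k = 3)
  expect_equal(ncol(tk), 3L)
  for (i in c(1, 40, 120))
    expect_equal(tk[i, ], colnames(pr)[order(-pr[i, ], seq_len(3))])
  expect_true(all(apply(tk, 1, function(r) setequal(r, c("A", "B", "C")))))
  expect_error(predict(fit, d$x, type = "topk", k = 0), "k must be")
  # exact ranking on a constructed probability row
  expect_equal(order(-c(0.5, 0.3, 0.2), 1:3)[1:2], c(1L, 2L))
})

test_that("mismatched input widths are rejected", {
  d <- gaussian_classes(30, c(A = 0, B = 1), seed = 6)
  fit <- coo_net(d$x, d$y, schedule = training_schedule(epochs = 1), seed = 1)
  bad <- list(f = matrix(0, 2, 7))
  expect_error(predict(fit, bad), "widths")
  expect_error(coo_net(list(f = matrix(0, 4, 2)), c("a", "b", "a"),
                       schedule = training_schedule(epochs = 1)),
               "length")
})
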