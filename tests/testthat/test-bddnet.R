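tiny_config <- function(...) {
  args <- list(n_features = 40, conv_filters = c(2, 3, 4),
               bilstm_layers = 2, bilstm_units = 3, rbm_units = c(6, 4),
               dropout = 0, step = 20, pretrain = FALSE, epochs = 5,
               batch_size = 4, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(bddnet_config, args)
}

scaled_params <- function(cfg, X) {
  p <- bddnet_init(cfg)
  p$scale <- eegstress:::fit_scale(X)
  p
}

test_that("softmax, ReLU and batch-norm obey their defining identities", {
  expect_equal(drop(eegstress:::softmax_rows(matrix(c(0, 0), 1))),
               c(0.5, 0.5))
  set.seed(1)
  Z <- matrix(rnorm(40), 8, 5)
  P <- eegstress:::softmax_rows(Z)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-9)
  expect_equal(eegstress:::relu_forward(array(c(-3.2, 1.5), c(1, 2, 1)))$out,
               array(c(0, 1.5), c(1, 2, 1)))
  # identical inputs through train-mode BN with unit scale, zero offset
  Y <- array(5, c(4, 3, 2))
  bn <- eegstress:::bn_forward(Y, gamma = c(1, 1), beta = c(0, 0),
                               run_mean = c(0, 0), run_var = c(1, 1),
                               mode = "train")
  expect_lt(max(abs(bn$out)), 1e-9)
  expect_equal(drop(eegstress:::sigmoid(0)), 0.5)
})

test_that("a zero-weight belief stack outputs one half everywhere", {
  rbms <- list(list(W = matrix(0, 5, 3), b = numeric(5), c = numeric(3)))
  out <- eegstress:::dbn_forward(matrix(rnorm(10), 2, 5), rbms)$out
  expect_true(all(out == 0.5))  # p(h=1|v) with zero couplings
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- tiny_config()
  X <- matrix(rnorm(5 * 40), 5, 40)
  params <- scaled_params(cfg, X)
  Y <- matrix(0, 5, 2)
  Y[cbind(1:5, c(1, 2, 1, 2, 2))] <- 1
  lg <- eegstress:::bddnet_loss_grads(params, X, Y, mode = "train")
  check_leaf <- function(get, set, analytic, eps = 1e-5) {
    w <- get(params$net)
    idx <- seq_len(min(length(w), 25L))
    num <- vapply(idx, function(i) {
      p2 <- params
      wp <- w; wp[i] <- w[i] + eps
      p2$net <- set(params$net, wp)
      lp <- eegstress:::bddnet_loss_grads(p2, X, Y, mode = "train")$loss
      wp[i] <- w[i] - eps
      p2$net <- set(params$net, wp)
      lm <- eegstress:::bddnet_loss_grads(p2, X, Y, mode = "train")$loss
      (lp - lm) / (2 * eps)
    }, numeric(1))
    a <- c(analytic)[idx]
    max(abs(num - a) / pmax(abs(num) + abs(a), 1e-6))
  }
  expect_lt(check_leaf(function(n) n$fc$W,
                       function(n, w) { n$fc$W <- w; n },
                       lg$grads$fc$W), 1e-4)
  expect_lt(check_leaf(function(n) n$conv[[1]]$W,
                       function(n, w) { n$conv[[1]]$W <- w; n },
                       lg$grads$conv[[1]]$W), 1e-4)
  expect_lt(check_leaf(function(n) n$conv[[2]]$gamma,
                       function(n, w) { n$conv[[2]]$gamma <- w; n },
                       lg$grads$conv[[2]]$gamma), 1e-4)
  expect_lt(check_leaf(function(n) n$lstm[[1]]$fwd$W,
                       function(n, w) { n$lstm[[1]]$fwd$W <- w; n },
                       lg$grads$lstm[[1]]$fwd$W), 1e-4)
  expect_lt(check_leaf(function(n) n$lstm[[2]]$bwd$b,
                       function(n, w) { n$lstm[[2]]$bwd$b <- w; n },
                       lg$grads$lstm[[2]]$bwd$b), 1e-4)
  expect_lt(check_leaf(function(n) n$rbm[[1]]$W,
                       function(n, w) { n$rbm[[1]]$W <- w; n },
                       lg$grads$rbm[[1]]$W), 1e-4)
})

test_that("training is deterministic and converges on separable features", {
  set.seed(3)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 40), n, 40)
  X[y == 1, 1:8] <- X[y == 1, 1:8] + 2.5
  cfg <- tiny_config(epochs = 50, learning_rate = 0.01)
  fit1 <- bddnet_train(X, y, cfg)
  fit2 <- bddnet_train(X, y, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_length(fit1$loss_trace, 50L)
  expect_lt(fit1$loss_trace[50], 0.1 * fit1$loss_trace[1])
  expect_gt(mean(bddnet_predict(fit1, X)$code == y), 0.95)
})

test_that("pretraining runs per layer and flags constant columns", {
  set.seed(4)
  X <- cbind(matrix(rnorm(12 * 38), 12, 38), 1, 2)  # two constant columns
  cfg <- bddnet_config(n_features = 40, rbm_units = c(6, 4), step = 20,
                       pretrain_epochs = 2, batch_size = 4)
  expect_warning(rbms <- pretrain_dbn(X, cfg), "constant")
  expect_length(rbms, 2L)
  expect_identical(dim(rbms[[1]]$W), c(40L, 6L))
  expect_identical(dim(rbms[[2]]$W), c(6L, 4L))
  expect_error(pretrain_dbn(X[1, , drop = FALSE], cfg), "2 vectors")
})

test_that("prediction ties break toward calm and ignore batch context", {
  set.seed(5)
  cfg <- tiny_config()
  X <- matrix(rnorm(6 * 40), 6, 40)
  params <- scaled_params(cfg, X)
  params$net$fc$W[] <- 0        # zero head -> exact 0.5/0.5 ties
  params$net$fc$b[] <- 0
  pred <- bddnet_predict(params, X)
  expect_equal(unname(pred$probabilities[, "calm"]), rep(0.5, 6))
  expect_true(all(pred$code == 0L))
  expect_true(all(pred$label == "calm"))
  # batch invariance of evaluation mode
  params2 <- scaled_params(cfg, X)
  alone <- bddnet_predict(params2, X[3, ])$probabilities
  batched <- bddnet_predict(params2, X)$probabilities[3, , drop = FALSE]
  expect_equal(unname(alone), unname(batched), tolerance = 1e-12)
})

test_that("invalid training inputs are rejected", {
  X <- matrix(rnorm(8 * 40), 8, 40)
  cfg <- tiny_config()
  expect_error(bddnet_train(X, rep(0, 8), cfg), "both classes")
  expect_error(bddnet_train(X, rep(0:1, 3), cfg), "length")
  expect_error(bddnet_train(X, rep(0:1, 4), tiny_config(n_features = 60)))
  expect_error(bddnet_config(n_features = 41, step = 20), "divide")
  expect_error(bddnet_config(n_features = 40, dropout = 1), "dropout")
  p <- bddnet_init(cfg)   # no fitted scaling yet
  expect_error(bddnet_forward(p, X), "untrained")
  p2 <- scaled_params(cfg, X)
  p2$net$fc$W[1, 1] <- NaN
  expect_error(bddnet_forward(p2, X), "non-finite")
  expect_error(bddnet_forward(scaled_params(cfg, X), X[, 1:10]), "match")
})
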