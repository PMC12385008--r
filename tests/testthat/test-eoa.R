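test_that("the population update follows the printed arithmetic", {
  p <- eoa_params(pop_size = 4)
  # all three potential references sit at 0.2, mover at 0.6, step 0.5:
  # proposal 0.6 + 0.5 * (0.6 - 0.2) = 0.8 in the repel (printed) form
  pos <- rbind(0.2, 0.2, 0.2, 0.6)
  # values chosen so the members at 0.2 never accept a proposal (their
  # recorded error is already below anything -x can reach), keeping every
  # possible reference for the mover at its original 0.2
  vals <- c(0, -1, -1, 1)
  set.seed(1)
  st <- eoa_step(pos, vals, function(x) -x, p, explore = TRUE, r = 0.5)
  expect_equal(st$positions[4, ], 0.8)
  expect_equal(st$values[4], -0.8)
  # zero step leaves every member in place
  st0 <- eoa_step(pos, vals, function(x) -x, p, explore = FALSE, r = 0)
  expect_equal(st0$positions, pos)
  # a member equal to the best is a fixed point of the exploit move
  pos2 <- rbind(0.4, 0.4, 0.9, 0.7)
  st2 <- eoa_step(pos2, c(0, 1, 2, 2), function(x) -x, p,
                  explore = FALSE, r = 0.5)
  expect_equal(st2$positions[2, ], 0.4)
  # the toward_reference switch flips the sign of the step
  pt <- eoa_params(pop_size = 4, toward_reference = TRUE)
  stt <- eoa_step(pos, vals, function(x) x, pt, explore = FALSE, r = 0.5)
  expect_equal(stt$positions[4, ], 0.6 - 0.5 * (0.6 - 0.2))
})

test_that("elite members pass unchanged and proposals stay in bounds", {
  p <- eoa_params(pop_size = 10, elite_frac = 0.2)
  set.seed(2)
  pos <- matrix(runif(20), 10, 2)
  vals <- apply(pos, 1, function(x) sum(x^2))
  st <- eoa_step(pos, vals, function(x) sum(x^2), p)
  elite <- order(vals)[1:2]
  expect_equal(st$positions[elite, ], pos[elite, ])
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_true(all(st$values <= vals))  # greedy acceptance only improves
})

test_that("a non-finite objective proposal is rejected with a warning", {
  p <- eoa_params(pop_size = 4)
  pos <- rbind(0.1, 0.5, 0.6, 0.7)
  vals <- c(0, 1, 1, 1)
  w <- capture_warnings(
    st <- eoa_step(pos, vals, function(x) NaN, p, explore = FALSE, r = 0.5))
  expect_true(all(grepl("non-finite", w)))  # one warning per rejected mover
  expect_length(w, 3L)
  expect_equal(st$positions, pos)
})

test_that("the optimizer recovers a known quadratic optimum", {
  hits <- vapply(1:10, function(s) {
    r <- eoa_optimize(function(x) (x - 0.3)^2, dim = 1,
                      eoa_params(pop_size = 10, iter_max = 100, seed = s))
    abs(r$best - 0.3) < 0.02
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("the best-error trace is non-increasing and seeded", {
  obj <- function(x) sum((x - 0.5)^2)
  r <- eoa_optimize(obj, 3, eoa_params(iter_max = 40, seed = 5))
  expect_false(is.unsorted(-r$trace))
  r2 <- eoa_optimize(obj, 3, eoa_params(iter_max = 40, seed = 5))
  expect_identical(r, r2)
  r0 <- eoa_optimize(obj, 3, eoa_params(iter_max = 0, seed = 5))
  expect_length(r0$trace, 0L)  # best of the random initialization
  expect_true(is.finite(r0$value))
})

test_that("decoded hyperparameters respect their bounds", {
  lo <- decode_hyperparameters(c(0, 0, 0))
  hi <- decode_hyperparameters(c(1, 1, 1))
  expect_equal(lo$learning_rate, 1e-4)
  expect_equal(hi$learning_rate, 1e-1)
  expect_equal(lo$decay, 1e-6)
  expect_equal(hi$decay, 1e-2)
  expect_equal(lo$momentum, 0.5)
  expect_equal(hi$momentum, 0.99)
  set.seed(6)
  for (i in 1:20) {
    hp <- decode_hyperparameters(runif(3))
    expect_true(hp$learning_rate >= 1e-4 && hp$learning_rate <= 1e-1)
    expect_true(hp$decay >= 1e-6 && hp$decay <= 1e-2)
    expect_true(hp$momentum >= 0.5 && hp$momentum <= 0.99)
  }
  expect_error(decode_hyperparameters(c(0.5, 0.5)), "length 3")
})

test_that("tuning beats random search on a small classifier surrogate", {
  set.seed(7)
  n <- 24; d <- 20
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 2
  cfg <- bddnet_config(d, conv_filters = c(2, 2, 2), bilstm_units = 2,
                       rbm_units = c(4, 3), step = 10, pretrain = FALSE,
                       batch_size = 8, epochs = 2, dropout = 0, seed = 9)
  sp <- local({ set.seed(1); eegstress:::stratified_indices(y, 0.25) })
  make_obj <- function() function(pos) {
    hp <- decode_hyperparameters(pos)
    c2 <- cfg
    c2$learning_rate <- hp$learning_rate
    c2$decay <- hp$decay
    c2$momentum <- hp$momentum
    fit <- bddnet_train(X[sp$train, ], y[sp$train], c2)
    mean(bddnet_predict(fit, X[sp$test, , drop = FALSE])$code != y[sp$test])
  }
  p <- eoa_params(pop_size = 5, iter_max = 4, seed = 1)
  n_evals <- p$pop_size + p$iter_max * (p$pop_size - 1)  # EOA budget
  wins <- vapply(1:10, function(s) {
    p$seed <- s
    eoa_best <- eoa_optimize(make_obj(), 3, p)$value
    set.seed(1000 + s)
    rand_best <- min(apply(matrix(runif(n_evals * 3), n_evals, 3), 1,
                           make_obj()))
    eoa_best <= rand_best
  }, logical(1))
  expect_gte(sum(wins), 7L)
})

test_that("tune_hyperparameters returns a usable tuned configuration", {
  set.seed(8)
  n <- 24; d <- 20
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 2
  cfg <- bddnet_config(d, conv_filters = c(2, 2, 2), bilstm_units = 2,
                       rbm_units = c(4, 3), step = 10, pretrain = FALSE,
                       batch_size = 8, seed = 9)
  res <- tune_hyperparameters(X, y, cfg,
                              eoa_params(pop_size = 5, iter_max = 3,
                                         seed = 2),
                              tune_epochs = 2)
  expect_s3_class(res$config, "bddnet_config")
  expect_equal(res$config$learning_rate, res$hyperparameters$learning_rate)
  expect_false(is.unsorted(-res$trace))
  expect_true(res$value >= 0)
})
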