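test_that("fitness is the weighted entropy/redundancy sum", {
  p <- icsa_params(k = 2)
  # entropy chosen so the normalized EN term is 2 / log(64) ~ 0.481;
  # off-diagonal correlation 0.4 gives redundancy term 0.6
  st <- list(entropy = c(2 / log(64), 2 / log(64), 0),
             abs_cor = matrix(c(1, 0.4, 0, 0.4, 1, 0, 0, 0, 1), 3, 3))
  fit <- channel_fitness(c(0.9, 0.8, 0.1), st, p)
  expect_equal(fit, 0.5 * 2 / log(64) + 0.5 * 0.6, tolerance = 1e-12)
  # perfectly correlated pair: redundancy term collapses to zero
  st$abs_cor[1, 2] <- st$abs_cor[2, 1] <- 1
  expect_equal(channel_fitness(c(0.9, 0.8, 0.1), st, p),
               0.5 * 2 / log(64), tolerance = 1e-12)
  # the reward orientation uses CV directly
  pr <- icsa_params(k = 2, cv_mode = "reward")
  expect_equal(channel_fitness(c(0.9, 0.8, 0.1), st, pr),
               0.5 * 2 / log(64) + 0.5 * 1, tolerance = 1e-12)
})

test_that("independent noise channels show low redundancy", {
  cvs <- vapply(1:20, function(s) {
    set.seed(s)
    ts <- trial_set(list(recording(matrix(rnorm(4 * 512), 4), 128)))
    st <- channel_stats(ts)
    mean(st$abs_cor[upper.tri(st$abs_cor)])
  }, numeric(1))
  expect_lt(mean(cvs), 0.2)
})

test_that("position decoding takes the k largest coordinates", {
  expect_identical(decode_channels(c(0.1, 0.9, 0.5, 0.7), 2), c(2L, 4L))
  expect_identical(decode_channels(c(0.5, 0.5, 0.5), 2), c(1L, 2L))  # ties
  expect_error(decode_channels(c(0.1, 0.2), 3), "exceeds")
  sel <- decode_channels(runif(30), 10)
  expect_identical(sel, sort(unique(sel)))
})

test_that("the crow step follows the aware/unaware rule", {
  p <- icsa_params(k = 1, fl = 2, ap = 0.1)
  got <- crow_step(c(0, 0), c(1, 0), p, r_i = 0.5, r_j = 0.9)
  expect_equal(got, c(1, 0))  # 0 + 0.5 * 2 * (1 - 0)
  expect_equal(crow_step(c(0.3, 0.3), c(0.3, 0.3), p,
                         r_i = 0.7, r_j = 0.9), c(0.3, 0.3))
  # awareness probability 1 always takes the random relocation branch
  p1 <- icsa_params(k = 1, ap = 1)
  set.seed(1)
  stray <- crow_step(c(0.5, 0.5), c(0.5, 0.5), p1)
  expect_false(all(stray == 0.5))
  expect_true(all(stray >= 0 & stray <= 1))
  # clamping keeps feasibility for large flight lengths
  pbig <- icsa_params(k = 1, fl = 50)
  out <- crow_step(c(0.1, 0.9), c(0.9, 0.1), pbig, r_i = 1, r_j = 0.9)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the Levy sampler has the requested tail index", {
  set.seed(12)
  draws <- abs(levy_mantegna(10000, beta = 1.5))
  top <- sort(draws, decreasing = TRUE)[1:500]
  hill <- 1 / (mean(log(top[-500])) - log(top[500]))  # Hill estimator
  expect_gt(hill, 1.3)
  expect_lt(hill, 1.7)
})

test_that("elite and worst-member updates behave at their fixed points", {
  p <- icsa_params(k = 2, flock_size = 4)
  ts <- small_trials()[1:2]
  st_stats <- channel_stats(ts)
  pos <- rbind(c(0.9, 0.8, 0.1, 0.2), c(0.9, 0.8, 0.1, 0.2),
               c(0.2, 0.3, 0.9, 0.8), c(0.5, 0.5, 0.5, 0.5))
  fit <- apply(pos, 1, channel_fitness, trials = st_stats, params = p)
  set.seed(3)
  upd <- elite_and_worst_updates(list(positions = pos, fitness = fit),
                                 st_stats, p)
  # best two identical -> LFEL proposal equals the best, never degrades it
  expect_gte(max(upd$fitness), max(fit))
  expect_equal(upd$positions[which.max(fit), ], pos[which.max(fit), ])
  # the worst crow moved onto the segment toward the best
  worst <- which.min(fit)
  moved <- upd$positions[worst, ]
  seg <- (moved - pos[worst, ]) /
    (pos[which.max(upd$fitness), ] - pos[worst, ])
  expect_lt(diff(range(seg)), 1e-9)  # collinear
  expect_true(all(seg >= 0 & seg <= 1))
})

test_that("the best-memory fitness trace never decreases", {
  ts <- small_trials()
  res <- select_channels(ts, icsa_params(k = 2, iter_max = 30, seed = 2))
  expect_false(is.unsorted(res$trace))
  expect_identical(res$channels, sort(unique(res$channels)))
  expect_true(all(res$channels >= 1 & res$channels <= 4))
  # zero iterations returns the best of the random initialization
  res0 <- select_channels(ts, icsa_params(k = 2, iter_max = 0, seed = 2))
  expect_length(res0$trace, 0L)
  expect_length(res0$channels, 2L)
  # determinism
  res2 <- select_channels(ts, icsa_params(k = 2, iter_max = 30, seed = 2))
  expect_identical(res, res2)
})

test_that("the search matches exhaustive enumeration on a small problem", {
  ts <- generate_synthetic_dataset(
    synth_spec(n_trials_per_class = 3, n_channels = 6, duration_s = 4,
               informative_channels = 1:3, seed = 21))
  st <- channel_stats(ts)
  p <- icsa_params(k = 2, iter_max = 200)
  subsets <- combn(6, 2)
  enum <- apply(subsets, 2, function(s) {
    pos <- numeric(6); pos[s] <- 1
    channel_fitness(pos, st, p)
  })
  best_fit <- max(enum)
  hits <- vapply(1:10, function(s) {
    p$seed <- s
    res <- select_channels(ts, p)
    abs(res$fitness - best_fit) < 1e-12
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("parameter validation catches bad configurations", {
  expect_error(icsa_params(k = 2, flock_size = 2), "flock_size")
  expect_error(icsa_params(k = 2, w1 = 0.7, w2 = 0.7), "w1")
  expect_error(icsa_params(k = 2, ap = 1.5), "ap")
  expect_error(icsa_params(k = 2, levy_beta = 3), "levy_beta")
  expect_error(icsa_params(k = 0), "k")
  ts <- small_trials()[1:2]
  expect_error(select_channels(ts, icsa_params(k = 9)), "exceeds")
})
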