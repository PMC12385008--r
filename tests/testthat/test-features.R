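test_that("time-domain block matches hand arithmetic", {
  f <- time_domain_features(c(1, 2, 3, 4, 5))
  expect_equal(f[["mean"]], 3)
  expect_equal(f[["median"]], 3)
  expect_equal(f[["rms"]], sqrt(11), tolerance = 1e-12)
  expect_equal(f[["activity"]], 2.5)          # 1/(N-1) sample variance
  expect_equal(f[["variance"]], 2)            # 1/N population variance
  expect_equal(f[["mobility"]], 0)            # derivative is constant
  expect_equal(f[["line_length"]], 4)
  k <- time_domain_features(c(0, 1, 0, 1))
  expect_equal(k[["nonlinear_energy"]], 0)    # (1-0) + (0-1)
  expect_equal(k[["line_length"]], 3)
  cst <- time_domain_features(rep(2, 50))
  expect_true(all(cst[c("sd", "variance", "zcr", "line_length",
                        "nonlinear_energy", "shannon_entropy")] == 0))
  expect_error(time_domain_features(c(1, 2)), "3 samples")
})

test_that("Hjorth parameters match a finite-difference oracle", {
  expect_equal(unname(hjorth_parameters(rep(1, 10))), c(0, 0, 0))
  alt <- rep(c(1, -1), 32)
  got <- hjorth_parameters(alt)
  orc <- oracle_time_domain(alt)
  expect_equal(got[["mobility"]], orc[["mobility"]], tolerance = 1e-9)
  expect_equal(got[["complexity"]], orc[["complexity"]], tolerance = 1e-9)
  over_one <- vapply(1:20, function(s) {
    set.seed(s)
    hjorth_parameters(rnorm(256))[["complexity"]] > 1
  }, logical(1))
  expect_true(all(over_one))  # differencing amplifies high frequencies
})

test_that("wavelet subband block has the advertised shape and energetics", {
  set.seed(6)
  x <- rnorm(640)
  f <- wpt_subband_features(x)
  expect_length(f, 224L)
  energies <- f[grep("energy", names(f))]
  expect_length(energies, 32L)
  expect_lt(abs(sum(energies) - sum(x^2)) / sum(x^2), 0.001)
  z <- wpt_subband_features(rep(0, 64))
  expect_true(all(z[grep("energy|entropy", names(z))] == 0))
  expect_error(wpt_subband_features(rnorm(16)), "32 samples")
})

test_that("spectral moments match degenerate-distribution arithmetic", {
  expect_equal(unname(psd_moments(c(0, 1, 0), c(5, 10, 20))), c(10, 0))
  expect_equal(unname(psd_moments(c(1, 1), c(8, 12))), c(10, 4))
  expect_equal(unname(psd_moments(c(0, 0), c(8, 12))), c(0, 0))
  expect_equal(sum(c(1, 2, 2)^2), 9)  # energy definition on [1,2,2]
  s <- spectral_features(rep(0, 600), 128)
  expect_length(s, 260L)
  expect_true(all(s == 0))
  expect_error(spectral_features(rnorm(100), 128), "512")
})

test_that("texture histograms are normalized and hit the right bins", {
  set.seed(7)
  f <- texture_features(rnorm(200))
  expect_length(f, 30L)
  for (fam in c("lbp", "lndp", "lgp"))
    expect_equal(sum(f[grep(fam, names(f))]), 1, tolerance = 1e-12)
  # strictly increasing ramp: left neighbors below center (bit 1), right
  # neighbors above (bit 0) -> one constant LBP code -> one nonzero bin
  ramp <- texture_features(seq_len(64))
  lbp <- ramp[grep("lbp", names(ramp))]
  expect_equal(sum(lbp > 0), 1L)
  cst <- texture_features(rep(3, 64))
  expect_equal(unname(cst[grep("lbp", names(cst))]),
               c(1, rep(0, 9)))  # code 0 everywhere
  expect_error(texture_features(rnorm(5)), "10 samples")
})

test_that("the registry counts 527 features in fixed family order", {
  nm <- mef_feature_names()
  expect_length(nm, 527L)
  expect_equal(sum(startsWith(nm, "td.")), 13L)
  expect_equal(sum(startsWith(nm, "wpt.")), 224L)
  expect_equal(sum(startsWith(nm, "spec.")), 260L)
  expect_equal(sum(startsWith(nm, "tex.")), 30L)
  expect_identical(nm[1], "td.mean")
})

test_that("extract_mef concatenates per-channel blocks", {
  set.seed(8)
  rec <- recording(matrix(rnorm(3 * 600), nrow = 3), fs = 128,
                   channel_names = c("Fz", "Cz", "Pz"))
  one <- extract_mef(rec, channels = 2)
  expect_length(one, 527L)
  expect_true(all(startsWith(names(one), "Cz.")))
  both <- extract_mef(rec, channels = c(3, 1))
  expect_length(both, 2L * 527L)
  # permuting channels permutes blocks but not values
  swapped <- extract_mef(rec, channels = c(1, 3))
  expect_equal(unname(both), unname(c(swapped[528:1054], swapped[1:527])))
  expect_error(extract_mef(rec, channels = 9), "out of range")
})

test_that("features scale the way their definitions demand", {
  set.seed(9)
  x <- rnorm(600)
  a <- 3.7
  f1 <- time_domain_features(x)
  fa <- time_domain_features(a * x)
  for (nm in c("mean", "sd", "rms", "line_length"))
    expect_equal(fa[[nm]], a * f1[[nm]], tolerance = 1e-9)
  for (nm in c("zcr", "mobility", "complexity"))
    expect_equal(fa[[nm]], f1[[nm]], tolerance = 1e-9)
  expect_equal(texture_features(a * x), texture_features(x),
               tolerance = 1e-12)
})

test_that("every time-domain and spectral feature matches its oracle", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(512:800, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    expect_equal(unname(time_domain_features(x)),
                 unname(oracle_time_domain(x)), tolerance = 1e-9)
    expect_equal(unname(spectral_features(x, 128)),
                 unname(oracle_spectral(x, 128)), tolerance = 1e-9)
  }
})

test_that("extract_features builds a labeled trial matrix", {
  ts <- small_trials()[c(1, 2, 7, 8)]
  X <- extract_features(ts, channels = 1:2)
  expect_equal(dim(X), c(4L, 2L * 527L))
  expect_identical(attr(X, "label"), ts$label)
  expect_true(all(is.finite(X)))
})
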