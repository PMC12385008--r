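# Independent brute-force oracle implementations used to validate the
# feature extractor. Deliberately written with plain loops and different
# library calls (e1071 moments) than the package code.

oracle_entropy <- function(x, n_bins = 64L) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  cuts <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    if (b < n_bins) counts[b] <- sum(x >= cuts[b] & x < cuts[b + 1])
    else counts[b] <- sum(x >= cuts[b] & x <= cuts[b + 1])
  }
  p <- counts / length(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_time_domain <- function(x) {
  n <- length(x)
  mu <- mean(x)
  v_pop <- sum((x - mu)^2) / n
  zc <- 0
  for (i in 2:n) if (sign(x[i]) * sign(x[i - 1]) < 0) zc <- zc + 1
  act <- stats::var(x)
  mobility <- function(v) {
    a <- stats::var(v)
    if (length(v) < 2 || !is.finite(a) || a <= 0) return(0)
    sqrt(stats::var(diff(v)) / a)
  }
  mob <- mobility(x)
  cmp <- if (mob <= 0) 0 else mobility(diff(x)) / mob
  ll <- 0
  for (i in 2:n) ll <- ll + abs(x[i] - x[i - 1])
  ne <- 0
  for (i in 2:(n - 1)) ne <- ne + x[i]^2 - x[i + 1] * x[i - 1]
  c(mean = mu,
    sd = sqrt(v_pop),
    variance = v_pop,
    median = stats::median(x),
    skewness = if (v_pop > 0) e1071::skewness(x, type = 1) else 0,
    zcr = zc / (n - 1),
    activity = if (act > 0) act else 0,
    mobility = mob,
    complexity = cmp,
    rms = sqrt(mean(x^2)),
    shannon_entropy = oracle_entropy(x),
    line_length = ll,
    nonlinear_energy = ne)
}

oracle_spectral <- function(x, fs, nseg = 512L) {
  n <- length(x)
  k <- 0:(nseg - 1)
  win <- 0.54 - 0.46 * cos(2 * pi * k / (nseg - 1))  # Hamming
  nb <- nseg / 2 + 1
  starts <- seq(1, n - nseg + 1, by = nseg / 2)
  psd <- numeric(nb)
  mags <- matrix(0, length(starts), nb)
  for (si in seq_along(starts)) {
    seg <- x[starts[si]:(starts[si] + nseg - 1)] * win
    sp <- stats::fft(seg)[1:nb]
    mags[si, ] <- sqrt(Re(sp)^2 + Im(sp)^2)
    p <- mags[si, ]^2 / (sum(win^2) * fs)
    p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
    psd <- psd + p
  }
  psd <- psd / length(starts)
  freq <- (0:(nb - 1)) * fs / nseg
  pn <- psd / sum(psd)
  iwmf <- sum(pn * freq)
  iwbf <- sum(pn * (freq - iwmf)^2)
  kurt1 <- function(v) {
    m2 <- mean((v - mean(v))^2)
    if (m2 <= 0) return(0)
    mean((v - mean(v))^4) / m2^2 - 3
  }
  sk <- apply(mags, 2, kurt1)
  c(energy = sum(x^2), iwmf = iwmf, iwbf = iwbf,
    stats::setNames(sk, sprintf("sk.b%03d", 0:(nb - 1))))
}

# small labeled trial set reused by several tests, built once per run
small_trials <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_synthetic_dataset(
        synth_spec(n_trials_per_class = 6, n_channels = 4, duration_s = 6,
                   informative_channels = 1:2, seed = 42))
    cache
  }
})
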