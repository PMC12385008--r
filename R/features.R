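#' Multiple EEG features (MEF): 527 descriptors per channel
#'
#' The extractor concatenates, per channel: 13 time-domain features, 224
#' wavelet-packet subband statistics (32 subbands x 7 stats, db2 at 5
#' levels), 3 spectral scalars (energy, instantaneous mean frequency IWMF,
#' instantaneous bandwidth IWBF), 257 spectral-kurtosis values (one per
#' one-sided bin of 512-sample STFT segments), and 30 texture features
#' (10-bin histograms of 1-D LBP, LNDP and LGP codes).
#'
#' @name mef
NULL

# ---- small statistical helpers (population moments, 1/N) -------------------

pop_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  list(n = n, mu = mu, m2 = sum(d^2) / n, m3 = sum(d^3) / n,
       m4 = sum(d^4) / n)
}

# Fisher moment coefficient of skewness, 0 for degenerate input
skewness_m <- function(x) {
  m <- pop_moments(x)
  if (m$m2 <= 0) return(0)
  m$m3 / m$m2^1.5
}

# excess kurtosis (m4/m2^2 - 3), 0 for degenerate input
kurtosis_m <- function(x) {
  m <- pop_moments(x)
  if (m$m2 <= 0) return(0)
  m$m4 / m$m2^2 - 3
}

#' Shannon entropy of a signal's amplitude distribution
#'
#' Probabilities come from a 64-bin equal-width histogram over the observed
#' amplitude range; natural logarithm; empty bins contribute zero. A
#' constant signal has zero entropy.
#'
#' @param x numeric signal.
#' @param n_bins histogram resolution.
#' @return non-negative scalar (nats).
#' @export
amplitude_entropy <- function(x, n_bins = 64L) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  cuts <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Shannon entropy of a probability vector (0 log 0 = 0)
prob_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

#' Hjorth parameters of a signal
#'
#' Activity is the sample variance (N-1 denominator); mobility is
#' `sqrt(act(dx)/act(x))` and complexity `mob(dx)/mob(x)`, with derivatives
#' taken as first differences. Degenerate denominators return 0 by
#' convention.
#'
#' @param x numeric signal of length >= 3.
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 3L)
    stop("Hjorth complexity needs at least 3 samples (second difference)")
  act <- function(v) if (length(v) < 2L) 0 else stats::var(v)
  mob <- function(v) {
    a <- act(v)
    if (a <= 0) return(0)
    sqrt(act(diff(v)) / a)
  }
  a <- act(x)
  m <- mob(x)
  cmp <- if (m <= 0) 0 else mob(diff(x)) / m
  c(activity = if (a <= 0) 0 else a, mobility = m, complexity = cmp)
}

#' Time-domain feature block (13 values)
#'
#' In order: mean, standard deviation, variance, median, skewness,
#' zero-crossing rate, Hjorth activity, mobility and complexity, RMS,
#' Shannon amplitude entropy, line length and nonlinear energy. SD and
#' variance use the 1/N (population) form; activity uses the 1/(N-1) sample
#' variance. Line length is the sum of absolute first differences;
#' nonlinear (Teager) energy sums `x_i^2 - x_{i+1} x_{i-1}` over interior
#' samples.
#'
#' @param x numeric signal of length >= 3.
#' @return named numeric vector of length 13.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 3L) stop("time-domain features need at least 3 samples")
  m <- pop_moments(x)
  sgn <- sign(x)
  zcr <- sum(sgn[-1] * sgn[-n] < 0) / (n - 1)
  hj <- hjorth_parameters(x)
  c(mean = m$mu,
    sd = sqrt(m$m2),
    variance = m$m2,
    median = stats::median(x),
    skewness = skewness_m(x),
    zcr = zcr,
    activity = hj[["activity"]],
    mobility = hj[["mobility"]],
    complexity = hj[["complexity"]],
    rms = sqrt(sum(x^2) / n),
    shannon_entropy = amplitude_entropy(x),
    line_length = sum(abs(diff(x))),
    nonlinear_energy = sum(x[2:(n - 1)]^2 - x[3:n] * x[1:(n - 2)]))
}

# ---- wavelet-packet subband block ------------------------------------------

#' Wavelet-packet subband statistics (224 values)
#'
#' Full 5-level db2 wavelet-packet tree; for each of the 32 terminal nodes,
#' taken in ascending frequency order, seven statistics of the node
#' coefficients: mean, median, energy (sum of squares), skewness, excess
#' kurtosis, variance (1/N) and Shannon entropy of the normalized squared
#' coefficients.
#'
#' @param x numeric signal of length >= 32.
#' @param wavelet,levels tree parameters (defaults db2, 5).
#' @return named numeric vector of length `2^levels * 7` (224 by default).
#' @export
wpt_subband_features <- function(x, wavelet = "db2", levels = 5L) {
  if (length(x) < 2^levels)
    stop(sprintf("need at least %d samples for %d-level analysis",
                 2^levels, levels))
  w <- wpt_decompose(x, wavelet, levels)
  ord <- wpt_frequency_order(levels)
  stats_one <- function(c) {
    en <- sum(c^2)
    ent <- if (en > 0) prob_entropy(c^2 / en) else 0
    m <- pop_moments(c)
    c(mean = m$mu, median = stats::median(c), energy = en,
      skewness = skewness_m(c), kurtosis = kurtosis_m(c),
      variance = m$m2, entropy = ent)
  }
  out <- unlist(lapply(w$nodes[ord], stats_one))
  names(out) <- as.vector(outer(
    c("mean", "median", "energy", "skewness", "kurtosis", "variance",
      "entropy"),
    sprintf("n%02d", seq_len(2^levels)),
    function(s, nd) paste(nd, s, sep = ".")))
  out
}

# ---- spectral block ---------------------------------------------------------

segment_starts <- function(n, nseg, noverlap) {
  step <- nseg - noverlap
  if (n < nseg) return(integer(0))
  seq(1L, n - nseg + 1L, by = step)
}

#' Welch power spectral density
#'
#' Hamming-windowed 512-sample segments with 50% overlap, averaged
#' one-sided periodograms.
#'
#' @param x numeric signal (length >= `nseg`).
#' @param fs sampling rate in Hz.
#' @param nseg segment length.
#' @return list with `freq` (Hz) and `psd` (one-sided, `nseg/2 + 1` bins).
#' @export
welch_psd <- function(x, fs, nseg = 512L) {
  starts <- segment_starts(length(x), nseg, nseg %/% 2L)
  if (!length(starts)) stop("signal shorter than one segment")
  win <- signal::hamming(nseg)
  wnorm <- sum(win^2)
  nb <- nseg %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    sp <- Mod(stats::fft(seg))[1:nb]^2 / (wnorm * fs)
    sp[2:(nb - 1L)] <- 2 * sp[2:(nb - 1L)]
    acc <- acc + sp
  }
  list(freq = (0:(nb - 1L)) * fs / nseg, psd = acc / length(starts))
}

#' Spectral mean frequency and bandwidth of a PSD
#'
#' IWMF is the PSD-weighted mean frequency (the PSD is normalized to unit
#' sum); IWBF is the PSD-weighted variance about it. An all-zero PSD gives
#' `c(0, 0)`.
#'
#' @param psd non-negative spectral weights.
#' @param freq frequencies (Hz) matching `psd`.
#' @return named vector `c(iwmf, iwbf)`.
#' @export
psd_moments <- function(psd, freq) {
  tot <- sum(psd)
  if (tot <= 0) return(c(iwmf = 0, iwbf = 0))
  p <- psd / tot
  mu <- sum(p * freq)
  c(iwmf = mu, iwbf = sum(p * (freq - mu)^2))
}

stft_magnitudes <- function(x, nseg = 512L) {
  starts <- segment_starts(length(x), nseg, nseg %/% 2L)
  win <- signal::hamming(nseg)
  nb <- nseg %/% 2L + 1L
  mags <- matrix(0, nrow = length(starts), ncol = nb)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nseg - 1L)] * win
    mags[i, ] <- Mod(stats::fft(seg))[1:nb]
  }
  mags
}

#' Spectral feature block (260 values)
#'
#' Total energy `sum(x^2)`, IWMF and IWBF from the Welch PSD, then the
#' spectral kurtosis: the excess kurtosis over time of the STFT magnitude
#' at each of the 257 one-sided bins of 512-sample, 50%-overlap segments.
#'
#' @param x numeric signal of length >= 512.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of length 260.
#' @export
spectral_features <- function(x, fs) {
  if (length(x) < 512L) stop("spectral features need at least 512 samples")
  en <- sum(x^2)
  if (en == 0) {
    mom <- c(iwmf = 0, iwbf = 0)
    sk <- rep(0, 257L)
  } else {
    pw <- welch_psd(x, fs)
    mom <- psd_moments(pw$psd, pw$freq)
    mags <- stft_magnitudes(x)
    sk <- apply(mags, 2, kurtosis_m)
  }
  out <- c(en, mom[["iwmf"]], mom[["iwbf"]], sk)
  names(out) <- c("energy", "iwmf", "iwbf", sprintf("sk.b%03d", 0:256))
  out
}

# ---- texture block ----------------------------------------------------------

# comparison indicator: 1 when the difference is negative, else 0
# (keeps matrix shape, unlike as.numeric)
tex_f <- function(u) (u < 0) + 0

# neighbor matrix for P = 8 (4 left, 4 right) centers; rows are centers
neighbor_codes <- function(v, bits_fun) {
  n <- length(v)
  centers <- 5:(n - 4L)
  offs <- c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)
  nb <- vapply(offs, function(o) v[centers + o], numeric(length(centers)))
  bits <- bits_fun(nb, v[centers])
  drop(bits %*% 2^(0:7))
}

lbp_codes <- function(x) {
  neighbor_codes(x, function(nb, ctr) tex_f(nb - ctr))
}

# gradient-domain LBP: codes computed on the first-difference sequence
lgp_codes <- function(x) {
  lbp_codes(diff(x))
}

# sign pattern of successive neighbor-difference comparisons (circular)
lndp_codes <- function(x) {
  neighbor_codes(x, function(nb, ctr) {
    d <- nb - ctr
    tex_f(d - d[, c(2:8, 1), drop = FALSE])
  })
}

code_histogram <- function(codes, n_bins = 10L) {
  cuts <- seq(0, 255, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(codes, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  counts / length(codes)
}

#' Texture feature block (30 values)
#'
#' One-dimensional local binary pattern (LBP), local neighborhood difference
#' pattern (LNDP) and local gradient pattern (LGP) codes with 8 neighbors
#' (4 on each side) and binary weights `2^(i-1)`, each histogrammed into 10
#' equal-width bins over the code range `[0, 255]` and normalized to sum 1.
#'
#' @param x numeric signal of length >= 10.
#' @return named numeric vector of length 30 (LBP, LNDP, LGP histograms).
#' @export
texture_features <- function(x) {
  if (length(x) < 10L) stop("texture features need at least 10 samples")
  out <- c(code_histogram(lbp_codes(x)),
           code_histogram(lndp_codes(x)),
           code_histogram(lgp_codes(x)))
  names(out) <- as.vector(outer(sprintf("h%02d", 1:10),
                                c("lbp", "lndp", "lgp"),
                                function(h, f) paste(f, h, sep = ".")))
  out
}

# ---- registry and per-channel assembly --------------------------------------

#' Names of the 527 per-channel features, in extraction order
#'
#' The registry fixes the ordering contract: time-domain (13), WPT subband
#' (224), energy/IWMF/IWBF (3), spectral kurtosis (257), texture (30).
#' The total is checked at build time.
#'
#' @return character vector of length 527.
#' @export
mef_feature_names <- function() {
  td <- paste0("td.", c("mean", "sd", "variance", "median", "skewness",
                        "zcr", "activity", "mobility", "complexity", "rms",
                        "shannon_entropy", "line_length",
                        "nonlinear_energy"))
  wpt <- paste0("wpt.", as.vector(outer(
    c("mean", "median", "energy", "skewness", "kurtosis", "variance",
      "entropy"),
    sprintf("n%02d", 1:32), function(s, nd) paste(nd, s, sep = "."))))
  sp <- paste0("spec.", c("energy", "iwmf", "iwbf"))
  sk <- sprintf("spec.sk.b%03d", 0:256)
  tex <- paste0("tex.", as.vector(outer(sprintf("h%02d", 1:10),
                                        c("lbp", "lndp", "lgp"),
                                        function(h, f) paste(f, h, sep = "."))))
  out <- c(td, wpt, sp, sk, tex)
  stopifnot(length(td) == 13L, length(wpt) == 224L,
            length(sp) + length(sk) == 260L, length(tex) == 30L,
            length(out) == 527L)
  out
}

extract_channel <- function(x, fs) {
  unname(c(time_domain_features(x), wpt_subband_features(x),
           spectral_features(x, fs), texture_features(x)))
}

#' Extract the MEF vector of one recording
#'
#' Concatenates the 527 per-channel features of the selected channels, in
#' channel order then registry order, with names
#' `"<channel>.<family>.<feature>"`.
#'
#' @param rec an `eeg_recording` with at least 512 samples.
#' @param channels integer channel indices (default: all).
#' @return named numeric vector of length `527 * length(channels)`.
#' @examples
#' rec <- recording(matrix(rnorm(600), nrow = 1), fs = 128)
#' length(extract_mef(rec))  # 527
#' @export
extract_mef <- function(rec, channels = seq_len(n_channels(rec))) {
  stopifnot(inherits(rec, "eeg_recording"))
  channels <- as.integer(channels)
  if (any(channels < 1L) || any(channels > n_channels(rec)))
    stop("channel indices out of range")
  reg <- mef_feature_names()
  out <- numeric(0)
  for (ch in channels) {
    v <- tryCatch(extract_channel(rec$data[ch, ], rec$fs),
                  error = function(e)
                    stop("feature extraction failed on channel ",
                         rec$channel_names[ch], ": ", conditionMessage(e)))
    names(v) <- paste(rec$channel_names[ch], reg, sep = ".")
    out <- c(out, v)
  }
  out
}

#' Extract the feature matrix of a trial set
#'
#' @param trials a `trial_set`.
#' @param channels integer channel indices (default: all).
#' @return numeric matrix, trials x (channels x 527), with registry column
#'   names and the trial labels attached as attribute `"label"`.
#' @export
extract_features <- function(trials, channels = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(channels)) channels <- seq_len(n_channels(trials$trials[[1]]))
  rows <- lapply(trials$trials, extract_mef, channels = channels)
  mat <- do.call(rbind, rows)
  colnames(mat) <- names(rows[[1]])
  attr(mat, "label") <- trials$label
  mat
}
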