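#' EEG frequency bands used by the synthetic generator
#'
#' Delta/theta/alpha/beta/gamma edges in Hz. The synthesis delta band starts
#' at 1 Hz (above the 0.75 Hz analysis high-pass edge) and gamma is capped at
#' 45 Hz so that all content survives the 0.75-45 Hz band-pass and respects
#' the 64 Hz Nyquist limit of 128 Hz recordings.
#' @return named list of `c(lo, hi)` edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

default_band_profiles <- function() {
  # mean band power in microvolt^2; stress = alpha suppression plus
  # beta/gamma elevation relative to calm
  list(calm   = c(delta = 20, theta = 15, alpha = 40, beta = 6,  gamma = 2),
       stress = c(delta = 20, theta = 15, alpha = 10, beta = 25, gamma = 10))
}

#' Specification of a synthetic EEG trial set
#'
#' Defines the study conditions the generator emulates: 128 Hz sampling,
#' 60 s trials, band-limited oscillatory content in the five classical EEG
#' bands, two classes differing in band power on a subset of *informative*
#' channels (alpha suppression with beta/gamma elevation for stress),
#' additive white Gaussian sensor noise, and per-trial arousal/valence
#' ratings drawn inside the calm/stress rating regions.
#'
#' Non-informative channels carry a *shared* background oscillation (the same
#' random component phases across those channels within a trial, mimicking
#' volume-conducted common activity) at the class-independent mean of the two
#' band profiles, plus channel-specific noise.
#'
#' @param n_trials_per_class trials to generate per class.
#' @param n_channels total channel count.
#' @param duration_s trial length in seconds.
#' @param fs sampling rate in Hz; must be at least twice the highest band
#'   edge.
#' @param informative_channels integer indices of channels whose band power
#'   differs between classes.
#' @param band_power_profile list with elements `calm` and `stress`, each a
#'   named numeric vector of mean band powers (microvolt^2) over
#'   delta/theta/alpha/beta/gamma.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (microvolts).
#' @param components_per_band number of random-frequency sinusoids used to
#'   fill each band.
#' @param seed RNG seed making the generated set reproducible.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_trials_per_class = 20, n_channels = 8,
                       duration_s = 60, fs = 128,
                       informative_channels = seq_len(min(4, n_channels)),
                       band_power_profile = default_band_profiles(),
                       noise_sd = 2, components_per_band = 3, seed = 1L) {
  chk <- function(cond, field, msg)
    if (!cond) stop("invalid synth_spec field `", field, "`: ", msg)
  chk(is.numeric(n_trials_per_class) && n_trials_per_class >= 1,
      "n_trials_per_class", "must be >= 1")
  chk(is.numeric(n_channels) && n_channels >= 1, "n_channels", "must be >= 1")
  chk(is.numeric(duration_s) && duration_s > 0, "duration_s", "must be > 0")
  chk(is.numeric(fs) && fs > 0, "fs", "must be > 0")
  chk(all(informative_channels >= 1) &&
        all(informative_channels <= n_channels),
      "informative_channels", "indices must lie in [1, n_channels]")
  chk(is.list(band_power_profile) &&
        all(c("calm", "stress") %in% names(band_power_profile)),
      "band_power_profile", "must have `calm` and `stress` entries")
  bands <- eeg_bands()
  for (cls in c("calm", "stress")) {
    p <- band_power_profile[[cls]]
    chk(length(p) == length(bands) && all(p >= 0) &&
          all(names(bands) %in% names(p)),
        "band_power_profile", "each profile needs the five named bands >= 0")
  }
  hi <- max(vapply(bands, max, numeric(1)))
  chk(fs >= 2 * hi, "fs",
      sprintf("must be >= 2 x highest band edge (%g Hz)", hi))
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a scalar")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels),
                 duration_s = duration_s, fs = fs,
                 informative_channels =
                   as.integer(sort(unique(informative_channels))),
                 band_power_profile = band_power_profile,
                 noise_sd = noise_sd,
                 components_per_band = as.integer(components_per_band),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# one channel worth of band-limited content: for each band, m sinusoids at
# uniformly random in-band frequencies and phases, amplitudes set so the
# band's expected power matches the profile (sinusoid power = A^2 / 2)
band_signal <- function(t, profile, m, draws) {
  bands <- eeg_bands()
  x <- numeric(length(t))
  for (b in seq_along(bands)) {
    p <- profile[[names(bands)[b]]]
    if (p <= 0) next
    amp <- sqrt(2 * p / m)
    for (j in seq_len(m)) {
      fr <- draws$freq[b, j]
      ph <- draws$phase[b, j]
      x <- x + amp * sin(2 * pi * fr * t + ph)
    }
  }
  x
}

band_draws <- function(m) {
  bands <- eeg_bands()
  freq <- t(vapply(bands, function(e) stats::runif(m, e[1], e[2]),
                   numeric(m)))
  if (m == 1L) freq <- matrix(freq, nrow = length(bands))
  phase <- matrix(stats::runif(length(bands) * m, 0, 2 * pi),
                  nrow = length(bands))
  list(freq = freq, phase = phase)
}

#' Generate a synthetic calm/stress EEG trial set
#'
#' Produces `n_trials_per_class` trials per class under the conditions of the
#' supplied [synth_spec()]. Informative channels receive independent
#' random-phase band oscillations at the class band-power profile;
#' the remaining channels share a common class-independent background (one
#' set of component phases per trial, reused across those channels) at the
#' average of the two profiles. White Gaussian noise of `noise_sd` microvolts
#' is added everywhere. Ratings are drawn uniformly inside the calm region
#' (arousal U(1, 3.9), valence U(4.1, 5.9)) or the stress region (arousal
#' U(5.1, 8), valence U(0.5, 2.9)) so the rating rule of [label_trial()]
#' always fires. Output is deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return a `trial_set` with `2 * n_trials_per_class` trials (calm first).
#' @examples
#' ts <- generate_synthetic_dataset(synth_spec(n_trials_per_class = 2,
#'                                             duration_s = 5, seed = 7))
#' ts
#' @export
generate_synthetic_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) spec <- do.call(synth_spec, spec)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  m <- spec$components_per_band
  bg_profile <- (spec$band_power_profile$calm +
                   spec$band_power_profile$stress) / 2
  info <- spec$informative_channels
  trials <- list(); arousal <- numeric(0); valence <- numeric(0)
  labels <- character(0)
  for (cls in c("calm", "stress")) {
    profile <- spec$band_power_profile[[cls]]
    for (k in seq_len(spec$n_trials_per_class)) {
      dat <- matrix(0, nrow = spec$n_channels, ncol = n)
      bg_draws <- band_draws(m)  # shared across non-informative channels
      for (ch in seq_len(spec$n_channels)) {
        base <- if (ch %in% info) band_signal(t, profile, m, band_draws(m))
                else band_signal(t, bg_profile, m, bg_draws)
        noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd)
                 else 0
        dat[ch, ] <- base + noise
      }
      trials[[length(trials) + 1L]] <- recording(dat, spec$fs)
      if (cls == "calm") {
        arousal <- c(arousal, stats::runif(1, 1, 3.9))
        valence <- c(valence, stats::runif(1, 4.1, 5.9))
      } else {
        arousal <- c(arousal, stats::runif(1, 5.1, 8))
        valence <- c(valence, stats::runif(1, 0.5, 2.9))
      }
      labels <- c(labels, cls)
    }
  }
  out <- trial_set(trials, arousal, valence, labels)
  stopifnot(identical(out$label, labels))  # ratings regions match the rule
  out
}

#' Periodogram band power of a signal
#'
#' Average power (amplitude^2 scale: a unit-amplitude sinusoid yields 0.5)
#' within a frequency band, from the raw periodogram.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band `c(lo, hi)` band edges in Hz.
#' @return scalar band power.
#' @export
band_power <- function(x, fs, band) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2  # power per bin, two-sided
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  p <- sp[half]
  f <- freqs[half]
  # fold negative frequencies onto the one-sided spectrum
  p[f > 0 & f < fs / 2] <- 2 * p[f > 0 & f < fs / 2]
  sum(p[f >= band[1] & f <= band[2]])
}
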