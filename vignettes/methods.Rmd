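---
title: "Methods: signal model, features, selection and the hybrid classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, features, selection and the hybrid classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`eegstress` detects a two-class mental state (*calm* versus *stress*) from
multi-channel EEG. The pipeline has five stages, each exposed as its own
function family so every stage can be tested and replaced independently:

1. **Preprocessing** — FIR band-pass filtering plus wavelet-packet
   soft-threshold denoising (`preprocess_trials()`, `wpt_denoise()`).
2. **Channel selection** — an improved crow search algorithm over binary
   channel subsets (`select_channels()`).
3. **Feature extraction** — 527 descriptors per channel
   (`extract_mef()`, `extract_features()`).
4. **Classification** — a hybrid network with convolutional, bidirectional
   LSTM and deep-belief branches (`bddnet_train()`, `bddnet_predict()`).
5. **Hyper-parameter tuning** — an employee optimization algorithm
   (`tune_hyperparameters()`), optional.

`run_experiment()` chains all stages with a stratified 70:30 train/test
split and returns confusion counts plus derived metrics
(`compute_metrics()`).

# Preprocessing

`denoise_config()` defaults: band-pass 0.75–45 Hz, FIR order 424 with a
Hamming window (via `signal::fir1`), wavelet-packet depth 4 with `db3`.

Numerical choices made here:

* **Zero-phase filtering.** The FIR filter is applied forward and backward
  with symmetric (reflection) end padding of one filter order on each side,
  then cropped back to the input length. This removes both group delay and
  edge transients; the operation is linear and exactly zero-phase.
* **Noise scale from the finest details.** The noise standard deviation is
  estimated as `median(|finest-level detail coefficients|) / 0.6745`, the
  usual robust estimator under Gaussian noise, and the universal threshold
  `T = sigma * sqrt(2 log N)` is applied as *soft* shrinkage
  `sign(c) * max(|c| - T, 0)` to every terminal node.
* **The approximation node is spared.** The lowest-frequency node carries
  the slow rhythms that dominate EEG band power; thresholding it mostly
  removes signal, not noise, so it is left untouched.
* **Sampling rate matters for the gain.** With the default depth, the
  protected approximation band spans `[0, fs / 2^(levels+1)]` Hz. At low
  sampling rates a mid-band rhythm falls outside this protected band and
  soft shrinkage biases its amplitude; the denoising mean-squared-error
  gain is therefore demonstrated (in the test suite) at a rate where the
  probe tone sits inside the protected band.

# Wavelet packet transform

No wavelet package for R is available in this environment, so the
transform is implemented directly (`wpt_decompose()`, `wpt_reconstruct()`):

* orthonormal Daubechies filters `db1`/`db2`/`db3` with **periodized**
  (circular) convolution, which keeps every level exactly orthonormal and
  makes decompose–reconstruct an identity to machine precision;
* inputs whose length is not a multiple of `2^levels` are reflection-padded
  before analysis and cropped after synthesis;
* terminal nodes are produced in natural (Paley) order and relabeled into
  **frequency order** with the Gray-code permutation, so node *i* covers
  the *i*-th frequency strip of `[0, fs/2]`.

Periodization was chosen over boundary-symmetric variants because exact
energy conservation (Parseval) and exact invertibility are the properties
the rest of the package relies on; the cost is a wrap-around artifact
confined to a filter-length neighborhood of the signal ends.

# The 527-feature set

`extract_mef()` computes, per channel:

* **13 time-domain features** — mean, standard deviation, variance, RMS,
  skewness, kurtosis, zero-crossing rate, line length, Shannon entropy of a
  10-bin amplitude histogram, Hjorth activity/mobility/complexity, and
  nonlinear energy. Standard deviation and variance use the population
  (1/N) convention so that Hjorth activity equals the variance feature
  exactly.
* **224 wavelet-packet features** — a 5-level `db2` decomposition yields 32
  terminal subbands; each contributes 7 statistics (mean, standard
  deviation, variance, RMS, energy, Shannon entropy, line length),
  32 × 7 = 224.
* **3 spectral features** — total spectral energy, instantaneous weighted
  mean frequency and weighted band frequency, from a Welch periodogram
  (512-sample Hamming segments, 50 % overlap).
* **257 spectral-kurtosis features** — excess kurtosis of the short-time
  Fourier magnitude in each of the 257 one-sided bins of a 512-point STFT.
* **30 texture features** — 10-bin histograms of three 1-D texture
  operators (local binary pattern, local neighborhood descriptive pattern,
  local gradient pattern) with eight neighbors (four on each side).

Texture conventions chosen by this package: the comparison function is
`f(u) = 1` if `u < 0` (ties count as "not smaller"), bit weights are
`2^(0:7)` ordered from the outermost left neighbor to the outermost right
one, codes therefore live in `[0, 255]` and are histogrammed into 10 equal
bins normalized to sum to one. The LNDP operator compares each neighbor to
its next neighbor (successive differences around the center); the LGP
operator compares each neighbor's gradient against the mean absolute
gradient.

13 + 224 + 3 + 257 + 30 = **527**; `mef_feature_names()` enumerates them
with stable `td.*`, `wpt.*`, `spec.*`, `tex.*` prefixes.

# Channel selection (improved crow search)

`select_channels()` searches `[0, 1]^d` positions decoded to channel
subsets by taking the `k` largest coordinates (ties break toward the lower
channel index). Fitness, maximized, is

```
w1 * EN + w2 * (1 - CV)
```

where `EN` is the normalized Shannon entropy of the selected channels'
pooled energy distribution and `CV` is their mean coefficient of variation
of per-trial band power across trials (default weights `w1 = 0.5`,
`w2 = 0.5`). The "improved" ingredients, on top of plain crow search
(awareness probability `ap = 0.1`, flight length `fl = 2`):

* **Lévy-flight elite learning** — the elite member proposes Mantegna
  Lévy steps (`beta = 1.5`) and keeps them only on improvement;
* **random worst-member replacement** every iteration;
* **greedy memory update**, making the best-memory trace monotone by
  construction.

Channel statistics are computed once and cached, so fitness evaluations
are cheap and exhaustive enumeration is feasible for small `d` (used as a
test oracle).

# The hybrid classifier

`bddnet_config()` / `bddnet_train()` implement a three-branch network over
the per-trial feature vector (selected channels × 527 features):

* **Convolutional branch** — three blocks of width-3 valid convolution →
  batch normalization → ReLU → max-pool/2, with 64/128/256 filters, on the
  z-scored feature vector treated as a 1-D sequence.
* **Bidirectional LSTM branch** — the feature vector is chunked into
  `n_features / step` time steps of width `step` (default 527, i.e. one
  step per selected channel), through two BiLSTM layers of 50 units per
  direction; the branch output concatenates the forward state at the last
  step with the backward state at the first step. Forget-gate biases are
  initialized to 1.
* **Deep-belief branch** — a 200–150–100 sigmoid stack on the min–max
  scaled input, optionally pretrained with one-step contrastive divergence
  (first layer Gaussian–Bernoulli, remaining layers Bernoulli–Bernoulli).

The branch outputs are concatenated, passed through inverted dropout
(rate 0.5) and a softmax head. Training is mini-batch stochastic gradient
descent with momentum 0.9, learning rate 0.001, batch size 16, and weight
decay `1e-4` applied to weight matrices only (not biases, gains or batch
statistics). All gradients are hand-derived and verified against central
finite differences in the test suite. Prediction ties break toward *calm*.
Input scaling statistics (z-score for the convolutional and LSTM branches,
min–max for the deep-belief branch) are fitted on the training set only
and stored with the model.

# Hyper-parameter tuning (employee optimization)

`eoa_optimize()` minimizes an objective over `[0, 1]^dim`. Each iteration
the best `elite_frac` members pass unchanged; every other member *i*
proposes

```
x_i + r * (x_i - ref)
```

with `r ~ U(0, 1)` and `ref` either a random other member (exploration,
probability `1 - t / iter_max`) or the current best member (exploitation).
The default move steps *away* from the reference; `toward_reference = TRUE`
flips the sign. Proposals are clamped to the unit box and accepted
greedily, so the best-error trace is non-increasing. Non-finite objective
values reject the proposal with a warning instead of corrupting the
population.

`tune_hyperparameters()` decodes a 3-vector into learning rate
(log-uniform on `[1e-4, 1e-1]`), weight decay (log-uniform on
`[1e-6, 1e-2]`) and momentum (linear on `[0.5, 0.99]`), scored by
validation error on a stratified holdout.

# Synthetic data generator

Real affect-labeled EEG benchmarks are registration-gated, so the package
ships a seeded generator (`synth_spec()`, `generate_synthetic_dataset()`)
whose defaults define the study conditions: 20 trials per class, 8
channels, 128 Hz, 15 s per trial.

Each trial is a sum of random-phase, random-frequency sinusoids drawn per
EEG band (delta/theta/alpha/beta/gamma), with band amplitudes set by a
per-class profile: the *stress* profile raises beta/gamma power and lowers
alpha power relative to *calm*, the qualitative signature the classifier
is meant to exploit. Only `informative_channels` (default the first half)
receive class-dependent profiles; the remaining channels mix a shared
volume-conducted background with channel noise, making them genuinely
uninformative and giving the channel-selection stage something to reject.
White Gaussian noise (`noise_sd`) is added everywhere.

Limits to keep in mind: the generator is stationary within a trial, has no
artifacts (eye blinks, muscle), no 1/f spectral slope, and its class
difference is purely a band-power shift. It validates the pipeline's
mechanics and separability behavior, not clinical performance; single
trial band power also has heavy-tailed scatter because two random in-band
components can interfere within a finite window, so generator-level checks
compare class *means* over dozens of trials.

# Reproducibility

Every stochastic function takes an explicit seed and restores the global
random state afterwards. The acceptance script regenerates the headline
numbers against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
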