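#' Improved crow search algorithm: parameters
#'
#' The improved variant augments the classical crow search with a
#' Levy-flight elite-learning step (LFEL, proposal built from the two best
#' solutions) and replacement of the worst member by a point on the segment
#' toward the best (RWM).
#'
#' @param k number of channels to select.
#' @param flock_size number of crows (>= 4).
#' @param fl flight length.
#' @param ap awareness probability in `[0, 1]`.
#' @param iter_max iterations.
#' @param w1,w2 fitness weights (must sum to 1): `w1` scales the mean
#'   normalized amplitude entropy of the selected channels, `w2` the
#'   redundancy term derived from their mean absolute pairwise correlation.
#' @param levy_beta Levy distribution index in `(1, 2]`.
#' @param cv_mode `"penalize"` (default) maps the correlation term to
#'   `1 - CV` so redundant subsets score lower; `"reward"` uses `CV`
#'   directly.
#' @param seed RNG seed.
#' @return object of class `icsa_params`.
#' @export
icsa_params <- function(k, flock_size = 20, fl = 2, ap = 0.1,
                        iter_max = 100, w1 = 0.5, w2 = 0.5,
                        levy_beta = 1.5, cv_mode = c("penalize", "reward"),
                        seed = 1L) {
  cv_mode <- match.arg(cv_mode)
  if (flock_size < 4) stop("flock_size must be >= 4")
  if (abs(w1 + w2 - 1) > 1e-12) stop("w1 + w2 must equal 1")
  if (ap < 0 || ap > 1) stop("ap must lie in [0, 1]")
  if (levy_beta <= 1 || levy_beta > 2) stop("levy_beta must lie in (1, 2]")
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), flock_size = as.integer(flock_size),
                 fl = fl, ap = ap, iter_max = as.integer(iter_max),
                 w1 = w1, w2 = w2, levy_beta = levy_beta,
                 cv_mode = cv_mode, seed = as.integer(seed)),
            class = "icsa_params")
}

#' Per-channel statistics used by the selection fitness
#'
#' Precomputes, once per trial set, the mean normalized amplitude entropy of
#' each channel (64-bin histogram entropy divided by `log(64)`, averaged
#' over trials) and the matrix of mean absolute pairwise channel
#' correlations (averaged over trials; channels with zero variance in a
#' trial contribute zero correlation there).
#'
#' @param trials a `trial_set`.
#' @return list with `entropy` (length d) and `abs_cor` (d x d).
#' @export
channel_stats <- function(trials) {
  stopifnot(inherits(trials, "trial_set"), length(trials$trials) >= 1L)
  d <- n_channels(trials$trials[[1]])
  ent <- numeric(d)
  ac <- matrix(0, d, d)
  for (tr in trials$trials) {
    ent <- ent + vapply(seq_len(d), function(ch)
      amplitude_entropy(tr$data[ch, ]) / log(64), numeric(1))
    sds <- apply(tr$data, 1, stats::sd)
    cc <- matrix(0, d, d)
    ok <- sds > 0
    if (sum(ok) >= 2)
      cc[ok, ok] <- abs(stats::cor(t(tr$data[ok, , drop = FALSE])))
    diag(cc) <- 1
    ac <- ac + cc
  }
  list(entropy = ent / length(trials$trials),
       abs_cor = ac / length(trials$trials))
}

#' Decode a continuous crow position into a channel subset
#'
#' Crows live in the unit hypercube `[0,1]^d`; the `k` largest coordinates
#' name the selected channels, ties broken toward the lower index.
#'
#' @param position numeric vector in `[0,1]^d`.
#' @param k subset size.
#' @return sorted integer vector of `k` channel indices.
#' @export
decode_channels <- function(position, k) {
  if (k > length(position)) stop("k exceeds the number of channels")
  sort(order(-position, seq_along(position))[seq_len(k)])
}

fitness_from_stats <- function(sel, stats, params) {
  en <- mean(stats$entropy[sel])
  cv <- if (length(sel) < 2) 0 else {
    sub <- stats$abs_cor[sel, sel]
    mean(sub[upper.tri(sub)])
  }
  term <- if (params$cv_mode == "penalize") 1 - cv else cv
  params$w1 * en + params$w2 * term
}

#' Fitness of a crow position (weighted entropy + redundancy term)
#'
#' `fitness = w1 * EN + w2 * (1 - CV)` (default orientation), where EN is
#' the mean normalized amplitude entropy of the decoded channels and CV
#' their mean absolute pairwise correlation; higher is better, so
#' informative, mutually non-redundant subsets win.
#'
#' @param position numeric vector in `[0,1]^d`.
#' @param trials a `trial_set`, or a precomputed [channel_stats()] list.
#' @param params an [icsa_params()].
#' @return scalar fitness (higher is better).
#' @export
channel_fitness <- function(position, trials, params) {
  stats <- if (inherits(trials, "trial_set")) channel_stats(trials)
           else trials
  fitness_from_stats(decode_channels(position, params$k), stats, params)
}

#' One crow position update
#'
#' With probability the followed crow is unaware (`r_j >= ap`), the crow
#' moves toward that crow's memory with step `r_i * fl`; otherwise it
#' relocates uniformly at random. The result is clamped to `[0, 1]`.
#'
#' @param x_i current position.
#' @param m_j memory of the followed crow.
#' @param params an [icsa_params()].
#' @param r_i,r_j uniform random draws (exposed for testing).
#' @return new position vector.
#' @export
crow_step <- function(x_i, m_j, params, r_i = stats::runif(1),
                      r_j = stats::runif(1)) {
  new <- if (r_j >= params$ap) x_i + r_i * params$fl * (m_j - x_i)
         else stats::runif(length(x_i))
  pmin(pmax(new, 0), 1)
}

#' Levy-stable step sampler (Mantegna's algorithm)
#'
#' Draws approximately from a symmetric heavy-tailed Levy distribution with
#' tail index `beta`: `u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and the Mantegna scale for `sigma_u`.
#'
#' @param n number of draws.
#' @param beta tail index in `(1, 2]`.
#' @return numeric vector of steps.
#' @export
levy_mantegna <- function(n, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Elite (LFEL) and worst-member (RWM) updates
#'
#' LFEL proposes a replacement for the best crow from the two fittest
#' solutions with a Levy-scaled step,
#' `x_best1 + (2 r1 - 1) * levy(beta) * (x_best1 - x_best2)`, accepted only
#' if fitter (greedy). RWM always moves the worst crow onto the segment
#' toward the best: `x_worst + r2 * (x_best - x_worst)`.
#'
#' @param state list with `positions` (N x d) and `fitness` (length N).
#' @param stats precomputed [channel_stats()].
#' @param params an [icsa_params()].
#' @return updated state.
#' @export
elite_and_worst_updates <- function(state, stats, params) {
  fit <- state$fitness
  ord <- order(-fit, seq_along(fit))
  b1 <- ord[1]; b2 <- ord[2]; worst <- ord[length(ord)]
  d <- ncol(state$positions)
  # LFEL: greedy elite proposal
  r1 <- stats::runif(1)
  prop <- state$positions[b1, ] + (2 * r1 - 1) *
    levy_mantegna(d, params$levy_beta) *
    (state$positions[b1, ] - state$positions[b2, ])
  prop <- pmin(pmax(prop, 0), 1)
  pf <- fitness_from_stats(decode_channels(prop, params$k), stats, params)
  if (pf > fit[b1]) {
    state$positions[b1, ] <- prop
    state$fitness[b1] <- pf
  }
  # RWM: pull the worst member toward the best
  r2 <- stats::runif(1)
  best_pos <- state$positions[which.max(state$fitness), ]
  neww <- state$positions[worst, ] + r2 * (best_pos - state$positions[worst, ])
  neww <- pmin(pmax(neww, 0), 1)
  state$positions[worst, ] <- neww
  state$fitness[worst] <-
    fitness_from_stats(decode_channels(neww, params$k), stats, params)
  state
}

#' Select a channel subset with the improved crow search algorithm
#'
#' Runs the full loop: random initialization of positions and memories in
#' `[0,1]^d`, fitness evaluation, per-crow position updates, LFEL and RWM
#' improvements, feasibility clamping, and greedy memory update (a memory
#' is replaced only when the new position is fitter). Deterministic given
#' `params$seed`.
#'
#' @param trials a `trial_set` with at least 2 channels.
#' @param params an [icsa_params()].
#' @return list with `channels` (sorted indices of the best memory's top-k
#'   coordinates), `fitness` (its fitness), `trace` (best memory fitness
#'   per iteration, non-decreasing) and `memory` (the best position).
#' @export
select_channels <- function(trials, params) {
  stopifnot(inherits(trials, "trial_set"))
  d <- n_channels(trials$trials[[1]])
  if (d < 2) stop("need at least 2 channels to select from")
  if (params$k > d) stop("k exceeds the number of channels")
  stats <- channel_stats(trials)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  N <- params$flock_size
  positions <- matrix(stats::runif(N * d), N, d)
  fit <- apply(positions, 1, function(p)
    fitness_from_stats(decode_channels(p, params$k), stats, params))
  memories <- positions
  mem_fit <- fit
  trace <- numeric(params$iter_max)
  iter <- 0L
  while (iter < params$iter_max) {
    iter <- iter + 1L
    for (i in seq_len(N)) {
      j <- sample(setdiff(seq_len(N), i), 1L)
      positions[i, ] <- crow_step(positions[i, ], memories[j, ], params)
    }
    fit <- apply(positions, 1, function(p)
      fitness_from_stats(decode_channels(p, params$k), stats, params))
    st <- elite_and_worst_updates(list(positions = positions, fitness = fit),
                                  stats, params)
    positions <- st$positions
    fit <- st$fitness
    improved <- fit > mem_fit
    memories[improved, ] <- positions[improved, ]
    mem_fit[improved] <- fit[improved]
    trace[iter] <- max(mem_fit)
  }
  best <- which.max(mem_fit)
  list(channels = decode_channels(memories[best, ], params$k),
       fitness = mem_fit[best],
       trace = trace,
       memory = memories[best, ])
}
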