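#' Employee optimization algorithm: parameters
#'
#' Population-based optimizer modeled on employees adjusting their effort:
#' the best performers pass to the next iteration unchanged (reward
#' policy), while the others propose moves relative to either a random
#' colleague (exploration) or the best member (exploitation), keeping a
#' proposal only when it improves their error.
#'
#' @param pop_size population size (>= 4).
#' @param iter_max iterations.
#' @param elite_frac fraction of the population passed through unchanged
#'   (at least one member).
#' @param toward_reference the printed update moves a member *away* from
#'   the reference (`EM_i + r (EM_i - ref)`); set `TRUE` to flip the sign
#'   and move toward it instead.
#' @param seed RNG seed.
#' @return object of class `eoa_params`.
#' @export
eoa_params <- function(pop_size = 10, iter_max = 20, elite_frac = 0.1,
                       toward_reference = FALSE, seed = 1L) {
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (iter_max < 0) stop("iter_max must be >= 0")
  if (elite_frac <= 0 || elite_frac >= 1)
    stop("elite_frac must lie in (0, 1)")
  structure(list(pop_size = as.integer(pop_size),
                 iter_max = as.integer(iter_max),
                 elite_frac = elite_frac,
                 toward_reference = isTRUE(toward_reference),
                 seed = as.integer(seed)),
            class = "eoa_params")
}

#' One population update of the employee optimization algorithm
#'
#' Elite members (top `elite_frac`, at least one) pass through unchanged.
#' Every other member `i` proposes `EM_i + r * (EM_i - ref)` with
#' `r ~ U(0,1)` per coordinate, where `ref` is the best member
#' (exploitation) or a random other member (exploration); with
#' `toward_reference = TRUE` the sign of the step flips. Proposals are
#' clamped to `[0, 1]` and accepted greedily (only when the objective
#' value, lower is better, improves). A proposal with a non-finite
#' objective value is rejected with a warning.
#'
#' @param positions numeric matrix (pop x dim) in `[0, 1]`.
#' @param values objective values of the rows (lower is better).
#' @param objective function mapping a position vector to a scalar.
#' @param params an [eoa_params()].
#' @param explore logical scalar or vector (recycled over non-elite
#'   members): exploration vs exploitation move per member.
#' @param r optional fixed step factor(s) replacing the uniform draws
#'   (exposed for testing).
#' @return list with updated `positions` and `values`.
#' @export
eoa_step <- function(positions, values, objective, params,
                     explore = TRUE, r = NULL) {
  N <- nrow(positions)
  n_elite <- max(1L, floor(params$elite_frac * N))
  ord <- order(values, seq_along(values))
  elite <- ord[seq_len(n_elite)]
  best <- ord[1]
  movers <- setdiff(seq_len(N), elite)
  explore <- rep_len(explore, length(movers))
  sgn <- if (params$toward_reference) -1 else 1
  for (mi in seq_along(movers)) {
    i <- movers[mi]
    ref <- if (explore[mi])
      positions[sample(setdiff(seq_len(N), i), 1L), ]
    else positions[best, ]
    ri <- if (is.null(r)) stats::runif(ncol(positions)) else r
    prop <- positions[i, ] + sgn * ri * (positions[i, ] - ref)
    prop <- pmin(pmax(prop, 0), 1)
    pv <- objective(prop)
    if (!is.finite(pv)) {
      warning("non-finite objective value; proposal rejected")
      next
    }
    if (pv < values[i]) {
      positions[i, ] <- prop
      values[i] <- pv
    }
  }
  list(positions = positions, values = values)
}

#' Minimize an objective over the unit hypercube with the EOA
#'
#' Random initialization in `[0, 1]^dim`, then `iter_max` population
#' updates; at iteration `t` each non-elite member explores (random
#' reference) with probability `1 - t / iter_max` and otherwise exploits
#' (best reference). With `iter_max = 0` the best random initial member is
#' returned. Deterministic given `params$seed`.
#'
#' @param objective function mapping a position in `[0, 1]^dim` to a
#'   scalar (lower is better).
#' @param dim dimensionality.
#' @param params an [eoa_params()].
#' @return list with `best` (position), `value`, and `trace` (best value
#'   per iteration, non-increasing).
#' @export
eoa_optimize <- function(objective, dim, params = eoa_params()) {
  if (dim < 1) stop("dim must be >= 1")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  N <- params$pop_size
  positions <- matrix(stats::runif(N * dim), N, dim)
  values <- apply(positions, 1, objective)
  if (any(!is.finite(values)))
    stop("objective is non-finite on the initial population")
  trace <- numeric(params$iter_max)
  n_elite <- max(1L, floor(params$elite_frac * N))
  for (t in seq_len(params$iter_max)) {
    p_explore <- 1 - t / params$iter_max
    explore <- stats::runif(N - n_elite) < p_explore
    st <- eoa_step(positions, values, objective, params, explore = explore)
    positions <- st$positions
    values <- st$values
    trace[t] <- min(values)
  }
  best <- which.min(values)
  list(best = positions[best, ], value = values[best], trace = trace)
}

#' Hyperparameter bounds and decoding for classifier tuning
#'
#' Maps a point in `[0, 1]^3` to (learning rate, weight decay, momentum):
#' learning rate log-uniform in `[1e-4, 1e-1]`, decay log-uniform in
#' `[1e-6, 1e-2]`, momentum linear in `[0.5, 0.99]`.
#'
#' @param position numeric vector of length 3 in `[0, 1]`.
#' @return named list with `learning_rate`, `decay`, `momentum`.
#' @export
decode_hyperparameters <- function(position) {
  if (length(position) != 3) stop("position must have length 3")
  loguni <- function(u, lo, hi) exp(log(lo) + u * (log(hi) - log(lo)))
  list(learning_rate = loguni(position[1], 1e-4, 1e-1),
       decay = loguni(position[2], 1e-6, 1e-2),
       momentum = 0.5 + position[3] * (0.99 - 0.5))
}

#' Tune training hyperparameters with the employee optimization algorithm
#'
#' Splits the data into a training part and a validation part (stratified,
#' `val_frac` of each class), and minimizes the validation error rate of a
#' truncated training run (`tune_epochs` epochs) over learning rate, weight
#' decay and momentum via [eoa_optimize()]. Ties in validation error are
#' broken by final training loss, so the search stays informative on
#' plateaus; a candidate whose training diverges scores worst.
#'
#' @param X feature matrix; `y` labels as in [bddnet_train()].
#' @param y class labels.
#' @param config base [bddnet_config()]; the tuned fields are overwritten.
#' @param params an [eoa_params()].
#' @param val_frac validation fraction per class.
#' @param tune_epochs epochs per candidate evaluation.
#' @return list with `config` (tuned), `hyperparameters`, `value`
#'   (best objective) and `trace`.
#' @export
tune_hyperparameters <- function(X, y, config, params = eoa_params(),
                                 val_frac = 0.2, tune_epochs = 5) {
  X <- as.matrix(X)
  if (is.character(y)) y <- class_code(y)
  y <- as.integer(y)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  sp <- stratified_indices(y, val_frac)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xva <- X[sp$test, , drop = FALSE]; yva <- y[sp$test]
  objective <- function(pos) {
    hp <- decode_hyperparameters(pos)
    cfg <- config
    cfg$learning_rate <- hp$learning_rate
    cfg$decay <- hp$decay
    cfg$momentum <- hp$momentum
    cfg$epochs <- as.integer(tune_epochs)
    fit <- tryCatch(bddnet_train(Xtr, ytr, cfg),
                    error = function(e) NULL)
    if (is.null(fit)) return(2)
    final_loss <- utils::tail(fit$loss_trace, 1)
    if (!is.finite(final_loss)) return(2)
    err <- mean(bddnet_predict(fit, Xva)$code != yva)
    err + 1e-3 * min(final_loss, 1)
  }
  res <- eoa_optimize(objective, dim = 3, params)
  hp <- decode_hyperparameters(res$best)
  config$learning_rate <- hp$learning_rate
  config$decay <- hp$decay
  config$momentum <- hp$momentum
  list(config = config, hyperparameters = hp, value = res$value,
       trace = res$trace)
}
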