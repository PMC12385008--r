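#' Hybrid classifier configuration
#'
#' Architecture and training settings of the three-branch network: a 1-D
#' deep convolutional branch (three conv/batch-norm/ReLU/max-pool stages),
#' a two-layer bidirectional LSTM branch sequencing over per-channel feature
#' blocks, and a deep-belief branch (stack of RBM-pretrained sigmoid
#' layers), fused by concatenation into one fully connected softmax head.
#'
#' @param n_features length of the input feature vector.
#' @param conv_filters filter counts of the three convolution stages.
#' @param conv_kernel kernel length (3, i.e. 3x1 filters).
#' @param bilstm_layers,bilstm_units recurrent depth and hidden units per
#'   direction.
#' @param rbm_units hidden sizes of the stacked RBMs.
#' @param dropout dropout probability on the fused vector (train mode only).
#' @param learning_rate initial learning rate of mini-batch gradient
#'   descent.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param momentum,decay SGD momentum and weight decay (tunable by the
#'   employee optimization algorithm).
#' @param step sequence-step width for the recurrent branch; the feature
#'   vector is chunked into `n_features / step` steps (default 527, one step
#'   per channel block). Must divide `n_features`.
#' @param pretrain whether to greedily pretrain the belief branch with CD-1.
#' @param pretrain_epochs,pretrain_lr contrastive-divergence settings.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return object of class `bddnet_config`.
#' @export
bddnet_config <- function(n_features,
                          conv_filters = c(64, 128, 256),
                          conv_kernel = 3,
                          bilstm_layers = 2, bilstm_units = 50,
                          rbm_units = c(200, 150, 100),
                          dropout = 0.5, learning_rate = 0.001,
                          batch_size = 16, epochs = 200,
                          momentum = 0.9, decay = 1e-4,
                          step = 527,
                          pretrain = TRUE, pretrain_epochs = 5,
                          pretrain_lr = 0.05, seed = 1L) {
  if (n_features < 1) stop("n_features must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (any(c(conv_filters, bilstm_layers, bilstm_units, rbm_units,
            batch_size) < 1)) stop("counts must be positive")
  if (n_features %% step != 0)
    stop("`step` must divide `n_features` (one step per channel block)")
  structure(list(n_features = as.integer(n_features),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 bilstm_layers = as.integer(bilstm_layers),
                 bilstm_units = as.integer(bilstm_units),
                 rbm_units = as.integer(rbm_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 momentum = momentum, decay = decay,
                 step = as.integer(step),
                 pretrain = isTRUE(pretrain),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_lr = pretrain_lr,
                 seed = as.integer(seed), n_classes = 2L),
            class = "bddnet_config")
}

conv_out_length <- function(L, config) {
  for (f in config$conv_filters) L <- (L - config$conv_kernel + 1L) %/% 2L
  L
}

#' Initialize network parameters
#'
#' He-scaled Gaussian weights for convolutional and dense layers, uniform
#' `+/- 1/sqrt(H)` for recurrent gates, zero biases, unit batch-norm scale.
#'
#' @param config a [bddnet_config()].
#' @return a `bddnet_params` list (field `net`) with empty input-scaling
#'   slots filled in by [bddnet_train()].
#' @export
bddnet_init <- function(config) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                nr, nc)
  net <- list()
  cin <- 1L
  net$conv <- list()
  for (l in seq_along(config$conv_filters)) {
    cout <- config$conv_filters[l]
    net$conv[[l]] <- list(W = he(config$conv_kernel * cin, cout),
                          b = numeric(cout),
                          gamma = rep(1, cout), beta = numeric(cout),
                          run_mean = numeric(cout), run_var = rep(1, cout))
    cin <- cout
  }
  H <- config$bilstm_units
  net$lstm <- list()
  din <- config$step
  for (l in seq_len(config$bilstm_layers)) {
    lim <- 1 / sqrt(H)
    mk <- function() list(
      W = matrix(stats::runif((din + H) * 4 * H, -lim, lim), din + H, 4 * H),
      b = c(numeric(H), rep(1, H), numeric(2 * H)))  # forget-gate bias 1
    net$lstm[[l]] <- list(fwd = mk(), bwd = mk())
    din <- 2L * H
  }
  net$rbm <- list()
  vis <- config$n_features
  for (l in seq_along(config$rbm_units)) {
    hid <- config$rbm_units[l]
    net$rbm[[l]] <- list(W = matrix(stats::rnorm(vis * hid, 0, 0.01),
                                    vis, hid),
                         b = numeric(vis), c = numeric(hid))
    vis <- hid
  }
  L <- conv_out_length(config$n_features, config)
  fused <- L * utils::tail(config$conv_filters, 1) + 2L * H +
    utils::tail(config$rbm_units, 1)
  net$fc <- list(W = he(fused, config$n_classes),
                 b = numeric(config$n_classes))
  structure(list(net = net, scale = NULL, config = config),
            class = "bddnet_params")
}

scale_z <- function(X, sc) sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
scale_mm <- function(X, sc) {
  out <- sweep(sweep(X, 2, sc$mn, "-"), 2, sc$rng, "/")
  pmin(pmax(out, 0), 1)
}

#' Forward pass of the hybrid classifier
#'
#' @param params a trained (or initialized + scaled) `bddnet_params`.
#' @param X feature matrix (rows = trials) or a single feature vector.
#' @param mode `"eval"` (running batch-norm statistics, no dropout) or
#'   `"train"`.
#' @return matrix of class probabilities (rows sum to 1); with
#'   `full = TRUE` internally, the cache for backpropagation.
#' @export
bddnet_forward <- function(params, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  fwd <- bddnet_forward_cache(params, as_feature_matrix(X, params), mode)
  fwd$probs
}

as_feature_matrix <- function(X, params) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != params$config$n_features)
    stop(sprintf("feature length %d does not match the configured %d",
                 ncol(X), params$config$n_features))
  X
}

bddnet_forward_cache <- function(params, X, mode, dropout_mask = NULL) {
  net <- params$net
  config <- params$config
  if (is.null(params$scale))
    stop("untrained parameters: input scaling has not been fitted")
  if (any(!is.finite(unlist(net$fc))))
    stop("parameter state contains non-finite values")
  b <- nrow(X)
  Xz <- scale_z(X, params$scale)
  Xmm <- scale_mm(X, params$scale)
  cache <- list(mode = mode)
  # --- convolutional branch
  A <- array(Xz, c(b, ncol(X), 1L))
  cache$conv <- list()
  for (l in seq_along(net$conv)) {
    p <- net$conv[[l]]
    cv <- conv1d_forward(A, p$W, p$b)
    bn <- bn_forward(cv$out, p$gamma, p$beta, p$run_mean, p$run_var, mode)
    rl <- relu_forward(bn$out)
    mp <- maxpool2_forward(rl$out)
    cache$conv[[l]] <- list(cv = cv, bn = bn, rl = rl, mp = mp)
    A <- mp$out
  }
  conv_flat <- matrix(A, nrow = b)
  # --- recurrent branch
  Tn <- config$n_features %/% config$step
  S <- array(Xz, c(b, config$step, Tn))   # features are channel-major blocks
  S <- aperm(S, c(1, 3, 2))               # (b, T, step)
  cache$lstm <- list()
  inp <- S
  for (l in seq_along(net$lstm)) {
    fw <- lstm_forward(inp, net$lstm[[l]]$fwd$W, net$lstm[[l]]$fwd$b,
                       reverse = FALSE)
    bw <- lstm_forward(inp, net$lstm[[l]]$bwd$W, net$lstm[[l]]$bwd$b,
                       reverse = TRUE)
    H <- config$bilstm_units
    out <- array(0, c(b, Tn, 2L * H))
    out[, , 1:H] <- fw$H_seq
    out[, , (H + 1):(2 * H)] <- bw$H_seq
    cache$lstm[[l]] <- list(fw = fw, bw = bw)
    inp <- out
  }
  H <- config$bilstm_units
  lstm_out <- cbind(matrix(inp[, Tn, 1:H], nrow = b),
                    matrix(inp[, 1, (H + 1):(2 * H)], nrow = b))
  # --- belief-network branch
  dbn <- dbn_forward(Xmm, net$rbm)
  # --- fusion
  Z <- cbind(conv_flat, lstm_out, dbn$out)
  if (mode == "train" && config$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::runif(length(Z)) >= config$dropout,
                             nrow(Z), ncol(Z)) / (1 - config$dropout)
    Zd <- Z * dropout_mask
  } else {
    dropout_mask <- NULL
    Zd <- Z
  }
  logits <- sweep(Zd %*% net$fc$W, 2, net$fc$b, "+")
  probs <- softmax_rows(logits)
  cache$dbn <- dbn
  cache$Z <- Z
  cache$Zd <- Zd
  cache$dropout_mask <- dropout_mask
  cache$dims <- list(b = b, Tn = Tn,
                     conv_flat_n = ncol(conv_flat),
                     lstm_n = ncol(lstm_out))
  list(probs = probs, cache = cache)
}

bddnet_loss_grads <- function(params, X, Y, mode = "train",
                              dropout_mask = NULL) {
  net <- params$net
  config <- params$config
  fwd <- bddnet_forward_cache(params, X, mode, dropout_mask)
  cache <- fwd$cache
  b <- nrow(X)
  loss <- -sum(Y * log(pmax(fwd$probs, 1e-12))) / b
  dlogits <- (fwd$probs - Y) / b
  g <- list()
  g$fc <- list(W = crossprod(cache$Zd, dlogits), b = colSums(dlogits))
  dZd <- dlogits %*% t(net$fc$W)
  dZ <- if (!is.null(cache$dropout_mask)) dZd * cache$dropout_mask else dZd
  nconv <- cache$dims$conv_flat_n
  nlstm <- cache$dims$lstm_n
  d_conv_flat <- dZ[, seq_len(nconv), drop = FALSE]
  d_lstm_out <- dZ[, nconv + seq_len(nlstm), drop = FALSE]
  d_dbn <- dZ[, (nconv + nlstm + 1):ncol(dZ), drop = FALSE]
  # --- convolutional branch backward
  lastc <- cache$conv[[length(cache$conv)]]
  dA <- array(d_conv_flat, dim(lastc$mp$out))
  g$conv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    cc <- cache$conv[[l]]
    p <- net$conv[[l]]
    dA <- maxpool2_backward(dA, cc$mp)
    dA <- relu_backward(dA, cc$rl)
    bb <- bn_backward(dA, cc$bn, p$gamma)
    cvb <- conv1d_backward(bb$dX, cc$cv, p$W)
    g$conv[[l]] <- list(W = cvb$dW, b = cvb$db,
                        gamma = bb$dgamma, beta = bb$dbeta,
                        run_mean = 0 * p$run_mean, run_var = 0 * p$run_var)
    dA <- cvb$dA
  }
  # --- recurrent branch backward
  H <- config$bilstm_units
  Tn <- cache$dims$Tn
  nl <- length(net$lstm)
  dSeq <- array(0, c(b, Tn, 2L * H))
  dSeq[, Tn, 1:H] <- d_lstm_out[, 1:H, drop = FALSE]
  dSeq[, 1, (H + 1):(2 * H)] <- d_lstm_out[, (H + 1):(2 * H), drop = FALSE]
  g$lstm <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    cc <- cache$lstm[[l]]
    dfw <- lstm_backward(dSeq[, , 1:H, drop = FALSE], cc$fw,
                         net$lstm[[l]]$fwd$W)
    dbw <- lstm_backward(dSeq[, , (H + 1):(2 * H), drop = FALSE], cc$bw,
                         net$lstm[[l]]$bwd$W)
    g$lstm[[l]] <- list(fwd = list(W = dfw$dW, b = dfw$db),
                        bwd = list(W = dbw$dW, b = dbw$db))
    if (l > 1) dSeq <- dfw$dX + dbw$dX
  }
  # --- belief-network branch backward
  rbm_g <- dbn_backward(d_dbn, cache$dbn, net$rbm)
  g$rbm <- lapply(seq_along(net$rbm), function(l)
    list(W = rbm_g[[l]]$W, b = 0 * net$rbm[[l]]$b, c = rbm_g[[l]]$c))
  # propagate updated batch-norm running statistics
  run_stats <- lapply(cache$conv, function(cc)
    list(run_mean = cc$bn$run_mean, run_var = cc$bn$run_var))
  list(loss = loss, grads = g, run_stats = run_stats, probs = fwd$probs)
}

# momentum SGD update of one leaf; weight decay on weight matrices only
sgd_leaf <- function(w, gr, v, lr, mom, decay, is_weight) {
  v <- mom * v - lr * (gr + if (is_weight) decay * w else 0)
  list(w = w + v, v = v)
}

zeros_like_tree <- function(x) {
  if (is.list(x)) lapply(x, zeros_like_tree) else x * 0
}

sgd_update_tree <- function(p, g, v, lr, mom, decay, name = "") {
  if (is.list(p)) {
    out_p <- p; out_v <- v
    for (nm in names(p)) {
      if (nm %in% c("run_mean", "run_var")) next
      r <- sgd_update_tree(p[[nm]], g[[nm]], v[[nm]], lr, mom, decay, nm)
      out_p[[nm]] <- r$p
      out_v[[nm]] <- r$v
    }
    if (is.null(names(p))) {
      for (i in seq_along(p)) {
        r <- sgd_update_tree(p[[i]], g[[i]], v[[i]], lr, mom, decay, name)
        out_p[[i]] <- r$p
        out_v[[i]] <- r$v
      }
    }
    list(p = out_p, v = out_v)
  } else {
    r <- sgd_leaf(p, g, v, lr, mom, decay, is_weight = (name == "W"))
    list(p = r$w, v = r$v)
  }
}

#' Greedy layer-wise CD-1 pretraining of the belief branch
#'
#' The first RBM is Gaussian-Bernoulli over min-max scaled features (linear
#' visible reconstruction); upper RBMs are Bernoulli-Bernoulli. One step of
#' contrastive divergence per mini-batch. Constant feature columns are
#' flagged with a warning (they carry no trainable signal; their scaled
#' value is identically zero).
#'
#' @param features numeric feature matrix (rows = trials).
#' @param config a [bddnet_config()].
#' @param scale optional precomputed scaling; computed from `features`
#'   otherwise.
#' @return list of RBM parameter lists (`W`, `b`, `c`).
#' @export
pretrain_dbn <- function(features, config, scale = NULL) {
  if (nrow(features) < 2) stop("pretraining needs at least 2 vectors")
  if (is.null(scale)) scale <- fit_scale(features)
  if (any(scale$rng == 1 & scale$constant))
    warning(sum(scale$constant), " constant feature column(s) carry no ",
            "signal for pretraining")
  V <- scale_mm(features, scale)
  rbms <- list()
  vis <- ncol(V)
  for (l in seq_along(config$rbm_units)) {
    hid <- config$rbm_units[l]
    W <- matrix(stats::rnorm(vis * hid, 0, 0.01), vis, hid)
    bv <- numeric(vis)
    ch <- numeric(hid)
    gaussian_vis <- (l == 1L)
    for (ep in seq_len(config$pretrain_epochs)) {
      idx <- sample(nrow(V))
      for (start in seq(1, nrow(V), by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1, nrow(V))]
        v0 <- V[rows, , drop = FALSE]
        h0 <- sigmoid(sweep(v0 %*% W, 2, ch, "+"))
        h0s <- (matrix(stats::runif(length(h0)), nrow(h0)) < h0) + 0
        v1 <- sweep(h0s %*% t(W), 2, bv, "+")
        if (!gaussian_vis) v1 <- sigmoid(v1)
        h1 <- sigmoid(sweep(v1 %*% W, 2, ch, "+"))
        nb <- length(rows)
        W <- W + config$pretrain_lr *
          (crossprod(v0, h0) - crossprod(v1, h1)) / nb
        bv <- bv + config$pretrain_lr * colSums(v0 - v1) / nb
        ch <- ch + config$pretrain_lr * colSums(h0 - h1) / nb
      }
    }
    rbms[[l]] <- list(W = W, b = bv, c = ch)
    V <- sigmoid(sweep(V %*% W, 2, ch, "+"))
    vis <- hid
  }
  rbms
}

fit_scale <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  constant <- sd == 0 | !is.finite(sd)
  sd[constant] <- 1
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  rng <- mx - mn
  rng[rng == 0] <- 1
  list(mu = mu, sd = sd, mn = mn, rng = rng, constant = constant)
}

#' Train the hybrid classifier by mini-batch gradient descent
#'
#' Fits the input scaling on the training set, optionally pretrains the
#' belief branch with CD-1, then minimizes the cross-entropy end to end
#' with shuffled mini-batches, momentum and weight decay. Deterministic
#' given `config$seed`.
#'
#' @param X numeric feature matrix (rows = trials).
#' @param y class labels: `"calm"`/`"stress"` strings or 0/1 codes
#'   (calm = 0, stress = 1).
#' @param config a [bddnet_config()]; its `n_features` must match `ncol(X)`.
#' @return a `bddnet_params` object with the per-epoch mean training loss
#'   in field `loss_trace`.
#' @export
bddnet_train <- function(X, y, config = bddnet_config(ncol(X))) {
  X <- as.matrix(X)
  if (is.character(y)) y <- class_code(y)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (ncol(X) != config$n_features)
    stop("config$n_features does not match ncol(X)")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  params <- bddnet_init(config)
  params$scale <- fit_scale(X)
  if (config$pretrain)
    params$net$rbm <- pretrain_dbn(X, config, params$scale)
  Y <- matrix(0, nrow(X), config$n_classes)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  vel <- zeros_like_tree(params$net)
  loss_trace <- numeric(config$epochs)
  n <- nrow(X)
  for (ep in seq_len(config$epochs)) {
    idx <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      rows <- idx[start:min(start + config$batch_size - 1, n)]
      lg <- bddnet_loss_grads(params, X[rows, , drop = FALSE],
                              Y[rows, , drop = FALSE])
      upd <- sgd_update_tree(params$net, lg$grads, vel,
                             config$learning_rate, config$momentum,
                             config$decay)
      params$net <- upd$p
      vel <- upd$v
      for (l in seq_along(lg$run_stats)) {
        params$net$conv[[l]]$run_mean <- lg$run_stats[[l]]$run_mean
        params$net$conv[[l]]$run_var <- lg$run_stats[[l]]$run_var
      }
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    loss_trace[ep] <- ep_loss / nb
  }
  params$loss_trace <- loss_trace
  params
}

#' Predict calm/stress classes
#'
#' Argmax of the softmax probabilities, ties broken toward calm (class 0).
#' Evaluation-mode forward pass: the prediction for a vector is identical
#' whether it is presented alone or inside a batch.
#'
#' @param params a trained `bddnet_params`.
#' @param X feature matrix or single feature vector.
#' @return list with `label` (character), `code` (0/1) and `probabilities`
#'   (matrix with columns `calm`, `stress`).
#' @export
bddnet_predict <- function(params, X) {
  probs <- bddnet_forward(params, X, mode = "eval")
  colnames(probs) <- c("calm", "stress")
  code <- as.integer(apply(probs, 1, which.max) - 1L)
  list(label = c("calm", "stress")[code + 1L], code = code,
       probabilities = probs)
}
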