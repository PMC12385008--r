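# Layer primitives for the hybrid classifier: 1-D valid convolution with
# im2col, batch normalization, ReLU, max pooling, LSTM cells and sigmoid
# stacks, each with a hand-derived backward pass. Arrays are (batch, length,
# channels); matrices collapse (batch, length) row-blocks in column-major
# order, so matrix(A, nrow = b * L) and its inverse are exact reshapes.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1-D convolution (valid) ------------------------------------------------

conv1d_forward <- function(A, W, bias) {
  dims <- dim(A)                       # (b, L, Cin)
  b <- dims[1]; L <- dims[2]; cin <- dims[3]
  K <- nrow(W) / cin
  L2 <- L - K + 1L
  cols <- array(0, c(b, L2, K * cin))
  for (kk in seq_len(K)) {
    cols[, , ((kk - 1L) * cin + 1L):(kk * cin)] <-
      A[, kk:(kk + L2 - 1L), , drop = FALSE]
  }
  M <- matrix(cols, nrow = b * L2)
  Y <- M %*% W
  Y <- sweep(Y, 2, bias, "+")
  list(out = array(Y, c(b, L2, ncol(W))), M = M, dims = dims, K = K)
}

conv1d_backward <- function(dY, cache, W) {
  b <- cache$dims[1]; L <- cache$dims[2]; cin <- cache$dims[3]
  K <- cache$K
  L2 <- L - K + 1L
  cout <- ncol(W)
  dYm <- matrix(dY, nrow = b * L2)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dCols <- array(dM, c(b, L2, K * cin))
  dA <- array(0, cache$dims)
  for (kk in seq_len(K)) {
    dA[, kk:(kk + L2 - 1L), ] <- dA[, kk:(kk + L2 - 1L), , drop = FALSE] +
      dCols[, , ((kk - 1L) * cin + 1L):(kk * cin), drop = FALSE]
  }
  list(dW = dW, db = db, dA = dA)
}

# ---- batch normalization (per output channel, over batch x positions) -------

bn_forward <- function(Y, gamma, beta, run_mean, run_var, mode,
                       eps = 1e-5, bn_momentum = 0.9) {
  dims <- dim(Y)
  cch <- dims[3]
  Ym <- matrix(Y, ncol = cch)           # (b*L) x C
  if (mode == "train") {
    mu <- colMeans(Ym)
    va <- colMeans(sweep(Ym, 2, mu, "-")^2)
    run_mean <- bn_momentum * run_mean + (1 - bn_momentum) * mu
    run_var <- bn_momentum * run_var + (1 - bn_momentum) * va
  } else {
    mu <- run_mean
    va <- run_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  norm <- sweep(sweep(Ym, 2, mu, "-"), 2, inv_sd, "*")
  out <- sweep(sweep(norm, 2, gamma, "*"), 2, beta, "+")
  list(out = array(out, dims), norm = norm, inv_sd = inv_sd, dims = dims,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dout, cache, gamma) {
  dims <- cache$dims
  m <- dims[1] * dims[2]
  dm <- matrix(dout, ncol = dims[3])
  dgamma <- colSums(dm * cache$norm)
  dbeta <- colSums(dm)
  dnorm <- sweep(dm, 2, gamma, "*")
  t1 <- sweep(dnorm, 2, colSums(dnorm) / m, "-")
  t2 <- cache$norm * matrix(colSums(dnorm * cache$norm) / m,
                            nrow = m, ncol = dims[3], byrow = TRUE)
  dx <- sweep(t1 - t2, 2, cache$inv_sd, "*")
  list(dX = array(dx, dims), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU and max pooling ---------------------------------------------------

relu_forward <- function(A) list(out = pmax(A, 0), mask = A > 0)
relu_backward <- function(dout, cache) dout * cache$mask

maxpool2_forward <- function(A) {
  dims <- dim(A)
  L3 <- dims[2] %/% 2L
  A1 <- A[, 2L * seq_len(L3) - 1L, , drop = FALSE]
  A2 <- A[, 2L * seq_len(L3), , drop = FALSE]
  first <- A1 >= A2                     # ties route to the earlier position
  list(out = ifelse(first, A1, A2), first = first, dims = dims, L3 = L3)
}

maxpool2_backward <- function(dout, cache) {
  dA <- array(0, cache$dims)
  L3 <- cache$L3
  dA[, 2L * seq_len(L3) - 1L, ] <- dout * cache$first
  dA[, 2L * seq_len(L3), ] <- dout * (!cache$first)
  dA
}

# ---- LSTM (one direction) ---------------------------------------------------
# W is (D + H) x 4H with gate blocks [input, forget, candidate, output];
# processing order is 1..T forward or T..1 backward; the returned sequence
# H_seq is indexed by original time.

lstm_forward <- function(X, W, bias, reverse = FALSE) {
  dims <- dim(X)                        # (b, T, D)
  b <- dims[1]; Tn <- dims[2]
  H <- ncol(W) / 4L
  order_t <- if (reverse) Tn:1 else 1:Tn
  h <- matrix(0, b, H)
  cst <- matrix(0, b, H)
  H_seq <- array(0, c(b, Tn, H))
  steps <- vector("list", Tn)
  for (s in seq_len(Tn)) {
    t <- order_t[s]
    xt <- matrix(X[, t, ], nrow = b)
    zin <- cbind(xt, h)
    G <- sweep(zin %*% W, 2, bias, "+")
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h <- o * tc
    H_seq[, t, ] <- h
    steps[[s]] <- list(zin = zin, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, c = cst, tc = tc, t = t)
  }
  list(H_seq = H_seq, steps = steps, dims = dims, reverse = reverse, H = H)
}

lstm_backward <- function(dH_seq, cache, W) {
  b <- cache$dims[1]; Tn <- cache$dims[2]; D <- cache$dims[3]
  H <- cache$H
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dX <- array(0, cache$dims)
  dh_next <- matrix(0, b, H)
  dc_next <- matrix(0, b, H)
  for (s in Tn:1) {
    st <- cache$steps[[s]]
    dh <- matrix(dH_seq[, st$t, ], nrow = b) + dh_next
    do <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dW <- dW + crossprod(st$zin, dG)
    db <- db + colSums(dG)
    dzin <- dG %*% t(W)
    dX[, st$t, ] <- dzin[, 1:D, drop = FALSE]
    dh_next <- dzin[, (D + 1):(D + H), drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- sigmoid stack (mean-field pass of the belief-network branch) -----------

dbn_forward <- function(X, rbms) {
  acts <- vector("list", length(rbms) + 1L)
  acts[[1]] <- X
  for (l in seq_along(rbms)) {
    acts[[l + 1]] <- sigmoid(sweep(acts[[l]] %*% rbms[[l]]$W, 2,
                                   rbms[[l]]$c, "+"))
  }
  list(out = acts[[length(acts)]], acts = acts)
}

dbn_backward <- function(dout, cache, rbms) {
  grads <- vector("list", length(rbms))
  d <- dout
  for (l in rev(seq_along(rbms))) {
    hidden <- cache$acts[[l + 1]]
    da <- d * hidden * (1 - hidden)
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], da), c = colSums(da))
    d <- da %*% t(rbms[[l]]$W)
  }
  grads
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
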