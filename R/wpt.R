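#' Daubechies analysis filters
#'
#' Orthonormal scaling (low-pass) and wavelet (high-pass) filter taps for the
#' db1-db3 family, with the quadrature-mirror relation
#' `g[n] = (-1)^n h[L-1-n]`.
#'
#' @param name one of `"db1"`, `"db2"`, `"db3"`.
#' @return list with elements `h` (low-pass) and `g` (high-pass).
#' @export
daubechies_filter <- function(name = c("db3", "db2", "db1")) {
  name <- match.arg(name)
  h <- switch(name,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314453416, 0.8365163037378079,
            0.2241438680420134, -0.12940952255126037),
    db3 = c(0.33267055295008263, 0.8068915093110925,
            0.45987750211849154, -0.13501102001025458,
            -0.08544127388202666, 0.03522629188570953))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

# one periodized analysis step: x (even length) -> approximation + detail
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(filt$h)
  idx <- (outer(2L * (seq_len(half) - 1L), 0:(L - 1L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% filt$h), d = drop(xm %*% filt$g))
}

# inverse of dwt_step (exact, by orthonormality of the periodized basis)
idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  L <- length(filt$h)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in 0:(L - 1L)) {
    pos <- ((base + m) %% n) + 1L
    contrib <- a * filt$h[m + 1L] + d * filt$g[m + 1L]
    if (anyDuplicated(pos)) {
      for (k in seq_along(pos)) x[pos[k]] <- x[pos[k]] + contrib[k]
    } else {
      x[pos] <- x[pos] + contrib
    }
  }
  x
}

#' Full wavelet-packet decomposition
#'
#' Decomposes a signal into the complete binary tree of `levels` filter-bank
#' splits with circular (periodized) boundary handling, so the transform is
#' orthonormal and exactly invertible at every dyadic length. Signals whose
#' length is not a multiple of `2^levels` are reflection-padded up to the
#' next multiple before analysis; [wpt_reconstruct()] crops back.
#'
#' @param x numeric signal.
#' @param wavelet filter name passed to [daubechies_filter()].
#' @param levels depth of the tree (the terminal level has `2^levels` nodes).
#' @return object of class `wpt` — a list with the terminal-node coefficient
#'   list `nodes` (in Paley/tree order), `levels`, `wavelet`, the original
#'   length `n`, and the padded length `n_pad`.
#' @export
wpt_decompose <- function(x, wavelet = "db3", levels = 3L) {
  n <- length(x)
  block <- 2^levels
  if (n < block)
    stop(sprintf("signal length %d is shorter than 2^levels = %d", n, block))
  n_pad <- as.integer(ceiling(n / block) * block)
  if (n_pad > n) {
    ext <- rev(x)[seq_len(n_pad - n)]  # reflection padding
    x <- c(x, ext)
  }
  filt <- daubechies_filter(wavelet)
  nodes <- list(x)
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- dwt_step(nodes[[i]], filt)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    nodes <- nxt
  }
  structure(list(nodes = nodes, levels = as.integer(levels),
                 wavelet = wavelet, n = n, n_pad = n_pad),
            class = "wpt")
}

#' Reconstruct a signal from a wavelet-packet decomposition
#'
#' Exact inverse of [wpt_decompose()] (identity to machine precision when the
#' coefficients are unmodified).
#'
#' @param w a `wpt` object, possibly with modified node coefficients.
#' @return numeric signal of the original length.
#' @export
wpt_reconstruct <- function(w) {
  stopifnot(inherits(w, "wpt"))
  filt <- daubechies_filter(w$wavelet)
  nodes <- w$nodes
  for (lev in seq_len(w$levels)) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- idwt_step(nodes[[2L * i - 1L]], nodes[[2L * i]], filt)
    }
    nodes <- nxt
  }
  nodes[[1L]][seq_len(w$n)]
}

#' Frequency (natural) ordering of terminal wavelet-packet nodes
#'
#' The terminal nodes of [wpt_decompose()] are stored in Paley (tree) order;
#' because the high-pass/decimate branch inverts the spectrum, ascending
#' frequency corresponds to the Gray-code permutation of the Paley index.
#'
#' @param levels tree depth.
#' @return integer vector `p` such that `nodes[p]` is in ascending frequency
#'   order.
#' @export
wpt_frequency_order <- function(levels) {
  f <- 0:(2^levels - 1)
  paley <- bitwXor(f, f %/% 2L)  # binary-reflected Gray code
  paley + 1L
}
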