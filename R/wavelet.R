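# Orthogonal Daubechies-4 (4-tap) discrete wavelet transform with
# periodic boundaries, for 2D/3D real or complex arrays. Used as the
# sparsity transform of the compressed-sensing reconstruction. The
# transform is orthonormal, so it preserves the l2 norm and its inverse
# is the exact transpose.

.db4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_g <- rev(.db4_h) * c(1, -1, 1, -1)

# one analysis step along the first axis of a matrix-shaped view
.dwt_step_axis <- function(x, axis) {
  d <- dim(x)
  perm <- seq_along(d)
  perm[c(1, axis)] <- perm[c(axis, 1)]
  x <- aperm(x, perm)
  dp <- dim(x)
  N <- dp[1]
  m <- matrix(x, N)
  idx <- function(s) ((s - 1) %% N) + 1
  half <- N / 2
  a <- matrix(0i, half, ncol(m)); dd <- a
  for (n_ in 1:4) {
    rows <- idx(2 * (seq_len(half) - 1) + n_)
    a <- a + .db4_h[n_] * m[rows, , drop = FALSE]
    dd <- dd + .db4_g[n_] * m[rows, , drop = FALSE]
  }
  out <- rbind(a, dd)
  dim(out) <- dp
  aperm(out, perm)
}

.idwt_step_axis <- function(x, axis) {
  d <- dim(x)
  perm <- seq_along(d)
  perm[c(1, axis)] <- perm[c(axis, 1)]
  x <- aperm(x, perm)
  dp <- dim(x)
  N <- dp[1]
  half <- N / 2
  m <- matrix(x, N)
  a <- m[seq_len(half), , drop = FALSE]
  dd <- m[half + seq_len(half), , drop = FALSE]
  out <- matrix(0i, N, ncol(m))
  idx <- function(s) ((s - 1) %% N) + 1
  for (n_ in 1:4) {
    rows <- idx(2 * (seq_len(half) - 1) + n_)
    out[rows, ] <- out[rows, ] + .db4_h[n_] * a + .db4_g[n_] * dd
  }
  dim(out) <- dp
  aperm(out, perm)
}

#' Multi-level separable Daubechies-4 wavelet transform
#'
#' Periodic orthonormal DWT of a 2D or 3D array; at each level all axes
#' of the current low-pass block are transformed and the block halves.
#' The number of levels is capped so every dimension stays divisible
#' by two.
#'
#' @param x Real or complex array (2D or 3D).
#' @param levels Requested decomposition depth (default 3).
#' @return Array of wavelet coefficients (same shape), with attribute
#'   `levels` = depth actually used.
#' @export
dwt_db4 <- function(x, levels = 3) {
  d <- dim(x)
  # each transformed block must be even and >= 4 samples per axis
  lmax_dim <- vapply(d, function(m) {
    l <- 0L
    while (m %% 2 == 0 && m >= 4) { l <- l + 1L; m <- m %/% 2L }
    l
  }, 1L)
  lmax <- min(lmax_dim)
  if (lmax < 1) stop("array dimensions too small/odd for the wavelet transform")
  levels <- max(1, min(levels, lmax))
  cur <- d
  for (l in seq_len(levels)) {
    blk <- do.call(`[`, c(list(x), lapply(cur, seq_len), list(drop = FALSE)))
    for (ax in seq_along(d)) blk <- .dwt_step_axis(blk, ax)
    x <- do.call(`[<-`, c(list(x), lapply(cur, seq_len), list(blk)))
    cur <- cur %/% 2L
  }
  attr(x, "levels") <- levels
  x
}

#' @rdname dwt_db4
#' @param w Coefficient array produced by [dwt_db4()].
#' @export
idwt_db4 <- function(w, levels = attr(w, "levels")) {
  d <- dim(w)
  cur <- d %/% (2L^(levels - 1))
  for (l in seq_len(levels)) {
    blk <- do.call(`[`, c(list(w), lapply(cur, seq_len), list(drop = FALSE)))
    for (ax in rev(seq_along(d))) blk <- .idwt_step_axis(blk, ax)
    w <- do.call(`[<-`, c(list(w), lapply(cur, seq_len), list(blk)))
    cur <- cur * 2L
  }
  attr(w, "levels") <- NULL
  w
}
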