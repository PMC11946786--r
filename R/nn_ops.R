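# Pure numeric neural-network kernels (no gradient tracking).
# Feature maps are (H, W, C) arrays; convolution weights are
# (k, k, C_in, C_out) arrays; depth-wise kernels are (k, k, C).
# The autodiff layer in autodiff.R wraps these forwards with backwards.

.op_cache <- new.env(parent = emptyenv())

# im2col index map for an (H, W) plane: idx[p, t] is the linear index into
# the zero-padded plane of kernel offset t for output pixel p. Output pixels
# are ordered column-major over (oh, ow); kernel offsets have the row offset
# varying fastest, matching R's flattening of a (k, k, ...) weight array.
#' @noRd
im2col_meta <- function(H, W, k, stride, pad) {
  key <- paste("i2c", H, W, k, stride, pad, sep = "_")
  m <- .op_cache[[key]]
  if (!is.null(m)) return(m)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oh <- (Hp - k) %/% stride + 1L
  ow <- (Wp - k) %/% stride + 1L
  stop_if(oh < 1L || ow < 1L,
          "convolution input %dx%d too small for kernel %d / stride %d",
          H, W, k, stride)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  i0 <- (oi - 1L) * stride + 1L
  j0 <- (oj - 1L) * stride + 1L
  idx <- matrix(0L, oh * ow, k * k)
  t <- 1L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    # a: kernel row offset (fastest), b: kernel column offset
    idx[, t] <- (i0 + a - 1L) + Hp * (j0 + b - 2L)
    t <- t + 1L
  }
  m <- list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
  .op_cache[[key]] <- m
  m
}

#' @noRd
pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  xp
}

# Forward 2D convolution; returns output plus the im2col matrix needed by
# the backward pass.
#' @noRd
conv2d_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  dx <- dim(x); dw <- dim(w)
  k <- dw[1L]; cin <- dw[3L]; cout <- dw[4L]
  stop_if(dx[3L] != cin, "conv2d: input has %d channels, kernel expects %d",
          dx[3L], cin)
  meta <- im2col_meta(dx[1L], dx[2L], k, stride, pad)
  xp <- pad_hw(x, pad)
  dim(xp) <- c(meta$Hp * meta$Wp, cin)
  xcol <- xp[as.vector(meta$idx), , drop = FALSE]
  dim(xcol) <- c(nrow(meta$idx), k * k * cin)
  wm <- w; dim(wm) <- c(k * k * cin, cout)
  y <- xcol %*% wm
  if (!is.null(b)) y <- y + matrix(b, nrow(y), cout, byrow = TRUE)
  dim(y) <- c(meta$oh, meta$ow, cout)
  list(y = y, xcol = xcol, meta = meta)
}

#' @noRd
conv2d_bwd <- function(g, fw, w, stride, pad, xdim) {
  dw <- dim(w); k <- dw[1L]; cin <- dw[3L]; cout <- dw[4L]
  meta <- fw$meta
  P <- nrow(meta$idx)
  gm <- g; dim(gm) <- c(P, cout)
  dwm <- crossprod(fw$xcol, gm)
  dim(dwm) <- dw
  db <- colSums(gm)
  wm <- w; dim(wm) <- c(k * k * cin, cout)
  dxcol <- gm %*% t(wm)
  dim(dxcol) <- c(P, k * k, cin)
  dxp <- matrix(0, meta$Hp * meta$Wp, cin)
  for (t in seq_len(k * k)) {
    rows <- meta$idx[, t]
    dxp[rows, ] <- dxp[rows, ] + dxcol[, t, ]
  }
  dim(dxp) <- c(meta$Hp, meta$Wp, cin)
  dx <- if (pad > 0L)
    dxp[pad + seq_len(xdim[1L]), pad + seq_len(xdim[2L]), , drop = FALSE]
  else dxp
  dim(dx) <- xdim
  list(dx = dx, dw = dwm, db = db)
}

# Depth-wise kernels are embedded in a block-diagonal dense kernel so the
# same im2col machinery serves; gradients are gathered back per channel.
#' @noRd
dw_dense <- function(w) {
  d <- dim(w); k <- d[1L]; C <- d[3L]
  dense <- array(0, c(k, k, C, C))
  for (c in seq_len(C)) dense[, , c, c] <- w[, , c]
  dense
}

#' @noRd
dw_gather <- function(dense_grad) {
  d <- dim(dense_grad); k <- d[1L]; C <- d[3L]
  g <- array(0, c(k, k, C))
  for (c in seq_len(C)) g[, , c] <- dense_grad[, , c, c]
  g
}

# Row/column interpolation matrix for separable bilinear resizing
# (half-pixel-centre convention, edges clamped).
#' @noRd
bilin_mat <- function(nin, nout) {
  key <- paste("bl", nin, nout, sep = "_")
  m <- .op_cache[[key]]
  if (!is.null(m)) return(m)
  M <- matrix(0, nout, nin)
  for (i in seq_len(nout)) {
    src <- (i - 0.5) * nin / nout + 0.5
    i0 <- floor(src); f <- src - i0
    lo <- clamp(i0, 1, nin); hi <- clamp(i0 + 1, 1, nin)
    M[i, lo] <- M[i, lo] + (1 - f)
    M[i, hi] <- M[i, hi] + f
  }
  .op_cache[[key]] <- M
  M
}

#' @noRd
upsample_bilinear_fwd <- function(x, oh, ow) {
  d <- dim(x)
  R <- bilin_mat(d[1L], oh); S <- bilin_mat(d[2L], ow)
  y <- array(0, c(oh, ow, d[3L]))
  for (c in seq_len(d[3L])) y[, , c] <- R %*% x[, , c] %*% t(S)
  y
}

#' @noRd
gelu <- function(x) x * stats::pnorm(x)

#' @noRd
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @noRd
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gm <- matrix(gamma, nrow(x), ncol(x), byrow = TRUE)
  bm <- matrix(beta, nrow(x), ncol(x), byrow = TRUE)
  list(y = xhat * gm + bm, xhat = xhat, inv = inv, gm = gm)
}
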