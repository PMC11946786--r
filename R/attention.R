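# Retention and Manhattan self-attention primitives.
#
# Token order convention, used everywhere in this package: tokens on an
# H x W grid are enumerated ROW-MAJOR, i.e. token n (1-based) sits at
#   x_n = (n - 1) %/% W   (row index, 0-based)
#   y_n = (n - 1) %%  W   (column index, 0-based)
# so the first W tokens are the first row left-to-right. `token_flatten()`
# and `token_unflatten()` implement the convention once; every attention
# routine and every decay matrix reuses it.

#' Flatten a token field to row-major token order
#'
#' A token field is a rank-3 array `(H, W, d)`: an `H x W` grid of
#' `d`-dimensional embeddings. Flattening enumerates grid positions
#' row-major (row 1 left-to-right, then row 2, ...), producing an
#' `(H*W) x d` matrix whose row `n` is the token at 0-based coordinates
#' `x = (n-1) %/% W`, `y = (n-1) %% W`.
#'
#' @param x numeric array `(H, W, d)`.
#' @return numeric matrix `(H*W, d)`.
#' @seealso [token_unflatten()]
#' @export
#' @examples
#' f <- array(1:8, c(2, 2, 2))
#' token_flatten(f)
token_flatten <- function(x) {
  stop_if(length(dim(x)) != 3L, "token field must be a rank-3 (H, W, d) array")
  d <- dim(x)
  y <- aperm(x, c(2L, 1L, 3L))
  dim(y) <- c(d[1L] * d[2L], d[3L])
  y
}

#' Restore a row-major token matrix to an (H, W, d) field
#'
#' @param m numeric matrix `(H*W, d)` in row-major token order.
#' @param H,W grid dimensions.
#' @return numeric array `(H, W, d)`.
#' @export
token_unflatten <- function(m, H, W) {
  stop_if(nrow(m) != H * W, "matrix has %d rows, expected H*W = %d",
          nrow(m), H * W)
  y <- m
  dim(y) <- c(W, H, ncol(m))
  aperm(y, c(2L, 1L, 3L))
}

#' Numerically stable row-wise softmax
#'
#' Applies the softmax independently to each row of `M` after subtracting
#' the row maximum, so each row of the result is positive and sums to 1.
#'
#' @param M numeric matrix with finite entries.
#' @return matrix of the same shape; rows sum to 1.
#' @export
#' @examples
#' softmax_rows(matrix(0, 2, 2))          # all 0.5
#' softmax_rows(matrix(c(0, log(3)), 1))  # 0.25, 0.75
softmax_rows <- function(M) {
  M <- as.matrix(M)
  check_finite(M, "softmax input")
  rmax <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  e <- exp(M - rmax)
  e / rowSums(e)
}

#' Causal 1D decay matrix
#'
#' The retention decay `D` for a length-`n` sequence:
#' `D[i, j] = gamma^(i - j)` for `i >= j` and 0 above the diagonal, combining
#' causal masking with exponential decay in relative position.
#'
#' @param n sequence length (`>= 1`).
#' @param gamma decay rate, strictly inside `(0, 1)`.
#' @return `n x n` lower-triangular matrix with unit diagonal; attributes
#'   `kind = "causal_1d"` and `gamma`.
#' @export
#' @examples
#' decay_1d(3, 0.5)
decay_1d <- function(n, gamma) {
  stop_if(!is_wholenumber(n) || n < 1, "n must be a positive integer")
  check_gamma(gamma)
  e <- outer(seq_len(n) - 1L, seq_len(n) - 1L, "-")
  D <- ifelse(e >= 0, gamma^e, 0)
  structure(D, kind = "causal_1d", gamma = gamma)
}

#' Axis-wise symmetric decay matrix
#'
#' One-dimensional spatial decay `D[i, j] = gamma^|i - j|` over `n`
#' positions along a single grid axis. With `kind = "horizontal"` the
#' positions are column coordinates (the decay used by the horizontal
#' attention factor); with `kind = "vertical"` they are row coordinates.
#' The numeric content is identical; the kind labels the axis.
#'
#' @param n number of positions along the axis.
#' @inheritParams decay_1d
#' @param kind `"horizontal"` or `"vertical"`.
#' @return symmetric `n x n` matrix with unit diagonal.
#' @export
decay_axis <- function(n, gamma, kind = c("horizontal", "vertical")) {
  kind <- match.arg(kind)
  stop_if(!is_wholenumber(n) || n < 1, "n must be a positive integer")
  check_gamma(gamma)
  D <- gamma^abs(outer(seq_len(n) - 1L, seq_len(n) - 1L, "-"))
  structure(D, kind = kind, gamma = gamma)
}

#' Manhattan spatial decay matrix for an H x W token grid
#'
#' Entry `(n, m)` is `gamma` raised to the Manhattan distance
#' `|x_n - x_m| + |y_n - y_m|` between the grid coordinates of tokens `n`
#' and `m` under the package's row-major token order. The matrix is
#' symmetric with unit diagonal and entries in `(0, 1]`.
#'
#' @param H,W grid dimensions (`>= 1`).
#' @inheritParams decay_1d
#' @return `(H*W) x (H*W)` matrix; attributes `kind = "manhattan_2d"`,
#'   `gamma`.
#' @export
#' @examples
#' decay_2d(2, 2, 0.5)
decay_2d <- function(H, W, gamma) {
  stop_if(!is_wholenumber(H) || H < 1 || !is_wholenumber(W) || W < 1,
          "H and W must be positive integers")
  check_gamma(gamma)
  n <- seq_len(H * W) - 1L
  xs <- n %/% W
  ys <- n %% W
  D <- gamma^(abs(outer(xs, xs, "-")) + abs(outer(ys, ys, "-")))
  structure(D, kind = "manhattan_2d", gamma = gamma)
}

#' One-dimensional retention
#'
#' `Retention(X) = (Q K' %o% D) V` where `%o%` is the Hadamard product and
#' `D` is the causal 1D decay matrix. There is no softmax in retention.
#'
#' @param Q,K,V numeric `N x d` matrices.
#' @inheritParams decay_1d
#' @param decay optional decay matrix overriding `decay_1d(N, gamma)`
#'   (useful for probing limiting cases).
#' @return `N x d` matrix.
#' @export
retention_1d <- function(Q, K, V, gamma, decay = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stop_if(!all(dim(Q) == dim(K)) || !all(dim(Q) == dim(V)),
          "Q, K, V must share the same N x d shape")
  D <- if (is.null(decay)) decay_1d(nrow(Q), gamma) else decay
  ((Q %*% t(K)) * D) %*% V
}

#' Full 2D Manhattan self-attention
#'
#' Tokens are flattened row-major; the output is
#' `(softmax_rows(Q K') %o% D2d) V`, restored to the `(H, W, d)` layout of
#' `V`. Rows of the masked attention matrix are intentionally NOT
#' renormalised after the Hadamard product with the decay matrix: the decay
#' reweights attention in favour of spatially close tokens.
#'
#' @param q,k,v numeric arrays `(H, W, d)` (token fields) of equal shape.
#' @inheritParams decay_1d
#' @return array `(H, W, d)`.
#' @export
masa_full <- function(q, k, v, gamma) {
  stop_if(!all(dim(q) == dim(k)) || !all(dim(q) == dim(v)),
          "q, k, v must share the same (H, W, d) shape")
  H <- dim(q)[1L]; W <- dim(q)[2L]
  Qm <- token_flatten(q); Km <- token_flatten(k); Vm <- token_flatten(v)
  D <- decay_2d(H, W, gamma)
  A <- softmax_rows(Qm %*% t(Km)) * D
  token_unflatten(A %*% Vm, H, W)
}

#' Decomposed Manhattan self-attention
#'
#' Factorises 2D Manhattan self-attention into two 1D attentions applied in
#' sequence, each with its own axis-wise decay. Inputs stay in `(H, W, d)`
#' layout (they are never flattened to `N x d`):
#'
#' 1. vertical factor — within every column `w`, attention across the `H`
#'    rows: `A_w = softmax(Q[,w,] K[,w,]') %o% gamma^|x_n - x_m|`, applied
#'    to `V[,w,]`;
#' 2. horizontal factor — within every row `h` of the intermediate result,
#'    attention across the `W` columns with decay `gamma^|y_n - y_m|`.
#'
#' The sequencing (vertical first, then horizontal) is the axis-permutation
#' reading of the factorised form; the contract is pinned by the
#' brute-force oracle in the test suite, and on single-row or single-column
#' grids the result coincides exactly with [masa_full()].
#'
#' @inheritParams masa_full
#' @return array `(H, W, d)`.
#' @export
masa_decomposed <- function(q, k, v, gamma) {
  stop_if(!all(dim(q) == dim(k)) || !all(dim(q) == dim(v)),
          "q, k, v must share the same (H, W, d) shape")
  H <- dim(q)[1L]; W <- dim(q)[2L]; d <- dim(q)[3L]
  Dv <- decay_axis(H, gamma, "vertical")
  Dh <- decay_axis(W, gamma, "horizontal")
  tmp <- array(0, c(H, W, d))
  for (w in seq_len(W)) {
    Qc <- matrix(q[, w, ], H, d); Kc <- matrix(k[, w, ], H, d)
    A <- softmax_rows(Qc %*% t(Kc)) * Dv
    tmp[, w, ] <- A %*% matrix(v[, w, ], H, d)
  }
  out <- array(0, c(H, W, d))
  for (h in seq_len(H)) {
    Qr <- matrix(q[h, , ], W, d); Kr <- matrix(k[h, , ], W, d)
    A <- softmax_rows(Qr %*% t(Kr)) * Dh
    out[h, , ] <- A %*% matrix(tmp[h, , ], W, d)
  }
  out
}

#' Analytic multiply-add counts for Manhattan self-attention
#'
#' Counts the multiplications and additions of the matrix products and the
#' decay Hadamard product (softmax exponentials excluded; they are common
#' to both forms). For the full form on `N = H*W` tokens the count is
#' `N^2 (2d - 1) + N^2 + N d (2N - 1)`; the decomposed form replaces the
#' `N x N` products with per-column and per-row `H x H` / `W x W` products.
#'
#' @param H,W grid dimensions.
#' @param d embedding dimensionality.
#' @param decomposed count the decomposed form instead of the full form.
#' @return a single number of multiply-add operations.
#' @export
#' @examples
#' masa_flops(56, 56, 32) / masa_flops(56, 56, 32, decomposed = TRUE)
masa_flops <- function(H, W, d, decomposed = FALSE) {
  H <- as.numeric(H); W <- as.numeric(W); d <- as.numeric(d)
  if (!decomposed) {
    N <- H * W
    N^2 * (2 * d - 1) + N^2 + N * d * (2 * N - 1)
  } else {
    vert <- W * H^2 * (2 * d - 1) + W * H^2 + W * (H * d) * (2 * H - 1)
    horiz <- H * W^2 * (2 * d - 1) + H * W^2 + H * (W * d) * (2 * W - 1)
    vert + horiz
  }
}

#' Per-head decay rates in the retention lineage
#'
#' Head `h` (0-based) uses `gamma_h = 1 - 2^(-5-h)`: later heads decay more
#' slowly and therefore see a wider spatial context.
#'
#' @param num_heads number of heads.
#' @return numeric vector of length `num_heads`, all inside (0, 1).
#' @export
masa_gammas <- function(num_heads) {
  stop_if(!is_wholenumber(num_heads) || num_heads < 1,
          "num_heads must be a positive integer")
  1 - 2^(-5 - (seq_len(num_heads) - 1))
}

#' Wall-time of one Manhattan self-attention call
#'
#' Median elapsed time (seconds) over `reps` calls on random inputs of the
#' given grid size, used for the empirical complexity-direction check.
#'
#' @inheritParams masa_flops
#' @param gamma decay rate.
#' @param reps number of repetitions (median reported).
#' @return median elapsed seconds.
#' @export
masa_time <- function(H, W, d, gamma = 0.9, decomposed = FALSE, reps = 3L) {
  q <- array(stats::rnorm(H * W * d), c(H, W, d))
  k <- array(stats::rnorm(H * W * d), c(H, W, d))
  v <- array(stats::rnorm(H * W * d), c(H, W, d))
  f <- if (decomposed) masa_decomposed else masa_full
  invisible(f(q, k, v, gamma))  # warm-up
  times <- vapply(seq_len(reps), function(i) {
    system.time(f(q, k, v, gamma))[["elapsed"]]
  }, numeric(1))
  stats::median(times)
}
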