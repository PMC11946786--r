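# Reverse-mode automatic differentiation on a linear tape.
#
# Nodes are environments holding $value (numeric array/matrix/scalar),
# $grad (accumulated during the backward sweep), $parents and $backfn.
# Non-constant nodes are appended to the tape in creation order, so a
# single reverse sweep visits them in valid topological order. Constants
# (fixed masks, decay matrices, data without gradient) are kept off-tape.
# Every op stores exactly what its backward needs in its closure.

#' @noRd
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

#' @noRd
ad_node <- function(tape, value, parents = NULL, backfn = NULL,
                    const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$const <- const
  nd$tape <- tape
  if (!const) {
    n <- tape$n + 1L
    if (n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

#' @noRd
ad_const <- function(tape, value) ad_node(tape, value, const = TRUE)

# A leaf with gradient (parameter or differentiable input).
#' @noRd
ad_leaf <- function(tape, value) ad_node(tape, value)

#' @noRd
ad_backward <- function(tape, root) {
  stop_if(length(root$value) != 1L, "backward root must be scalar")
  root$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (isTRUE(p$const)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL  # release memory; leaves keep theirs (no backfn)
  }
  invisible(NULL)
}

# ---- elementwise ----------------------------------------------------------

#' @noRd
ad_add <- function(a, b)
  ad_node(a$tape, a$value + b$value, list(a, b), function(g) list(g, g))

#' @noRd
ad_sub <- function(a, b)
  ad_node(a$tape, a$value - b$value, list(a, b), function(g) list(g, -g))

#' @noRd
ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(a$tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' @noRd
ad_scale <- function(a, s)
  ad_node(a$tape, a$value * s, list(a), function(g) list(g * s))

# Hadamard with a fixed matrix (e.g. a decay matrix).
#' @noRd
ad_mul_const <- function(a, C)
  ad_node(a$tape, a$value * C, list(a), function(g) list(g * C))

#' @noRd
ad_add_n <- function(lst) {
  v <- lst[[1L]]$value
  for (i in seq_along(lst)[-1L]) v <- v + lst[[i]]$value
  ad_node(lst[[1L]]$tape, v, lst,
          function(g) rep(list(g), length(lst)))
}

#' @noRd
ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ad_node(a$tape, y, list(a), function(g) list(g * y * (1 - y)))
}

#' @noRd
ad_gelu <- function(a) {
  x <- a$value
  ad_node(a$tape, gelu(x), list(a), function(g) list(g * gelu_grad(x)))
}

#' @noRd
ad_abs <- function(a) {
  x <- a$value
  ad_node(a$tape, abs(x), list(a), function(g) list(g * sign(x)))
}

#' @noRd
ad_mean <- function(a) {
  n <- length(a$value)
  dims <- dim(a$value)
  ad_node(a$tape, mean(a$value), list(a), function(g) {
    gr <- rep(g / n, n)
    if (!is.null(dims)) dim(gr) <- dims
    list(gr)
  })
}

# ---- shape ----------------------------------------------------------------

#' @noRd
ad_reshape <- function(a, dims) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ad_node(a$tape, v, list(a), function(g) {
    dim(g) <- old
    list(g)
  })
}

#' @noRd
ad_aperm <- function(a, perm) {
  inv <- order(perm)
  ad_node(a$tape, aperm(a$value, perm), list(a),
          function(g) list(aperm(g, inv)))
}

#' @noRd
ad_transpose <- function(a)
  ad_node(a$tape, t(a$value), list(a), function(g) list(t(g)))

# ---- matrix ---------------------------------------------------------------

#' @noRd
ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(a$tape, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

#' @noRd
ad_bias_rows <- function(x, b) {
  # x: (N, C) matrix node; b: length-C vector node, added to every row
  n <- nrow(x$value)
  ad_node(x$tape, x$value + matrix(b$value, n, length(b$value), byrow = TRUE),
          list(x, b), function(g) list(g, colSums(g)))
}

#' @noRd
ad_rowsoftmax <- function(a) {
  y <- softmax_rows(a$value)
  ad_node(a$tape, y, list(a),
          function(g) list(y * (g - rowSums(g * y))))
}

#' @noRd
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  fw <- layernorm_fwd(x$value, gamma$value, beta$value, eps)
  ad_node(x$tape, fw$y, list(x, gamma, beta), function(g) {
    gx <- g * fw$gm
    dx <- fw$inv * (gx - rowMeans(gx) - fw$xhat * rowMeans(gx * fw$xhat))
    list(dx, colSums(g * fw$xhat), colSums(g))
  })
}

# Instance norm on an (H, W, C) map: each channel standardised over its
# spatial positions, then scaled/shifted per channel. Removing the spatial
# DC per channel keeps downstream logits driven by contrast, not offset.
#' @noRd
ad_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1L] * d[2L]
  xm <- x$value; dim(xm) <- c(hw, d[3L])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- rep(1 / sqrt(v + eps), each = hw)
  xhat <- xc * inv
  gm <- rep(gamma$value, each = hw)
  y <- xhat * gm + rep(beta$value, each = hw)
  dim(y) <- d
  ad_node(x$tape, y, list(x, gamma, beta), function(g) {
    gmat <- g; dim(gmat) <- c(hw, d[3L])
    gx <- gmat * gm
    mg <- rep(colMeans(gx), each = hw)
    mgx <- rep(colMeans(gx * xhat), each = hw)
    dx <- inv * (gx - mg - xhat * mgx)
    dim(dx) <- d
    list(dx, colSums(gmat * xhat), colSums(gmat))
  })
}

#' @noRd
ad_rows <- function(x, idx) {
  dims <- dim(x$value)
  ad_node(x$tape, x$value[idx, , drop = FALSE], list(x), function(g) {
    z <- matrix(0, dims[1L], dims[2L])
    z[idx, ] <- g
    list(z)
  })
}

#' @noRd
ad_rbind <- function(lst) {
  rows <- vapply(lst, function(n) nrow(n$value), integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(lst[[1L]]$tape, do.call(rbind, lapply(lst, `[[`, "value")), lst,
          function(g) lapply(seq_along(lst), function(i)
            g[starts[i]:ends[i], , drop = FALSE]))
}

# ---- rank-3 slicing / stacking (for decomposed attention) -----------------

#' @noRd
ad_slab_row <- function(x, i) {
  d <- dim(x$value)
  ad_node(x$tape, matrix(x$value[i, , ], d[2L], d[3L]), list(x), function(g) {
    z <- array(0, d)
    z[i, , ] <- g
    list(z)
  })
}

#' @noRd
ad_slab_col <- function(x, j) {
  d <- dim(x$value)
  ad_node(x$tape, matrix(x$value[, j, ], d[1L], d[3L]), list(x), function(g) {
    z <- array(0, d)
    z[, j, ] <- g
    list(z)
  })
}

# Stack W matrices (H, d) into (H, W, d) along dim 2.
#' @noRd
ad_stack_cols <- function(lst) {
  H <- nrow(lst[[1L]]$value); d <- ncol(lst[[1L]]$value); W <- length(lst)
  v <- array(0, c(H, W, d))
  for (j in seq_len(W)) v[, j, ] <- lst[[j]]$value
  ad_node(lst[[1L]]$tape, v, lst, function(g)
    lapply(seq_len(W), function(j) matrix(g[, j, ], H, d)))
}

# Stack H matrices (W, d) into (H, W, d) along dim 1.
#' @noRd
ad_stack_rows <- function(lst) {
  W <- nrow(lst[[1L]]$value); d <- ncol(lst[[1L]]$value); H <- length(lst)
  v <- array(0, c(H, W, d))
  for (i in seq_len(H)) v[i, , ] <- lst[[i]]$value
  ad_node(lst[[1L]]$tape, v, lst, function(g)
    lapply(seq_len(H), function(i) matrix(g[i, , ], W, d)))
}

# ---- channel ops on (H, W, C) --------------------------------------------

#' @noRd
ad_channels <- function(x, idx) {
  d <- dim(x$value)
  ad_node(x$tape, x$value[, , idx, drop = FALSE], list(x), function(g) {
    z <- array(0, d)
    z[, , idx] <- g
    list(z)
  })
}

#' @noRd
ad_cat_channels <- function(lst) {
  d1 <- dim(lst[[1L]]$value)
  chans <- vapply(lst, function(n) dim(n$value)[3L], integer(1))
  ends <- cumsum(chans)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  v <- array(0, c(d1[1L], d1[2L], sum(chans)))
  for (i in seq_along(lst)) v[, , starts[i]:ends[i]] <- lst[[i]]$value
  ad_node(lst[[1L]]$tape, v, lst, function(g)
    lapply(seq_along(lst), function(i)
      g[, , starts[i]:ends[i], drop = FALSE]))
}

#' @noRd
ad_bias_chan <- function(x, b) {
  d <- dim(x$value)
  hw <- d[1L] * d[2L]
  ad_node(x$tape, x$value + array(rep(b$value, each = hw), d), list(x, b),
          function(g) {
            gm <- g; dim(gm) <- c(hw, d[3L])
            list(g, colSums(gm))
          })
}

# Per-channel learnable scale s (length C) applied to (H, W, C).
#' @noRd
ad_chan_scale <- function(x, s) {
  d <- dim(x$value)
  hw <- d[1L] * d[2L]
  sarr <- array(rep(s$value, each = hw), d)
  xv <- x$value
  ad_node(x$tape, xv * sarr, list(x, s), function(g) {
    gm <- g * xv; dim(gm) <- c(hw, d[3L])
    list(g * sarr, colSums(gm))
  })
}

# Subtract a single-channel map u (H, W, 1) from every channel of y.
#' @noRd
ad_bcast_sub <- function(y, u) {
  d <- dim(y$value)
  hw <- d[1L] * d[2L]
  urep <- array(as.vector(u$value), d)
  ad_node(y$tape, y$value - urep, list(y, u), function(g) {
    gm <- g; dim(gm) <- c(hw, d[3L])
    gu <- rowSums(gm); dim(gu) <- c(d[1L], d[2L], 1L)
    list(g, -gu)
  })
}

# ---- structured ops -------------------------------------------------------

#' @noRd
ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xdim <- dim(x$value)
  wv <- w$value
  fw <- conv2d_fwd(x$value, wv, b$value, stride, pad)
  ad_node(x$tape, fw$y, list(x, w, b), function(g) {
    bw <- conv2d_bwd(g, fw, wv, stride, pad, xdim)
    list(bw$dx, bw$dw, bw$db)
  })
}

#' @noRd
ad_dwconv2d <- function(x, w, b, pad = 1L) {
  xdim <- dim(x$value)
  dense <- dw_dense(w$value)
  fw <- conv2d_fwd(x$value, dense, b$value, 1L, pad)
  ad_node(x$tape, fw$y, list(x, w, b), function(g) {
    bw <- conv2d_bwd(g, fw, dense, 1L, pad, xdim)
    list(bw$dx, dw_gather(bw$dw), bw$db)
  })
}

#' @noRd
ad_upsample <- function(x, oh, ow) {
  d <- dim(x$value)
  R <- bilin_mat(d[1L], oh); S <- bilin_mat(d[2L], ow)
  ad_node(x$tape, upsample_bilinear_fwd(x$value, oh, ow), list(x),
          function(g) {
            dx <- array(0, d)
            for (c in seq_len(d[3L])) dx[, , c] <- crossprod(R, g[, , c]) %*% S
            list(dx)
          })
}

# 1x1 projection of an (H, W, Cin) map with a (Cin, Cout) matrix + bias.
#' @noRd
ad_proj <- function(x, w, b) {
  d <- dim(x$value)
  xm <- ad_reshape(x, c(d[1L] * d[2L], d[3L]))
  y <- ad_bias_rows(ad_matmul(xm, w), b)
  ad_reshape(y, c(d[1L], d[2L], ncol(w$value)))
}
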