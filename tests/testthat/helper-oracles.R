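# Independent brute-force oracles and small fixture builders.
# These deliberately use scalar loops and closed forms, never the
# package's vectorised code paths.

rand_field <- function(H, W, d) array(stats::rnorm(H * W * d), c(H, W, d))

# token n (1-based, row-major) -> 0-based (x = row, y = col)
oracle_coord <- function(n, W) c((n - 1) %/% W, (n - 1) %% W)

# Entry-wise evaluation of full Manhattan self-attention.
oracle_masa_full <- function(q, k, v, gamma) {
  H <- dim(q)[1]; W <- dim(q)[2]; d <- dim(q)[3]
  N <- H * W
  Qm <- matrix(0, N, d); Km <- Qm; Vm <- Qm
  for (n in seq_len(N)) {
    cc <- oracle_coord(n, W)
    Qm[n, ] <- q[cc[1] + 1, cc[2] + 1, ]
    Km[n, ] <- k[cc[1] + 1, cc[2] + 1, ]
    Vm[n, ] <- v[cc[1] + 1, cc[2] + 1, ]
  }
  out <- matrix(0, N, d)
  for (n in seq_len(N)) {
    s <- vapply(seq_len(N), function(m) sum(Qm[n, ] * Km[m, ]), numeric(1))
    a <- exp(s - max(s)); a <- a / sum(a)
    for (m in seq_len(N)) {
      cn <- oracle_coord(n, W); cm <- oracle_coord(m, W)
      w <- gamma^(abs(cn[1] - cm[1]) + abs(cn[2] - cm[2]))
      out[n, ] <- out[n, ] + a[m] * w * Vm[m, ]
    }
  }
  res <- array(0, dim(q))
  for (n in seq_len(N)) {
    cc <- oracle_coord(n, W)
    res[cc[1] + 1, cc[2] + 1, ] <- out[n, ]
  }
  res
}

# Nested-loop evaluation of the decomposed form: vertical attention within
# each column (row-distance decay), then horizontal within each row
# (column-distance decay).
oracle_masa_decomposed <- function(q, k, v, gamma) {
  H <- dim(q)[1]; W <- dim(q)[2]; d <- dim(q)[3]
  tmp <- array(0, dim(q))
  for (w in seq_len(W)) for (n in seq_len(H)) {
    s <- vapply(seq_len(H), function(m) sum(q[n, w, ] * k[m, w, ]),
                numeric(1))
    a <- exp(s - max(s)); a <- a / sum(a)
    acc <- numeric(d)
    for (m in seq_len(H)) acc <- acc + a[m] * gamma^abs(n - m) * v[m, w, ]
    tmp[n, w, ] <- acc
  }
  out <- array(0, dim(q))
  for (h in seq_len(H)) for (n in seq_len(W)) {
    s <- vapply(seq_len(W), function(m) sum(q[h, n, ] * k[h, m, ]),
                numeric(1))
    a <- exp(s - max(s)); a <- a / sum(a)
    acc <- numeric(d)
    for (m in seq_len(W)) acc <- acc + a[m] * gamma^abs(n - m) * tmp[h, m, ]
    out[h, n, ] <- acc
  }
  out
}

# Pairwise-loop retention oracle.
oracle_retention <- function(Q, K, V, gamma) {
  N <- nrow(Q); d <- ncol(Q)
  out <- matrix(0, N, d)
  for (n in seq_len(N)) for (m in seq_len(N)) {
    if (m > n) next
    out[n, ] <- out[n, ] + sum(Q[n, ] * K[m, ]) * gamma^(n - m) * V[m, ]
  }
  out
}

# Straight-line TCSA reference: embedding conv as explicit sums, one
# window size at a time, plain attention per group, explicit restoration.
oracle_tcsa <- function(clip, cfg, weights) {
  Tn <- dim(clip)[1]; C <- dim(clip)[2]; H <- dim(clip)[3]; W <- dim(clip)[4]
  tc <- Tn * C; r <- cfg$r; per <- r * r * cfg$D
  fused <- array(0, c(tc, H, W))
  for (t in seq_len(Tn)) for (c in seq_len(C))
    fused[(t - 1) * C + c, , ] <- clip[t, c, , ]
  h <- H / r; w <- W / r
  emb <- array(0, c(3 * per, h, w))
  for (oc in seq_len(3 * per)) for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- weights$embed.b[oc]
    for (a in seq_len(r)) for (b in seq_len(r)) for (ic in seq_len(tc))
      acc <- acc + fused[ic, (i - 1) * r + a, (j - 1) * r + b] *
        weights$embed.w[a, b, ic, oc]
    emb[oc, i, j] <- acc
  }
  L <- h * w
  # row-major spatial flatten
  flat <- matrix(0, 3 * per, L)
  for (oc in seq_len(3 * per)) for (i in seq_len(h)) for (j in seq_len(w))
    flat[oc, (i - 1) * w + j] <- emb[oc, i, j]
  total <- array(0, c(tc, H, W))
  for (wi_idx in seq_along(cfg$window_sizes)) {
    wsz <- cfg$window_sizes[wi_idx]
    om <- matrix(0, per, L)
    for (g in seq_len(per / wsz)) {
      rows <- (g - 1) * wsz + seq_len(wsz)
      Qg <- flat[rows, , drop = FALSE]
      Kg <- flat[per + rows, , drop = FALSE]
      Vg <- flat[2 * per + rows, , drop = FALSE]
      S <- Qg %*% t(Kg)
      A <- t(apply(S, 1, function(s) { e <- exp(s - max(s)); e / sum(e) }))
      if (wsz == 1) A <- matrix(1, 1, 1)
      om[rows, ] <- A %*% Vg
    }
    o3 <- array(0, c(per, h, w))
    for (oc in seq_len(per)) for (i in seq_len(h)) for (j in seq_len(w))
      o3[oc, i, j] <- om[oc, (i - 1) * w + j]
    rw <- weights[[paste0("restore", wi_idx, ".w")]]
    rb <- weights[[paste0("restore", wi_idx, ".b")]]
    for (i in seq_len(h)) for (j in seq_len(w)) {
      cell <- numeric(r * r * tc)
      for (oc in seq_len(r * r * tc)) {
        acc <- rb[oc]
        for (ic in seq_len(per)) acc <- acc + o3[ic, i, j] * rw[1, 1, ic, oc]
        cell[oc] <- acc
      }
      # depth-to-space: channel order (row offset a fastest, then col
      # offset b, then fused channel)
      for (ic in seq_len(tc)) for (b in seq_len(r)) for (a in seq_len(r)) {
        oc <- a + (b - 1) * r + (ic - 1) * r * r
        total[ic, (i - 1) * r + a, (j - 1) * r + b] <-
          total[ic, (i - 1) * r + a, (j - 1) * r + b] + cell[oc]
      }
    }
  }
  out <- array(0, dim(clip))
  for (t in seq_len(Tn)) for (c in seq_len(C))
    out[t, c, , ] <- total[(t - 1) * C + c, , ]
  out
}

gelu_ref <- function(x) x * stats::pnorm(x)

# Builders ------------------------------------------------------------------

tiny_model_config <- function(size = 32L) {
  model_config(
    tffm = tffm_config(r = 2L, D = 4L, window_sizes = c(2L, 4L, 8L)),
    encoder = encoder_config(depths = c(1L, 1L, 1L, 1L),
                             widths = c(8L, 8L, 16L, 16L),
                             heads = c(2L, 2L, 2L, 2L), ffn_ratio = 2L),
    decoder = decoder_config(fpn_width = 8L),
    frames = 8L, in_channels = 1L)
}

rand_mask <- function(H, W, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(H * W) < p, H, W)
}

disk_mask <- function(H, W, cr, cc, rad) {
  r <- matrix(rep(0:(H - 1), times = W), H, W)
  c <- matrix(rep(0:(W - 1), each = H), H, W)
  (r - cr)^2 + (c - cc)^2 <= rad^2
}
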