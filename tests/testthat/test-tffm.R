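# Temporal feature fusion: fusion, embedding, window grouping, TCSA,
# channel aggregation.

test_that("temporal-channel fusion stacks frames in order and round-trips", {
  set.seed(31)
  clip <- array(rnorm(8 * 3 * 10 * 12), c(8, 3, 10, 12))
  fused <- fuse_temporal_channel(clip)
  expect_equal(dim(fused), c(24, 10, 12))
  # fused channel (t-1)*C + c is channel c of frame t
  expect_equal(fused[5, , ], clip[2, 2, , ])
  expect_equal(unfuse_temporal_channel(fused, 8, 3), clip)
  one <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  expect_equal(fuse_temporal_channel(one)[2, , ], one[1, 2, , ])
})

test_that("embedding compresses space into channels per the r-stride rule", {
  cfg <- tffm_config(r = 2, D = 16)
  w <- tffm_init(cfg, 8, 3, seed = 1)
  fused <- array(rnorm(24 * 112 * 112), c(24, 112, 112))
  emb <- embed_compress_qkv(fused, w, cfg)
  expect_equal(dim(emb), c(3 * 4 * 16, 56, 56))
  cfg1 <- tffm_config(r = 1, D = 8, window_sizes = c(1, 2, 4))
  w1 <- tffm_init(cfg1, 2, 1, seed = 1)
  f1 <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  expect_equal(dim(embed_compress_qkv(f1, w1, cfg1))[2:3], c(6, 6))
  # zero input, zero bias -> zero output
  expect_equal(max(abs(embed_compress_qkv(array(0, c(2, 6, 6)), w1, cfg1))), 0)
  expect_error(embed_compress_qkv(array(0, c(24, 7, 8)), w, cfg),
               "divisible")
})

test_that("window grouping partitions the block axis and round-trips", {
  cfg <- tffm_config(r = 2, D = 16)
  set.seed(32)
  emb <- array(rnorm(192 * 4 * 5), c(192, 4, 5))  # r^2 D = 64 per block
  g4 <- group_windows(emb, 4)
  expect_length(g4$Q, 16)
  expect_equal(dim(g4$Q[[1]]), c(4, 20))
  g64 <- group_windows(emb, 64)
  expect_length(g64$Q, 1)
  expect_equal(dim(g64$Q[[1]]), c(64, 20))
  for (wsz in c(2, 4, 8)) {
    gr <- group_windows(emb, wsz)
    expect_equal(ungroup_windows(gr$Q, gr$h, gr$w), emb[1:64, , ])
    expect_equal(ungroup_windows(gr$V, gr$h, gr$w), emb[129:192, , ])
  }
  expect_error(group_windows(emb, 5), "divide")
})

test_that("tcsa preserves shape, averages V under uniform attention, and
           matches the straight-line reference", {
  cfg <- tffm_config(r = 1, D = 4, window_sizes = c(1, 2, 4))
  set.seed(33)
  w <- tffm_init(cfg, 2, 2, seed = 5)
  clip <- array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  out <- tcsa(clip, cfg, w)
  expect_equal(dim(out), dim(clip))
  expect_equal(out, oracle_tcsa(clip, cfg, w), tolerance = 1e-10)
  # determinism
  expect_equal(tcsa(clip, cfg, w), out)
})

test_that("single whole-block window with zero Q/K embedding rows averages
           the V window", {
  # craft weights so the Q and K blocks are zero: softmax is uniform and
  # each output slot is the mean of the V window rows
  cfg <- tffm_config(r = 1, D = 4, window_sizes = c(4, 4, 4))
  Tn <- 2; C <- 2
  w <- tffm_init(cfg, Tn, C, seed = 6)
  w$embed.w[, , , 1:8] <- 0          # Q and K blocks (4 + 4 channels)
  w$embed.b[] <- 0
  ns <- asNamespace("echoretnet")
  clip <- array(rnorm(Tn * C * 3 * 3), c(Tn, C, 3, 3))
  fused <- fuse_temporal_channel(clip)
  emb <- embed_compress_qkv(fused, w, cfg)
  gr <- group_windows(emb, 4)
  A <- softmax_rows(gr$Q[[1]] %*% t(gr$K[[1]]))
  expect_equal(A, matrix(0.25, 4, 4))
  vbar <- colMeans(gr$V[[1]])
  out <- A %*% gr$V[[1]]
  for (i in 1:4) expect_equal(out[i, ], vbar)
})

test_that("channel aggregation: s = 0 collapses CA(Y) to Y; zero input with
           zero biases maps to zero; scalar walkthrough", {
  cfg <- tffm_config(r = 1, D = 4, window_sizes = c(1, 2, 4),
                     ca_expansion = 2)
  Tn <- 1; C <- 2
  w <- tffm_init(cfg, Tn, C, seed = 7)
  ns <- asNamespace("echoretnet")

  # s = 0: the X_out = Conv1x1(Y) + X path must be unaffected by the
  # universal-feature branch; verify by perturbing that branch's weights
  w$ca.s[] <- 0
  set.seed(34)
  x <- array(rnorm(Tn * C * 4 * 4), c(Tn, C, 4, 4))
  out1 <- channel_aggregate(x, cfg, w)
  w2 <- w; w2$ca.u.w <- w2$ca.u.w + 5; w2$ca.u.b <- w2$ca.u.b + 3
  expect_equal(channel_aggregate(x, cfg, w2), out1)

  # zero input, zero biases -> zero output
  wz <- w
  for (nm in grep("\\.b$", names(wz), value = TRUE)) wz[[nm]][] <- 0
  wz$ca.ln.b[] <- 0
  z <- array(0, c(Tn, C, 4, 4))
  expect_equal(max(abs(channel_aggregate(z, cfg, wz))), 0)

  # scalar walkthrough with identity/unit kernels and s = 1 on a 2x2 frame
  cfg1 <- tffm_config(r = 1, D = 1, window_sizes = c(1, 1, 1),
                      ca_expansion = 1)
  wp <- tffm_init(cfg1, 1, 2, seed = 8)
  wp$ca.ln.g[] <- 1; wp$ca.ln.b[] <- 0
  wp$ca.c1.w <- array(diag(2), c(1, 1, 2, 2)); wp$ca.c1.b[] <- 0
  wp$ca.dw.w <- array(0, c(3, 3, 2)); wp$ca.dw.w[2, 2, ] <- 1  # identity
  wp$ca.dw.b[] <- 0
  wp$ca.s[] <- 1
  wp$ca.u.w <- array(1, c(1, 1, 2, 1)); wp$ca.u.b[] <- 0
  wp$ca.o.w <- array(diag(2), c(1, 1, 2, 2)); wp$ca.o.b[] <- 0
  x <- array(0, c(1, 2, 2, 2))
  x[1, 1, , ] <- matrix(c(1, -1, 2, 0), 2, 2)
  x[1, 2, , ] <- matrix(c(0.5, 1.5, -0.5, 1), 2, 2)
  got <- channel_aggregate(x, cfg1, wp)
  # reference computed entry-wise from the three aggregation equations
  eps <- 1e-5
  ref <- x
  for (i in 1:2) for (j in 1:2) {
    v <- c(x[1, 1, i, j], x[1, 2, i, j])
    mu <- mean(v); sd2 <- mean((v - mu)^2)
    yn <- (v - mu) / sqrt(sd2 + eps)          # layer norm, gamma 1 beta 0
    y <- gelu_ref(yn)                          # conv1 = I, dw = identity
    u <- gelu_ref(sum(y))                      # unit 1x1 to one channel
    ca <- y + 1 * (y - u)
    ref[1, , i, j] <- ca + v                   # out conv = I, residual
  }
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("tffm_forward preserves shape for T in {1, 4, 8}, is
           deterministic, and propagates gradient to every frame", {
  ns <- asNamespace("echoretnet")
  for (Tn in c(1, 4, 8)) {
    cfg <- tffm_config(r = 2, D = 4, window_sizes = c(2, 4, 8))
    w <- tffm_init(cfg, Tn, 1, seed = 9)
    clip <- array(rnorm(Tn * 1 * 8 * 8), c(Tn, 1, 8, 8))
    out <- tffm_forward(clip, cfg, w)
    expect_equal(dim(out), dim(clip))
    expect_equal(tffm_forward(clip, cfg, w), out)
  }
  # gradient from a key-frame-only loss reaches all T frames
  Tn <- 8
  cfg <- tffm_config(r = 2, D = 4, window_sizes = c(2, 4, 8))
  w <- tffm_init(cfg, Tn, 1, seed = 10)
  clip <- array(rnorm(Tn * 8 * 8), c(Tn, 1, 8, 8))
  tp <- ns$ad_tape()
  xf <- ns$ad_leaf(tp, ns$chw_to_hwc(fuse_temporal_channel(clip)))
  pn <- ns$params_to_nodes(tp, w)
  out <- ns$tffm_fwd(xf, pn, cfg, Tn, 1)
  key <- ns$ad_channels(out, 5L)  # key frame 5, C = 1
  loss <- ns$ad_mean(ns$ad_mul(key, key))
  ns$ad_backward(tp, loss)
  g <- xf$grad  # (H, W, T*C)
  norms <- vapply(seq_len(Tn), function(t) sqrt(sum(g[, , t]^2)), numeric(1))
  expect_true(all(norms > 0))
})
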