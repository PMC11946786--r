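# Retention / Manhattan self-attention primitives vs closed forms and
# brute-force oracles.

test_that("softmax_rows: closed forms, normalization, stability, errors", {
  expect_equal(softmax_rows(matrix(0, 2, 2)), matrix(0.5, 2, 2))
  expect_equal(softmax_rows(matrix(c(0, log(3)), 1, 2)),
               matrix(c(0.25, 0.75), 1, 2))
  set.seed(42)
  M <- matrix(rnorm(16), 4, 4)
  expect_equal(rowSums(softmax_rows(M)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(softmax_rows(M) > 0))
  # row-max subtraction keeps huge logits finite
  expect_equal(rowSums(softmax_rows(M + 1e4)), rep(1, 4), tolerance = 1e-12)
  expect_error(softmax_rows(matrix(c(1, NA, 0, 1), 2)), "non-finite")
  expect_error(softmax_rows(matrix(c(1, Inf, 0, 1), 2)), "non-finite")
})

test_that("decay_1d matches the closed form and a pairwise loop", {
  expect_equal(unclass(decay_1d(3, 0.5)),
               matrix(c(1, 0.5, 0.25, 0, 1, 0.5, 0, 0, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(as.numeric(decay_1d(1, 0.3)), 1)
  D <- decay_1d(5, 0.9)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) if (i >= j) ref[i, j] <- 0.9^(i - j)
  expect_equal(unclass(D), ref, ignore_attr = TRUE)
  expect_true(all(D[upper.tri(D)] == 0))
  expect_error(decay_1d(3, 1.0), "gamma")
  expect_error(decay_1d(3, 0), "gamma")
})

test_that("decay_2d: Manhattan distances, symmetry, unit diagonal,
           monotone decay", {
  D <- decay_2d(2, 2, 0.5)
  # tokens row-major: (0,0),(0,1),(1,0),(1,1)
  expect_equal(D[1, 4], 0.25)  # distance 2
  expect_equal(D[1, 2], 0.5)
  expect_equal(D[1, 3], 0.5)
  ref <- matrix(0, 4, 4)
  co <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (n in 1:4) for (m in 1:4)
    ref[n, m] <- 0.5^(sum(abs(co[[n]] - co[[m]])))
  expect_equal(unclass(D), ref, ignore_attr = TRUE)
  for (case in list(c(3, 5), c(4, 4), c(1, 6))) {
    g <- runif(1, 0.2, 0.95)
    D <- decay_2d(case[1], case[2], g)
    expect_equal(diag(D), rep(1, prod(case)))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    # non-increasing in Manhattan distance
    W <- case[2]
    n <- prod(case)
    xs <- (seq_len(n) - 1) %/% W; ys <- (seq_len(n) - 1) %% W
    md <- abs(outer(xs, xs, "-")) + abs(outer(ys, ys, "-"))
    o <- order(as.vector(md))
    expect_true(all(diff(as.vector(D)[o]) <= 1e-12))
  }
})

test_that("retention_1d: single token, diagonal-decay limit, brute force", {
  q <- matrix(rnorm(3), 1); k <- matrix(rnorm(3), 1); v <- matrix(rnorm(3), 1)
  expect_equal(retention_1d(q, k, v, 0.5), sum(q * k) * v)
  set.seed(7)
  N <- 4; d <- 3
  Q <- matrix(rnorm(N * d), N); K <- matrix(rnorm(N * d), N)
  V <- matrix(rnorm(N * d), N)
  # gamma -> 0 limit: identity decay keeps only the diagonal term
  out <- retention_1d(Q, K, V, 0.5, decay = diag(N))
  ref <- t(vapply(seq_len(N), function(n) sum(Q[n, ] * K[n, ]) * V[n, ],
                  numeric(d)))
  expect_equal(out, ref)
  expect_equal(retention_1d(Q, K, V, 0.7), oracle_retention(Q, K, V, 0.7),
               tolerance = 1e-12)
  expect_error(retention_1d(Q, K, V[1:2, ], 0.7), "shape")
})

test_that("masa_full: single token, uniform limit, brute-force oracle", {
  v <- rand_field(1, 1, 4)
  expect_equal(masa_full(rand_field(1, 1, 4), rand_field(1, 1, 4), v, 0.5), v)
  # Q = K = 0 and gamma ~ 1: every token averages V
  set.seed(8)
  v <- rand_field(2, 3, 4)
  z <- array(0, dim(v))
  out <- masa_full(z, z, v, 1 - 1e-9)
  mv <- colMeans(token_flatten(v))
  for (i in 1:2) for (j in 1:3)
    expect_equal(out[i, j, ], mv, tolerance = 1e-6)
  set.seed(9)
  q <- rand_field(3, 3, 4); k <- rand_field(3, 3, 4); v <- rand_field(3, 3, 4)
  expect_lt(max(abs(masa_full(q, k, v, 0.85) -
                      oracle_masa_full(q, k, v, 0.85))), 1e-6)
  expect_error(masa_full(q, k, rand_field(3, 2, 4), 0.8), "shape")
})

test_that("masa_decomposed: degenerate grids equal masa_full; 4x4 oracle", {
  set.seed(10)
  v <- rand_field(1, 1, 3)
  expect_equal(masa_decomposed(rand_field(1, 1, 3), rand_field(1, 1, 3), v,
                               0.6), v)
  for (dims in list(c(1, 7), c(7, 1))) {
    q <- rand_field(dims[1], dims[2], 5)
    k <- rand_field(dims[1], dims[2], 5)
    v <- rand_field(dims[1], dims[2], 5)
    expect_lt(max(abs(masa_decomposed(q, k, v, 0.8) -
                        masa_full(q, k, v, 0.8))), 1e-6)
  }
  q <- rand_field(4, 4, 8); k <- rand_field(4, 4, 8); v <- rand_field(4, 4, 8)
  expect_lt(max(abs(masa_decomposed(q, k, v, 0.9) -
                      oracle_masa_decomposed(q, k, v, 0.9))), 1e-6)
})

test_that("token flatten/unflatten round-trips and orders row-major", {
  f <- array(0, c(2, 3, 1))
  f[1, , 1] <- 1:3; f[2, , 1] <- 4:6
  expect_equal(as.vector(token_flatten(f)), 1:6)  # row 1 then row 2
  set.seed(11)
  x <- rand_field(4, 5, 3)
  expect_equal(token_unflatten(token_flatten(x), 4, 5), x)
})

test_that("analytic multiply-add counts favour the decomposed form on all
           square grids with side >= 2", {
  for (d in c(4, 32, 64)) {
    sides <- 2:64
    full <- vapply(sides, function(s) masa_flops(s, s, d), numeric(1))
    deco <- vapply(sides, function(s) masa_flops(s, s, d, TRUE), numeric(1))
    expect_true(all(deco < full))
  }
  # side 1: decomposition buys nothing
  expect_gte(masa_flops(1, 1, 8, TRUE), masa_flops(1, 1, 8))
})

test_that("per-head decay rates follow the retention schedule", {
  g <- masa_gammas(4)
  expect_equal(g, 1 - 2^(-5 - (0:3)))
  expect_true(all(g > 0 & g < 1))
})
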