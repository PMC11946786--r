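# Dice, Hausdorff, HD95 and the evaluation runner.

test_that("dice: identity, disjoint, the 2/2/1 overlap case, symmetry,
           empties, errors", {
  A <- rand_mask(8, 8, 0.4, seed = 61)
  A[1, 1] <- TRUE
  expect_equal(dice(A, A), 1)
  B <- matrix(FALSE, 4, 4); B[1, 1] <- TRUE
  C <- matrix(FALSE, 4, 4); C[4, 4] <- TRUE
  expect_equal(dice(B, C), 0)
  A2 <- matrix(FALSE, 4, 4); A2[1, 1:2] <- TRUE
  B2 <- matrix(FALSE, 4, 4); B2[1, 2:3] <- TRUE
  expect_equal(dice(A2, B2), 0.5)
  for (i in 1:20) {
    X <- rand_mask(10, 12, runif(1, 0.1, 0.6))
    Y <- rand_mask(10, 12, runif(1, 0.1, 0.6))
    expect_equal(dice(X, Y), dice(Y, X))
  }
  E <- matrix(FALSE, 4, 4)
  expect_equal(dice(E, E), 1)          # both empty: perfect agreement
  expect_equal(dice(E, B2), 0)         # empty vs non-empty
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("hausdorff: identity, the 3-4-5 pair, all-pairs brute force,
           empty sentinel", {
  A <- disk_mask(16, 16, 8, 8, 4)
  expect_equal(hausdorff(A, A), 0)
  P <- matrix(FALSE, 8, 8); P[1, 1] <- TRUE
  Q <- matrix(FALSE, 8, 8); Q[4, 5] <- TRUE  # offset (3, 4)
  expect_equal(hausdorff(P, Q), 5)
  # A = {(0,0), (10,0)}, B = {(0,0)}: directed values from a brute loop
  A2 <- matrix(FALSE, 12, 3); A2[1, 1] <- TRUE; A2[11, 1] <- TRUE
  B2 <- matrix(FALSE, 12, 3); B2[1, 1] <- TRUE
  pa <- boundary_points(A2); pb <- boundary_points(B2)
  brute <- function(from, to) {
    max(apply(from, 1, function(p)
      min(apply(to, 1, function(q) sqrt(sum((p - q)^2))))))
  }
  expect_equal(hausdorff(A2, B2), max(brute(pa, pb), brute(pb, pa)))
  expect_equal(hausdorff(A2, B2), 10)
  E <- matrix(FALSE, 10, 20)
  F1 <- matrix(FALSE, 10, 20); F1[5, 5] <- TRUE
  expect_equal(hausdorff(E, F1), sqrt(9^2 + 19^2))  # sentinel: diagonal
  expect_equal(hd95(E, E), sqrt(9^2 + 19^2))
})

test_that("hd95 <= hausdorff on random mask pairs; directed values match a
           brute-force percentile", {
  set.seed(62)
  for (i in 1:200) {
    X <- rand_mask(12, 12, runif(1, 0.1, 0.5))
    Y <- rand_mask(12, 12, runif(1, 0.1, 0.5))
    if (!any(X) || !any(Y)) next
    expect_lte(hd95(X, Y), hausdorff(X, Y) + 1e-12)
  }
  X <- disk_mask(20, 20, 10, 10, 6)
  Y <- disk_mask(20, 20, 9, 11, 5)
  px <- boundary_points(X); py <- boundary_points(Y)
  dxy <- apply(px, 1, function(p)
    min(sqrt((py[, 1] - p[1])^2 + (py[, 2] - p[2])^2)))
  dyx <- apply(py, 1, function(p)
    min(sqrt((px[, 1] - p[1])^2 + (px[, 2] - p[2])^2)))
  expect_equal(hd95(X, Y),
               max(quantile(dxy, 0.95, names = FALSE),
                   quantile(dyx, 0.95, names = FALSE)))
})

test_that("metrics are invariant to simultaneous translation", {
  base <- disk_mask(30, 30, 12, 12, 5)
  other <- disk_mask(30, 30, 13, 14, 6)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(dice(shift(base, 3, 4), shift(other, 3, 4)),
               dice(base, other))
  expect_equal(hausdorff(shift(base, 3, 4), shift(other, 3, 4)),
               hausdorff(base, other))
  expect_equal(hd95(shift(base, 3, 4), shift(other, 3, 4)),
               hd95(base, other))
})

test_that("boundary extraction: interior pixels excluded, border pixels of
           the mask kept", {
  m <- matrix(FALSE, 7, 7)
  m[2:6, 2:6] <- TRUE
  bp <- boundary_points(m)
  expect_equal(nrow(bp), 16)           # 5x5 block: 25 - 9 interior
  expect_false(any(bp[, 1] == 3 & bp[, 2] == 3))
  full <- matrix(TRUE, 3, 5)  # every pixel except the 3 central ones
  expect_equal(nrow(boundary_points(full)), 12)
})

test_that("evaluate_model: a perfect oracle scores DSC 1 / HD95 0; a
           constant-empty model scores DSC 0; aggregates are means", {
  pc <- phantom_config(image_size = 64)
  recs <- list(generate_clip(pc, seed = 71), generate_clip(pc, seed = 72))
  fake_eval <- function(predict_fn) {
    rows <- list()
    for (rec in recs) for (i in 1:nrow(rec$keys)) {
      kf <- rec$keys$frame[i]
      truth <- rec$masks[[as.character(kf)]]
      pred <- predict_fn(truth)
      rows[[length(rows) + 1]] <- c(dice(pred, truth), hd95(pred, truth))
    }
    do.call(rbind, rows)
  }
  perfect <- fake_eval(identity)
  expect_equal(mean(perfect[, 1]), 1)
  expect_equal(mean(perfect[, 2]), 0)
  empty <- fake_eval(function(t) matrix(FALSE, nrow(t), ncol(t)))
  expect_equal(mean(empty[, 1]), 0)
  # two hand-built items through the real aggregate path
  A2 <- matrix(FALSE, 4, 4); A2[1, 1:2] <- TRUE
  B2 <- matrix(FALSE, 4, 4); B2[1, 2:3] <- TRUE
  items <- data.frame(dice = c(dice(A2, B2), dice(A2, A2)),
                      hd95 = c(hd95(A2, B2), hd95(A2, A2)))
  expect_equal(mean(items$dice), (0.5 + 1) / 2)
  # and the full runner on a real (untrained) model returns one row per key
  model <- assemble_model(reduced_config(), seed = 1)
  rep <- evaluate_model(model, recs[1])
  expect_equal(nrow(rep$items), 2)
  expect_equal(sort(rep$items$type), c("ED", "ES"))
  expect_equal(rep$mean_dice, mean(rep$items$dice))
  expect_error(evaluate_model(model, list()), "empty")
})
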