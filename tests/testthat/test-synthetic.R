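# Phantom generator: cyclic geometry, speckle statistics, sector clipping,
# corpus writing/reading round trips.

test_that("phantom_frame: ED area exceeds ES area with the configured
           ratio; clean frames are piecewise constant; oversized ellipse
           errors", {
  pc <- phantom_config(image_size = 64, speckle_sd = 0, blur_sigma = 0)
  ed <- phantom_frame(pc, 0)
  es <- phantom_frame(pc, 0.5)
  expect_gt(sum(ed$mask), sum(es$mask))
  expect_equal(sum(es$mask) / sum(ed$mask), pc$systolic_area_fraction,
               tolerance = 0.05)
  # clean frame: only the configured intensity levels (plus sector zeros)
  lv <- sort(unique(as.vector(ed$image)))
  expect_true(all(vapply(lv, function(x)
    min(abs(x - c(0, pc$lumen, pc$rim, pc$background))) < 1e-12,
    logical(1))))
  big <- phantom_config(image_size = 32, axes_ed = c(0.6, 0.5))
  expect_error(phantom_frame(big, 0), "fit")
})

test_that("speckle is multiplicative with unit mean; CNR never increases
           with speckle strength", {
  ns <- asNamespace("echoretnet")
  set.seed(91)
  f <- ns$speckle_field(1000, 1000, 0.5)
  expect_equal(mean(f), 1, tolerance = 0.01)
  expect_equal(sd(f), 0.5, tolerance = 0.01)
  f1 <- ns$speckle_field(1000, 1000, 1)   # single-look exponential limit
  expect_equal(mean(f1), 1, tolerance = 0.01)
  cnrs <- vapply(c(0.1, 0.4, 0.8, 1.2), function(s) {
    phantom_cnr(phantom_config(image_size = 96, speckle_sd = s), seed = 5)
  }, numeric(1))
  expect_true(all(diff(cnrs) <= 0))
})

test_that("generate_clip: deterministic per seed, survives the cleaning
           rule, ED is the argmax-area frame", {
  pc <- phantom_config(image_size = 48)
  c1 <- generate_clip(pc, seed = 17)
  c2 <- generate_clip(pc, seed = 17)
  expect_identical(c1$frames, c2$frames)
  expect_identical(c1$masks, c2$masks)
  expect_false(identical(generate_clip(pc, seed = 18)$frames, c1$frames))
  for (s in c(3, 9, 27)) {
    rec <- generate_clip(pc, seed = s, all_masks = TRUE)
    expect_length(clean_dataset(list(rec)), 1)
    areas <- vapply(attr(rec, "all_masks"), sum, numeric(1))
    ed <- rec$keys$frame[rec$keys$type == "ED"]
    es <- rec$keys$frame[rec$keys$type == "ES"]
    expect_equal(which.max(areas), ed)
    expect_equal(which.min(areas), es)
    expect_gt(sum(rec$masks[[as.character(ed)]]),
              sum(rec$masks[[as.character(es)]]))
  }
})

test_that("generate_corpus: documented split rounding; per-clip seeds are
           reproducible; n < 3 errors", {
  pc <- phantom_config(image_size = 32)
  recs <- generate_corpus(10, pc, dir = NULL, seed = 3)
  expect_equal(as.integer(table(factor(vapply(recs, `[[`, "", "split"),
                                       c("TRAIN", "VAL", "TEST")))),
               c(7, 1, 2))
  recs2 <- generate_corpus(10, pc, dir = NULL, seed = 3)
  expect_identical(recs[[4]]$frames, recs2[[4]]$frames)
  expect_error(generate_corpus(2, pc), "at least 3")
})

test_that("a corpus written in the EchoNet-style dialect re-reads with
           key-frame masks at dice >= 0.99 and intact splits", {
  pc <- phantom_config(image_size = 48)
  dir <- file.path(tempdir(), "echonet_rt")
  unlink(dir, recursive = TRUE)
  recs <- generate_corpus(6, pc, dir = dir, seed = 41)
  expect_true(file.exists(file.path(dir, "FileList.csv")))
  expect_true(file.exists(file.path(dir, "VolumeTracings.csv")))
  back <- read_echonet_dataset(dir)
  expect_length(back, 6)
  for (i in seq_along(recs)) {
    orig <- recs[[i]]
    got <- back[[match(orig$video_id, vapply(back, `[[`, "", "video_id"))]]
    expect_equal(got$split, orig$split)
    expect_equal(got$n_frames, orig$n_frames)
    # frames survive 8-bit PNG quantisation
    expect_lt(max(abs(got$frames - orig$frames)), 1 / 255)
    for (k in orig$keys$frame) {
      expect_gte(dice(got$masks[[as.character(k)]],
                      orig$masks[[as.character(k)]]), 0.99)
    }
    # ED/ES relabelling from areas agrees with the generator
    expect_equal(got$keys$type[order(got$keys$frame)],
                 orig$keys$type[order(orig$keys$frame)])
  }
  unlink(dir, recursive = TRUE)
})

test_that("CAMUS-style reader: half-cycle ED/ES keys, endocardium label
           retained, other labels dropped", {
  dir <- file.path(tempdir(), "camus_rt")
  unlink(dir, recursive = TRUE)
  pdir <- file.path(dir, "patient0001")
  dir.create(pdir, recursive = TRUE)
  set.seed(92)
  Tn <- 10
  vol <- array(runif(32 * 32 * Tn, 0, 255), c(32, 32, Tn))
  gt <- array(0L, c(32, 32, Tn))
  gt[10:20, 10:20, 1] <- 1L   # endocardium
  gt[5:8, 5:8, 1] <- 2L       # myocardium: must be dropped
  gt[12:18, 12:18, Tn] <- 1L
  RNifti::writeNifti(RNifti::asNifti(vol),
                     file.path(pdir, "patient0001_2CH_sequence.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(gt),
                     file.path(pdir, "patient0001_2CH_sequence_gt.nii.gz"))
  recs <- read_camus_dataset(dir)
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_equal(rec$keys$frame, c(1, Tn))
  expect_equal(rec$keys$type, c("ED", "ES"))
  expect_equal(sum(rec$masks[["1"]]), 11 * 11)      # label-2 region dropped
  expect_equal(sum(rec$masks[[as.character(Tn)]]), 7 * 7)
  expect_true(all(rec$frames >= 0 & rec$frames <= 1))
  unlink(dir, recursive = TRUE)
})

test_that("mask_to_trace pairs round-trip through rasterize_trace exactly
           for row-convex masks", {
  m <- disk_mask(24, 24, 12, 11, 7)
  tr <- mask_to_trace(m)
  back <- rasterize_trace(tr, 24, 24)
  expect_equal(dice(back, m), 1)
})

test_that("out-of-view sector shifts truncate the ventricle at the sector
           border for some clips", {
  pc <- phantom_config(image_size = 64, out_of_view_prob = 1)
  pc0 <- phantom_config(image_size = 64, out_of_view_prob = 0)
  # with probability 1 the apex is shifted: the ED mask must lose area
  # relative to the unshifted geometry for at least one seed
  lost <- vapply(1:5, function(s) {
    a1 <- sum(generate_clip(pc, seed = s)$masks[["5"]])
    a0 <- sum(generate_clip(pc0, seed = s)$masks[["5"]])
    a1 < a0
  }, logical(1))
  expect_true(any(lost))
})
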