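# Synthetic echocardiography phantoms.
#
# A clip shows a pulsating ellipse (dark blood pool inside a brighter
# myocardial rim) over one cardiac cycle, corrupted by unit-mean
# multiplicative speckle, blurred, and clipped to a fan-shaped sector of
# view; occasionally the sector is shifted so part of the ventricle leaves
# the field of view. Masks (the exact ellipse interior clipped to the
# sector) are attached only at the ED and ES key frames, mirroring how
# clinical echo videos are annotated.

#' Phantom configuration
#'
#' Geometry is in fractions of the image size; intensities in `[0, 1]`.
#' Defaults aim at realistic apical-view echo appearance: a hypoechoic
#' blood pool (intensity ~0.08) inside a brighter myocardium (~0.55) over
#' mid-grey surrounding tissue (~0.28), strong single-look-like speckle
#' (sd 0.5), and an ES/ED area fraction of 0.55 (a healthy ventricle
#' loses roughly half its cross-sectional area in systole).
#'
#' @param image_size square frame size in pixels.
#' @param frames_per_cycle frames covering one full cardiac cycle
#'   (`>= 8` so both key frames admit the 4-before/3-after clip window).
#' @param center ventricle centre `(row, col)` as fractions of the size.
#' @param center_jitter uniform jitter half-range applied per clip.
#' @param axes_ed ED semi-axes `(row, col)` as fractions of the size.
#' @param axes_range multiplicative per-clip jitter range on the axes.
#' @param systolic_area_fraction ES mask area / ED mask area, in (0, 1).
#' @param speckle_sd standard deviation of the unit-mean multiplicative
#'   speckle (gamma multi-look family; 0 disables).
#' @param blur_sigma Gaussian blur in pixels (0 disables).
#' @param lumen,rim,background base intensities.
#' @param rim_width myocardial rim thickness as a fraction of the size.
#' @param sector_angle full opening angle of the imaging sector, degrees
#'   in (0, 180].
#' @param out_of_view_prob per-clip probability that the sector is
#'   shifted so a ventricle edge leaves the field of view.
#' @param seed base seed used when a clip does not supply one.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 112L, frames_per_cycle = 16L,
                           center = c(0.46, 0.5), center_jitter = 0.04,
                           axes_ed = c(0.26, 0.17), axes_range = c(0.9, 1.1),
                           systolic_area_fraction = 0.55,
                           speckle_sd = 0.5, blur_sigma = 1,
                           lumen = 0.08, rim = 0.55, background = 0.28,
                           rim_width = 0.06, sector_angle = 75,
                           out_of_view_prob = 0.15, seed = 1L) {
  stop_if(systolic_area_fraction <= 0 || systolic_area_fraction >= 1,
          "systolic_area_fraction must be in (0, 1)")
  stop_if(speckle_sd < 0, "speckle_sd must be >= 0")
  stop_if(sector_angle <= 0 || sector_angle > 180,
          "sector_angle must be in (0, 180] degrees")
  stop_if(frames_per_cycle < 8L, "frames_per_cycle must be >= 8")
  structure(as.list(environment()), class = "phantom_config")
}

# Smooth axis scale over the cycle: 1 at phase 0 (ED), sqrt(fraction) at
# phase 0.5 (ES), so mask area interpolates between the ED area and
# fraction * ED area.
#' @noRd
phase_scale <- function(t, fraction) {
  1 - (1 - sqrt(fraction)) * (1 - cos(2 * pi * t)) / 2
}

#' @noRd
sector_mask <- function(n, angle_deg, apex_col_frac = 0.5) {
  apex_r <- -0.02 * n
  apex_c <- apex_col_frac * (n - 1)
  r <- rep(0:(n - 1), times = n)
  c <- rep(0:(n - 1), each = n)
  ang <- atan2(c - apex_c, r - apex_r)   # 0 = straight down
  rad <- sqrt((r - apex_r)^2 + (c - apex_c)^2)
  half <- angle_deg / 2 * pi / 180
  matrix(abs(ang) <= half & rad <= 1.15 * n, n, n)
}

#' @noRd
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * ceiling(2 * sigma) + 1L
  g <- stats::dnorm(seq(-(k %/% 2L), k %/% 2L), sd = sigma)
  g <- g / sum(g)
  pad <- k %/% 2L
  n <- nrow(img); m <- ncol(img)
  xp <- matrix(0, n + 2L * pad, m)
  xp[pad + seq_len(n), ] <- img
  tmp <- matrix(0, n, m)
  for (i in seq_len(k)) tmp <- tmp + g[i] * xp[(i - 1L) + seq_len(n), ]
  xp2 <- matrix(0, n, m + 2L * pad)
  xp2[, pad + seq_len(m)] <- tmp
  out <- matrix(0, n, m)
  for (i in seq_len(k)) out <- out + g[i] * xp2[, (i - 1L) + seq_len(m)]
  out
}

# Unit-mean multiplicative speckle: gamma(shape 1/sd^2, scale sd^2); the
# single-look limit sd = 1 is the squared-magnitude Rayleigh
# (exponential) law.
#' @noRd
speckle_field <- function(n, m, sd) {
  if (sd <= 0) return(matrix(1, n, m))
  shape <- 1 / sd^2
  matrix(stats::rgamma(n * m, shape = shape, scale = 1 / shape), n, m)
}

#' Render one phantom frame
#'
#' @param config a [phantom_config()].
#' @param phase cycle phase in `[0, 1)`: 0 is end-diastole (largest
#'   area), 0.5 end-systole (smallest).
#' @param geometry optional per-clip geometry overriding the config
#'   (fields `center`, `axes_ed`, `apex_col`), as sampled by
#'   [generate_clip()].
#' @param noise add speckle/blur (`TRUE`) or return the clean piecewise
#'   pattern.
#' @return list `(image, mask)`: numeric `(n, n)` frame in `[0, 1]` and
#'   logical mask of the ventricle interior clipped to the sector.
#' @export
phantom_frame <- function(config, phase, geometry = NULL, noise = TRUE) {
  n <- config$image_size
  g <- geometry %||% list(center = config$center * n,
                          axes_ed = config$axes_ed * n,
                          apex_col = 0.5)
  s <- phase_scale(phase, config$systolic_area_fraction)
  ar <- g$axes_ed[1L] * s
  ac <- g$axes_ed[2L] * s
  rimw <- config$rim_width * n
  stop_if(g$center[1L] - ar - rimw < 0 || g$center[1L] + ar + rimw > n - 1 ||
            g$center[2L] - ac - rimw < 0 || g$center[2L] + ac + rimw > n - 1,
          "ellipse (with rim) does not fit inside the %dx%d image", n, n)
  r <- matrix(rep(0:(n - 1), times = n), n, n)
  c <- matrix(rep(0:(n - 1), each = n), n, n)
  q_in <- ((r - g$center[1L]) / ar)^2 + ((c - g$center[2L]) / ac)^2
  q_out <- ((r - g$center[1L]) / (ar + rimw))^2 +
    ((c - g$center[2L]) / (ac + rimw))^2
  interior <- q_in <= 1
  rim <- q_out <= 1 & !interior
  img <- matrix(config$background, n, n)
  img[rim] <- config$rim
  img[interior] <- config$lumen
  sec <- sector_mask(n, config$sector_angle, g$apex_col)
  if (noise) {
    img <- img * speckle_field(n, n, config$speckle_sd)
    img <- gauss_blur(img, config$blur_sigma)
  }
  img[!sec] <- 0
  list(image = clamp(img, 0, 1), mask = interior & sec)
}

#' Generate one phantom clip with ED/ES key frames
#'
#' Renders `frames_per_cycle` frames covering one cardiac cycle, phased so
#' the ED frame sits at index 5 (with the 4 preceding frames available)
#' and the ES frame half a cycle later; masks are attached at the two key
#' frames only. With probability `out_of_view_prob` the sector apex is
#' shifted sideways so a ventricle edge leaves the field of view.
#' Deterministic per seed.
#'
#' @param config a [phantom_config()].
#' @param seed clip seed.
#' @param all_masks also render the mask of every frame (for inspection),
#'   attached as attribute `all_masks`.
#' @return an [echo_record()]; also carries the generator's exact key
#'   masks in `$masks`.
#' @export
generate_clip <- function(config, seed = config$seed, all_masks = FALSE) {
  Fc <- config$frames_per_cycle
  n <- config$image_size
  local_seed(seed, {
    jit <- stats::runif(2, -config$center_jitter, config$center_jitter)
    axf <- stats::runif(2, config$axes_range[1L], config$axes_range[2L])
    geom <- list(center = (config$center + jit) * n,
                 axes_ed = config$axes_ed * axf * n,
                 apex_col = 0.5)
    if (stats::runif(1) < config$out_of_view_prob) {
      # shift the apex towards one side until the ED ellipse edge exits
      side <- sample(c(-1, 1), 1L)
      half <- config$sector_angle / 2 * pi / 180
      reach <- geom$center[1L] * tan(half)
      need <- abs(geom$center[2L] + side * geom$axes_ed[2L] * 0.6 -
                    0.5 * (n - 1)) + reach
      geom$apex_col <- 0.5 - side * (need - reach + geom$axes_ed[2L] * 0.8) / n
    }
    ed_i <- 5L
    es_i <- 5L + Fc %/% 2L
    phases <- ((seq_len(Fc) - ed_i) / Fc) %% 1
    frames <- array(0, c(n, n, Fc))
    masks_all <- vector("list", Fc)
    for (i in seq_len(Fc)) {
      fr <- phantom_frame(config, phases[i], geom)
      frames[, , i] <- fr$image
      masks_all[[i]] <- fr$mask
    }
    keys <- data.frame(frame = c(ed_i, es_i), type = c("ED", "ES"),
                       stringsAsFactors = FALSE)
    masks <- stats::setNames(masks_all[c(ed_i, es_i)],
                             as.character(c(ed_i, es_i)))
    rec <- echo_record(sprintf("phantom_%06d", seed), frames, keys, masks)
    if (all_masks) attr(rec, "all_masks") <- masks_all
    rec
  })
}

#' Generate a synthetic corpus and write it in the EchoNet-style dialect
#'
#' `n` clips with per-clip seeds derived as `seed + index`, split
#' train/val/test as `floor(0.70 n)` / `floor(0.15 n)` / remainder (in
#' index order), written under `dir` as per-frame PNG directories plus
#' `FileList.csv` and `VolumeTracings.csv` (paired per-row boundary
#' coordinates of each key mask, 0-based frame indices) so the dataset
#' readers are exercised end-to-end.
#'
#' @param n number of clips (`>= 3`).
#' @param config a [phantom_config()].
#' @param dir output directory (created if needed); `NULL` keeps the
#'   corpus in memory only.
#' @param seed corpus seed.
#' @return list of [echo_record()]s with a `split` field; invisibly also
#'   written to `dir`.
#' @export
generate_corpus <- function(n, config, dir = NULL, seed = 1L) {
  stop_if(n < 3L, "a corpus needs at least 3 clips for a 3-way split")
  n_train <- floor(0.70 * n)
  n_val <- floor(0.15 * n)
  splits <- rep(c("TRAIN", "VAL", "TEST"),
                c(n_train, n_val, n - n_train - n_val))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- generate_clip(config, seed = seed + i)
    rec$video_id <- sprintf("clip%04d", i)
    rec$split <- splits[i]
    records[[i]] <- rec
  }
  if (!is.null(dir)) write_echonet_corpus(records, dir)
  invisible(records)
}

#' Lumen/rim contrast-to-noise ratio of a phantom frame
#'
#' `|mean(rim) - mean(lumen)| / sd(rim)` measured on the rendered ED
#' frame; used to verify that increasing speckle never increases
#' contrast-to-noise.
#'
#' @param config a [phantom_config()].
#' @param seed render seed.
#' @return a single number.
#' @export
phantom_cnr <- function(config, seed = 1L) {
  n <- config$image_size
  local_seed(seed, {
    fr <- phantom_frame(config, 0)
    geom <- list(center = config$center * n, axes_ed = config$axes_ed * n,
                 apex_col = 0.5)
    rimw <- config$rim_width * n
    r <- matrix(rep(0:(n - 1), times = n), n, n)
    c <- matrix(rep(0:(n - 1), each = n), n, n)
    q_in <- ((r - geom$center[1L]) / geom$axes_ed[1L])^2 +
      ((c - geom$center[2L]) / geom$axes_ed[2L])^2
    q_out <- ((r - geom$center[1L]) / (geom$axes_ed[1L] + rimw))^2 +
      ((c - geom$center[2L]) / (geom$axes_ed[2L] + rimw))^2
    sec <- sector_mask(n, config$sector_angle)
    lum <- fr$image[q_in <= 0.8 & sec]
    rim <- fr$image[q_out <= 1 & q_in > 1.1 & sec]
    abs(mean(rim) - mean(lum)) / stats::sd(rim)
  })
}
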