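# Dataset records, clip sampling, the key-frame cleaning rule, trace
# rasterization and train-time augmentation.
#
# Conventions: pixel coordinates are 0-based (row, col); trace tables use
# image coordinates X = column, Y = row (also 0-based); frame indices are
# 1-based inside R records and 0-based in on-disk tracing tables.

#' Construct an echo video record
#'
#' @param video_id character id.
#' @param frames numeric array `(H, W, T)` with values in `[0, 1]`.
#' @param keys data frame with columns `frame` (1-based index) and `type`
#'   (`"ED"` or `"ES"`).
#' @param masks named list of logical `(H, W)` masks, keyed by
#'   `as.character(frame)`; only key frames carry masks.
#' @param traces optional named list of tracing tables (columns
#'   `x1, y1, x2, y2`), same keys as `masks`.
#' @return an object of class `echo_record`.
#' @export
echo_record <- function(video_id, frames, keys, masks = list(),
                        traces = NULL) {
  d <- dim(frames)
  stop_if(length(d) != 3L, "frames must be an (H, W, T) array")
  stop_if(any(keys$frame < 1L) || any(keys$frame > d[3L]),
          "key frame indices out of range for a %d-frame video", d[3L])
  structure(list(video_id = video_id, frames = frames, keys = keys,
                 masks = masks, traces = traces,
                 height = d[1L], width = d[2L], n_frames = d[3L]),
            class = "echo_record")
}

#' @export
print.echo_record <- function(x, ...) {
  cat(sprintf("<echo_record %s: %d frames %dx%d, keys [%s]>\n", x$video_id,
              x$n_frames, x$height, x$width,
              paste(sprintf("%s@%d", x$keys$type, x$keys$frame),
                    collapse = ", ")))
  invisible(x)
}

#' Sample the 8-frame training clip around a key frame
#'
#' The clip covers the four frames before the key frame, the key frame
#' itself, and the three frames after, so the key frame sits at clip
#' position 5 (1-based). Records whose key frames lack this context are
#' removed by [clean_dataset()]; sampling such a key frame is an error.
#'
#' @param record an [echo_record()].
#' @param key_frame_index 1-based frame index of an annotated key frame.
#' @param channels replicate the grayscale frame to this many channels.
#' @return list with `clip` (`(8, channels, H, W)` array), `key_index`
#'   (always 5), `mask` (if the record has one for this frame), `type`.
#' @export
sample_clip <- function(record, key_frame_index, channels = 1L) {
  k <- key_frame_index
  stop_if(k - 4L < 1L || k + 3L > record$n_frames,
          "key frame %d lacks the 4-before/3-after context in a %d-frame video",
          k, record$n_frames)
  idx <- (k - 4L):(k + 3L)
  fr <- record$frames[, , idx, drop = FALSE]          # (H, W, 8)
  clip <- array(0, c(8L, channels, record$height, record$width))
  for (t in seq_len(8L)) for (c in seq_len(channels))
    clip[t, c, , ] <- fr[, , t]
  ktype <- record$keys$type[match(k, record$keys$frame)]
  list(clip = clip, key_index = 5L,
       mask = record$masks[[as.character(k)]],
       type = if (length(ktype)) ktype else NA_character_)
}

#' Remove records violating the 8-frame clip rule
#'
#' Keeps only records in which EVERY key frame has at least 4 frames
#' before and 3 after it. Order-preserving and idempotent.
#'
#' @param records list of [echo_record()]s.
#' @return filtered list.
#' @export
clean_dataset <- function(records) {
  keep <- vapply(records, function(r) {
    all(r$keys$frame - 4L >= 1L & r$keys$frame + 3L <= r$n_frames)
  }, logical(1))
  records[keep]
}

#' Expand records into training items
#'
#' One item per (record, key frame) pair: ED and ES clips from the same
#' video are independent items.
#'
#' @param records list of cleaned [echo_record()]s.
#' @param channels clip channels.
#' @return list of `list(clip, mask, key_index, id, type)` items.
#' @export
dataset_items <- function(records, channels = 1L) {
  items <- list()
  for (rec in records) {
    for (i in seq_len(nrow(rec$keys))) {
      it <- sample_clip(rec, rec$keys$frame[i], channels = channels)
      it$id <- rec$video_id
      items[[length(items) + 1L]] <- it
    }
  }
  items
}

#' Rasterize a paired-coordinate boundary trace into a mask
#'
#' EchoNet-style tracings give paired left/right boundary points per
#' scanline: row `i` contributes points `(x1, y1)` and `(x2, y2)`. The
#' polygon formed by the `(x1, y1)` chain followed by the reversed
#' `(x2, y2)` chain is filled. A pixel `(row, col)` (0-based) belongs to
#' the mask when its centre `(X = col, Y = row)` lies inside the polygon
#' or exactly on its boundary (even-odd rule, boundary inclusive).
#'
#' @param trace data frame with columns `x1, y1, x2, y2` (>= 2 rows).
#' @param H,W output mask size.
#' @return logical `(H, W)` mask.
#' @export
rasterize_trace <- function(trace, H, W) {
  stop_if(nrow(trace) < 2L,
          "trace needs at least 2 coordinate pairs, got %d", nrow(trace))
  px <- c(trace$x1, rev(trace$x2))
  py <- c(trace$y1, rev(trace$y2))
  # drop consecutive duplicate vertices
  keep <- c(TRUE, diff(px) != 0 | diff(py) != 0)
  px <- px[keep]; py <- py[keep]
  if (px[1L] == px[length(px)] && py[1L] == py[length(py)]) {
    px <- px[-length(px)]; py <- py[-length(py)]
  }
  stop_if(length(px) < 3L, "degenerate trace: fewer than 3 distinct vertices")
  area2 <- sum(px * c(py[-1L], py[1L]) - c(px[-1L], px[1L]) * py)
  stop_if(abs(area2) < 1e-9, "degenerate trace: collinear boundary points")
  gx <- rep(0:(W - 1L), each = H)   # X = col for each pixel, column-major
  gy <- rep(0:(H - 1L), times = W)  # Y = row
  inside <- rep(FALSE, H * W)
  on_edge <- rep(FALSE, H * W)
  nv <- length(px)
  jx <- px[c(nv, seq_len(nv - 1L))]
  jy <- py[c(nv, seq_len(nv - 1L))]
  for (e in seq_len(nv)) {
    x1 <- jx[e]; y1 <- jy[e]; x2 <- px[e]; y2 <- py[e]
    crosses <- (y1 > gy) != (y2 > gy)
    if (any(crosses)) {
      xint <- x1 + (gy - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (gx < xint))
    }
    # boundary-inclusive: point on the segment?
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    tpar <- ((gx - x1) * dx + (gy - y1) * dy) / len2
    tpar <- clamp(tpar, 0, 1)
    d2 <- (gx - (x1 + tpar * dx))^2 + (gy - (y1 + tpar * dy))^2
    on_edge <- on_edge | d2 < 1e-12
  }
  matrix(inside | on_edge, H, W)
}

#' Train-time augmentation of a clip/mask pair
#'
#' One geometric transform is sampled per clip (random horizontal flip,
#' rotation in `[-20, 20]` degrees, scaling in `[0.9, 1.1]`, shift in
#' `[-0.0625, 0.0625]` of the image size) and applied identically to all
#' frames and to the mask (bilinear for frames, nearest for the mask);
#' photometric jitter (brightness and contrast factors in `[0.8, 1.2]`)
#' applies to frames only. Deterministic given `seed`.
#'
#' @param clip numeric array `(T, C, H, W)`.
#' @param mask logical `(H, W)` key-frame mask.
#' @param seed RNG seed.
#' @param rotation,scaling,shifting,photometric ranges of the jitters.
#' @return list `(clip, mask, params)`.
#' @export
augment_clip <- function(clip, mask, seed,
                         rotation = c(-20, 20), scaling = c(0.9, 1.1),
                         shifting = c(-0.0625, 0.0625),
                         photometric = c(0.8, 1.2)) {
  d <- dim(clip)
  H <- d[3L]; W <- d[4L]
  local_seed(seed, {
    pars <- list(flip = stats::runif(1) < 0.5,
                 rot = stats::runif(1, rotation[1L], rotation[2L]),
                 scale = stats::runif(1, scaling[1L], scaling[2L]),
                 shift_r = stats::runif(1, shifting[1L], shifting[2L]) * H,
                 shift_c = stats::runif(1, shifting[1L], shifting[2L]) * W,
                 brightness = stats::runif(1, photometric[1L],
                                           photometric[2L]),
                 contrast = stats::runif(1, photometric[1L], photometric[2L]))
    out <- clip
    for (t in seq_len(d[1L])) for (c in seq_len(d[2L])) {
      fr <- warp_affine(matrix(clip[t, c, , ], H, W), pars, bilinear = TRUE)
      fr <- (fr - 0.5) * pars$contrast + 0.5
      fr <- clamp(fr * pars$brightness, 0, 1)
      out[t, c, , ] <- fr
    }
    m2 <- warp_affine(matrix(as.numeric(mask), H, W), pars,
                      bilinear = FALSE) > 0.5
    list(clip = out, mask = m2, params = pars)
  })
}

# Affine warp about the image centre; inverse mapping with border zeros.
#' @noRd
warp_affine <- function(img, pars, bilinear = TRUE) {
  H <- nrow(img); W <- ncol(img)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  th <- pars$rot * pi / 180
  # inverse transform: undo shift, rotation, scale, flip (in that order)
  ro <- rep(0:(H - 1), times = W) - cr - pars$shift_r
  co <- rep(0:(W - 1), each = H) - cc - pars$shift_c
  rs <- (cos(th) * ro + sin(th) * co) / pars$scale
  cs <- (-sin(th) * ro + cos(th) * co) / pars$scale
  if (isTRUE(pars$flip)) cs <- -cs
  rs <- rs + cr
  cs <- cs + cc
  if (bilinear) {
    r0 <- floor(rs); c0 <- floor(cs)
    fr <- rs - r0; fc <- cs - c0
    val <- function(r, c) {
      ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
      v <- numeric(length(r))
      v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
      v
    }
    v <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
      val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  } else {
    rn <- round(rs); cn <- round(cs)
    ok <- rn >= 0 & rn <= H - 1 & cn >= 0 & cn <= W - 1
    v <- numeric(length(rs))
    v[ok] <- img[cbind(rn[ok] + 1, cn[ok] + 1)]
  }
  matrix(v, H, W)
}
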