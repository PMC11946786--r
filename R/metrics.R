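# Segmentation metrics: Dice similarity, Hausdorff distance, HD95, and an
# evaluation runner producing per-clip and aggregate reports.
#
# Masks are 2D logical grids; pixel coordinates are 0-based (row, col).
# Conventions for degenerate inputs (the usual medical-imaging choices):
#   * dice(empty, empty) = 1 (perfect agreement);
#     dice(empty, nonempty) = 0;
#   * any empty mask makes HD / HD95 the image diagonal (a sentinel, so an
#     empty prediction is maximally penalised rather than undefined).

#' @noRd
check_masks <- function(A, B) {
  stop_if(is.null(dim(A)) || is.null(dim(B)) ||
            length(dim(A)) != 2L || length(dim(B)) != 2L,
          "masks must be 2D")
  stop_if(!all(dim(A) == dim(B)),
          "mask shapes differ: %s vs %s",
          paste(dim(A), collapse = "x"), paste(dim(B), collapse = "x"))
  invisible(NULL)
}

#' Dice similarity coefficient
#'
#' `DSC(A, B) = 2|A n B| / (|A| + |B|)`; symmetric, in `[0, 1]`. Both
#' masks empty gives 1; exactly one empty gives 0.
#'
#' @param A,B logical (or 0/1) matrices of identical shape.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' A <- matrix(FALSE, 4, 4); A[1, 1:2] <- TRUE
#' B <- matrix(FALSE, 4, 4); B[1, 2:3] <- TRUE
#' dice(A, B)  # |A|=2, |B|=2, overlap 1 -> 0.5
dice <- function(A, B) {
  check_masks(A, B)
  A <- A != 0; B <- B != 0
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Boundary pixels of a binary mask
#'
#' Inner boundary under 8-connectivity: mask pixels with at least one of
#' their 8 neighbours outside the mask (image-border pixels of the mask
#' count as boundary). Coordinates are 0-based (row, col).
#'
#' @param mask logical matrix.
#' @return 2-column matrix of 0-based (row, col) coordinates.
#' @export
boundary_points <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  if (!any(mask)) return(matrix(numeric(0), 0L, 2L))
  padded <- matrix(FALSE, d[1L] + 2L, d[2L] + 2L)
  padded[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- mask
  all_in <- matrix(TRUE, d[1L], d[2L])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    all_in <- all_in & padded[(2:(d[1L] + 1L)) + dr, (2:(d[2L] + 1L)) + dc]
  }
  idx <- which(mask & !all_in, arr.ind = TRUE)
  cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
}

# Directed distances: for each point of `from`, the Euclidean distance to
# its nearest point of `to`.
#' @noRd
directed_dists <- function(from, to) {
  d2 <- outer(from[, 1L], to[, 1L], "-")^2 + outer(from[, 2L], to[, 2L], "-")^2
  sqrt(apply(d2, 1L, min))
}

#' @noRd
hd_generic <- function(A, B, reduce) {
  check_masks(A, B)
  pa <- boundary_points(A)
  pb <- boundary_points(B)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    return(sqrt(sum((dim(A) - 1)^2)))  # sentinel: image diagonal
  max(reduce(directed_dists(pa, pb)), reduce(directed_dists(pb, pa)))
}

#' Hausdorff distance between mask boundaries
#'
#' `HD(A, B) = max(h(A, B), h(B, A))` with
#' `h(A, B) = max_a min_b ||a - b||` over the 8-connectivity boundary
#' point sets, in pixels. Any empty mask yields the image diagonal as a
#' sentinel.
#'
#' @inheritParams dice
#' @return distance in pixels (`>= 0`).
#' @export
hausdorff <- function(A, B) hd_generic(A, B, max)

#' 95th-percentile Hausdorff distance
#'
#' Replaces each directed maximum with the 95th percentile of that
#' direction's distance distribution (outlier-robust), then takes the
#' maximum over the two directions; always `<=` [hausdorff()].
#'
#' @inheritParams dice
#' @param probs percentile (default 0.95).
#' @return distance in pixels.
#' @export
hd95 <- function(A, B, probs = 0.95) {
  hd_generic(A, B, function(d) stats::quantile(d, probs, names = FALSE))
}

#' Evaluate a model over a dataset of records
#'
#' Runs [predict_mask()] on the 8-frame clip around every key frame of
#' every record and scores it against the ground-truth mask.
#'
#' @param model an `echoretnet_model`.
#' @param records list of `echo_record` objects (see [echo_record()]).
#' @param channels clip channels to present to the model.
#' @return a `seg_report`: `items` data frame (id, frame, type, dice,
#'   hd95), aggregate means, and counts by key-frame type.
#' @export
evaluate_model <- function(model, records, channels = NULL) {
  stop_if(length(records) == 0L, "empty dataset")
  channels <- channels %||% model$config$in_channels
  rows <- list()
  for (rec in records) {
    for (i in seq_len(nrow(rec$keys))) {
      kf <- rec$keys$frame[i]
      item <- sample_clip(rec, kf, channels = channels)
      pred <- predict_mask(model, item$clip, item$key_index)
      truth <- rec$masks[[as.character(kf)]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$video_id, frame = kf, type = rec$keys$type[i],
        dice = dice(pred, truth), hd95 = hd95(pred, truth),
        stringsAsFactors = FALSE)
    }
  }
  items <- do.call(rbind, rows)
  structure(list(items = items,
                 mean_dice = mean(items$dice),
                 mean_hd95 = mean(items$hd95),
                 counts = table(items$type)),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, ...) {
  cat("<seg_report>\n")
  cat(sprintf("  items: %d (%s)\n", nrow(x$items),
              paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
                    collapse = ", ")))
  cat(sprintf("  mean DSC:  %.4f\n", x$mean_dice))
  cat(sprintf("  mean HD95: %.3f px\n", x$mean_hd95))
  invisible(x)
}

#' Write a segmentation report to CSV and JSON
#'
#' @param report a `seg_report`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return the report, invisibly.
#' @export
write_seg_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$items, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(mean_dice = report$mean_dice, mean_hd95 = report$mean_hd95,
           items = report$items),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
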