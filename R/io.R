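# On-disk dataset dialects.
#
# EchoNet-style: a corpus directory with
#   Videos/<id>/frame_0001.png ...   (grayscale frames; this package
#                                     stores video frames as PNG
#                                     sequences)
#   FileList.csv                     FileName,Split,NumberOfFrames
#   VolumeTracings.csv               FileName,X1,Y1,X2,Y2,Frame
# Frames in VolumeTracings are 0-based (matching the public tables);
# X = column, Y = row, 0-based pixel coordinates.
#
# CAMUS-style: per-patient NIfTI volumes <id>_<view>_sequence.nii.gz and
# <id>_<view>_sequence_gt.nii.gz, half a cycle from ED (first frame) to
# ES (last frame); the endocardium label is retained as the left
# ventricle and every other label dropped.

#' Write records as an EchoNet-style corpus
#'
#' @param records list of [echo_record()]s (with optional `$split`).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_echonet_corpus <- function(records, dir) {
  vdir <- file.path(dir, "Videos")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  fl <- data.frame(FileName = character(0), Split = character(0),
                   NumberOfFrames = integer(0))
  tr <- list()
  for (rec in records) {
    rdir <- file.path(vdir, rec$video_id)
    dir.create(rdir, showWarnings = FALSE)
    for (t in seq_len(rec$n_frames)) {
      png::writePNG(clamp(rec$frames[, , t], 0, 1),
                    file.path(rdir, sprintf("frame_%04d.png", t)))
    }
    fl <- rbind(fl, data.frame(FileName = rec$video_id,
                               Split = rec$split %||% "TRAIN",
                               NumberOfFrames = rec$n_frames))
    for (k in rec$keys$frame) {
      trace <- mask_to_trace(rec$masks[[as.character(k)]])
      tr[[length(tr) + 1L]] <- data.frame(
        FileName = rec$video_id, X1 = trace$x1, Y1 = trace$y1,
        X2 = trace$x2, Y2 = trace$y2, Frame = k - 1L)
    }
  }
  utils::write.csv(fl, file.path(dir, "FileList.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, tr), file.path(dir, "VolumeTracings.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Export a mask as paired per-row boundary coordinates
#'
#' For every mask row containing pixels, emits the leftmost and rightmost
#' column (the ventricle section is row-convex, so the pair represents
#' the row exactly). This is the same paired-coordinate dialect as
#' EchoNet tracings, so [rasterize_trace()] round-trips it.
#'
#' @param mask logical matrix.
#' @return data frame `x1, y1, x2, y2` (0-based image coordinates,
#'   X = column, Y = row).
#' @export
mask_to_trace <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  stop_if(length(rows) < 2L, "mask has fewer than 2 non-empty rows")
  x1 <- integer(length(rows)); x2 <- integer(length(rows))
  for (i in seq_along(rows)) {
    cc <- which(mask[rows[i], ])
    x1[i] <- min(cc) - 1L
    x2[i] <- max(cc) - 1L
  }
  data.frame(x1 = x1, y1 = rows - 1L, x2 = x2, y2 = rows - 1L)
}

#' Read an EchoNet-style corpus
#'
#' Reads the file list, tracing tables and PNG frame directories written
#' by [write_echonet_corpus()] (or arranged likewise), rasterizes each
#' key frame's trace into a mask, and labels the larger-area key frame of
#' each video ED and the smaller ES.
#'
#' @param dir corpus directory.
#' @param split optional subset: `"TRAIN"`, `"VAL"` or `"TEST"`.
#' @return list of [echo_record()]s.
#' @export
read_echonet_dataset <- function(dir, split = NULL) {
  fl <- utils::read.csv(file.path(dir, "FileList.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(split)) fl <- fl[fl$Split %in% split, , drop = FALSE]
  tr <- utils::read.csv(file.path(dir, "VolumeTracings.csv"),
                        stringsAsFactors = FALSE)
  records <- vector("list", nrow(fl))
  for (i in seq_len(nrow(fl))) {
    id <- fl$FileName[i]
    rdir <- file.path(dir, "Videos", id)
    files <- sort(list.files(rdir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    stop_if(length(files) == 0L, "no frames found for video %s", id)
    first <- png::readPNG(files[1L])
    if (length(dim(first)) == 3L) first <- first[, , 1L]
    frames <- array(0, c(nrow(first), ncol(first), length(files)))
    frames[, , 1L] <- first
    for (t in seq_along(files)[-1L]) {
      fr <- png::readPNG(files[t])
      if (length(dim(fr)) == 3L) fr <- fr[, , 1L]
      frames[, , t] <- fr
    }
    vt <- tr[tr$FileName == id, , drop = FALSE]
    kf <- sort(unique(vt$Frame)) + 1L            # to 1-based
    masks <- list()
    for (k in kf) {
      seg <- vt[vt$Frame == k - 1L, , drop = FALSE]
      masks[[as.character(k)]] <- rasterize_trace(
        data.frame(x1 = seg$X1, y1 = seg$Y1, x2 = seg$X2, y2 = seg$Y2),
        nrow(first), ncol(first))
    }
    areas <- vapply(masks, sum, numeric(1))
    types <- rep("ES", length(kf))
    types[which.max(areas)] <- "ED"
    keys <- data.frame(frame = kf, type = types, stringsAsFactors = FALSE)
    rec <- echo_record(id, frames, keys, masks)
    rec$split <- fl$Split[i]
    records[[i]] <- rec
  }
  records
}

#' Read a CAMUS-style dataset
#'
#' Per-patient NIfTI sequence volumes plus label volumes
#' (`<id>_<view>_sequence.nii[.gz]` and `..._sequence_gt.nii[.gz]`); the
#' half-cycle convention puts ED at the first and ES at the last frame.
#' Only the endocardium label is retained as the left ventricle; other
#' labels are dropped.
#'
#' @param dir dataset root containing patient subdirectories.
#' @param views which views to load (`"2CH"`, `"4CH"`).
#' @param endo_label integer label id of the endocardium in the ground
#'   truth volumes.
#' @return list of [echo_record()]s (one per patient-view).
#' @export
read_camus_dataset <- function(dir, views = c("2CH", "4CH"),
                               endo_label = 1L) {
  patients <- list.dirs(dir, recursive = FALSE)
  records <- list()
  for (p in patients) {
    pid <- basename(p)
    for (v in views) {
      seqf <- Sys.glob(file.path(p, sprintf("%s_%s_sequence.nii*", pid, v)))
      gtf <- Sys.glob(file.path(p, sprintf("%s_%s_sequence_gt.nii*", pid, v)))
      if (length(seqf) == 0L || length(gtf) == 0L) next
      vol <- as.array(RNifti::readNifti(seqf[1L]))
      gt <- as.array(RNifti::readNifti(gtf[1L]))
      if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
      if (length(dim(gt)) == 2L) dim(gt) <- c(dim(gt), 1L)
      Tn <- dim(vol)[3L]
      rng <- range(vol)
      frames <- (vol - rng[1L]) / max(rng[2L] - rng[1L], 1e-12)
      keys <- data.frame(frame = c(1L, Tn), type = c("ED", "ES"),
                         stringsAsFactors = FALSE)
      masks <- list()
      masks[["1"]] <- gt[, , 1L] == endo_label
      masks[[as.character(Tn)]] <- gt[, , Tn] == endo_label
      records[[length(records) + 1L]] <-
        echo_record(paste(pid, v, sep = "_"), frames, keys, masks)
    }
  }
  records
}
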