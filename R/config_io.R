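# YAML model-configuration files.

#' Read a model configuration from YAML
#'
#' The file may contain `tffm`, `encoder`, `decoder`, `frames`,
#' `in_channels` and `phantom` blocks; omitted fields take the package
#' defaults.
#'
#' @param path YAML file.
#' @return list with `model` (a [model_config()]) and, if present,
#'   `phantom` (a [phantom_config()]).
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(ctor, args) do.call(ctor, args %||% list())
  model <- model_config(
    tffm = mk(tffm_config, y$tffm),
    encoder = mk(encoder_config, y$encoder),
    decoder = mk(decoder_config, y$decoder),
    frames = y$frames %||% 8L,
    in_channels = y$in_channels %||% 1L)
  out <- list(model = model)
  if (!is.null(y$phantom)) out$phantom <- mk(phantom_config, y$phantom)
  out
}

#' Write a model configuration to YAML
#'
#' @param config a [model_config()].
#' @param path output file.
#' @param phantom optional [phantom_config()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path, phantom = NULL) {
  y <- list(
    tffm = unclass(config$tffm),
    encoder = unclass(config$encoder)[c("depths", "widths", "heads",
                                        "ffn_ratio", "use_decomposed",
                                        "stem")],
    decoder = unclass(config$decoder),
    frames = config$frames,
    in_channels = config$in_channels)
  if (!is.null(phantom)) y$phantom <- unclass(phantom)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Plot a mask overlay on a frame
#'
#' Plumbing for quick visual inspection: frame as grayscale, ground truth
#' and prediction boundaries overlaid in colour.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param truth,pred optional logical masks.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_overlay <- function(frame, truth = NULL, pred = NULL, main = "") {
  graphics::image(t(frame[nrow(frame):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, main = main, useRaster = TRUE)
  add_boundary <- function(mask, col) {
    if (is.null(mask)) return()
    bp <- boundary_points(mask)
    if (nrow(bp) == 0L) return()
    graphics::points(bp[, 2L] / (ncol(frame) - 1),
                     1 - bp[, 1L] / (nrow(frame) - 1),
                     col = col, pch = ".", cex = 2)
  }
  add_boundary(truth, "green")
  add_boundary(pred, "red")
  invisible(NULL)
}
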