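# Feature pyramid decoder and segmentation head.

#' Decoder configuration
#'
#' @param fpn_width common channel width the four pyramid levels are
#'   projected to before fusion.
#' @param num_classes number of output channels (1: binary left-ventricle
#'   mask).
#' @return an object of class `decoder_config`.
#' @export
decoder_config <- function(fpn_width = 64L, num_classes = 1L) {
  stop_if(fpn_width < 1L, "fpn_width must be >= 1")
  structure(list(fpn_width = as.integer(fpn_width),
                 num_classes = as.integer(num_classes)),
            class = "decoder_config")
}

#' Initialise decoder parameters
#'
#' @param cfg a [decoder_config()].
#' @param widths encoder stage widths (4 entries).
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
decoder_init <- function(cfg, widths, seed = 1L) {
  fw <- cfg$fpn_width
  local_seed(seed, {
    p <- list()
    for (i in 1:4) {
      p[[sprintf("lat%d.w", i)]] <- he_init(c(1L, 1L, widths[i], fw))
      p[[sprintf("lat%d.b", i)]] <- numeric(fw)
    }
    # normalising the fused map keeps head activations O(1) regardless of
    # encoder depth, so the sigmoid never starts saturated
    p$hn.g <- rep(1, fw)
    p$hn.b <- numeric(fw)
    p$h1.w <- he_init(c(3L, 3L, fw, fw))
    p$h1.b <- numeric(fw)
    # zero-init the logit projection: probabilities start at 0.5, keeping
    # the sigmoid unsaturated so the absolute-error loss has gradient
    p$h2.w <- array(0, c(1L, 1L, fw, cfg$num_classes))
    p$h2.b <- numeric(cfg$num_classes)
    p
  })
}

#' @noRd
fpn_fwd <- function(pyr, pn, cfg) {
  stop_if(length(pyr) != 4L, "feature pyramid must have exactly 4 levels")
  target <- dim(pyr[[1L]]$value)[1:2]
  fused <- vector("list", 4L)
  for (i in 1:4) {
    lvl <- ad_conv2d(pyr[[i]], pn[[sprintf("lat%d.w", i)]],
                     pn[[sprintf("lat%d.b", i)]])
    if (!all(dim(lvl$value)[1:2] == target))
      lvl <- ad_upsample(lvl, target[1L], target[2L])
    fused[[i]] <- lvl
  }
  ad_add_n(fused)
}

#' @noRd
seg_head_fwd <- function(fused, pn, out_h, out_w) {
  x <- ad_instnorm(fused, pn$hn.g, pn$hn.b)
  x <- ad_gelu(ad_conv2d(x, pn$h1.w, pn$h1.b, stride = 1L, pad = 1L))
  x <- ad_conv2d(x, pn$h2.w, pn$h2.b)
  ad_upsample(x, out_h, out_w)
}

#' Fuse a feature pyramid by projection, upsampling and addition
#'
#' Each level is projected to the common width with a 1x1 convolution,
#' bilinearly upsampled to the finest (stride-4) level's resolution, and
#' the four maps are summed element-wise.
#'
#' @param pyramid list of 4 feature maps `(H_i, W_i, C_i)`.
#' @param params parameters from [decoder_init()].
#' @param cfg a [decoder_config()].
#' @return fused map at the finest level's resolution, `fpn_width`
#'   channels.
#' @export
fpn_decode <- function(pyramid, params, cfg) {
  run_tape(function(tp) {
    fpn_fwd(lapply(pyramid, function(m) ad_leaf(tp, m)),
            params_to_nodes(tp, params), cfg)
  })
}

#' Segmentation head
#'
#' 3x3 convolution + GELU + 1x1 convolution to `num_classes` logit
#' channels, bilinearly upsampled to the requested output resolution.
#' Probabilities are `sigmoid(logits)`; masks threshold probabilities at
#' 0.5 (equivalently logits at 0).
#'
#' @param fused fused feature map from [fpn_decode()].
#' @param params parameters from [decoder_init()].
#' @param cfg a [decoder_config()].
#' @param out_h,out_w output (input-image) resolution.
#' @return logits array `(out_h, out_w, num_classes)`.
#' @export
seg_head <- function(fused, params, cfg, out_h, out_w) {
  run_tape(function(tp) {
    seg_head_fwd(ad_leaf(tp, fused), params_to_nodes(tp, params),
                 out_h, out_w)
  })
}
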