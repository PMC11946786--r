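# Four-stage retentive vision encoder.
#
# Layer = conditional positional encoding (residual depth-wise 3x3),
# pre-norm Manhattan self-attention (decomposed in stages 1-3, full in
# stage 4) plus local context enhancement on the value path, and a
# pre-norm feed-forward network; stride-2 3x3 convolutions between stages.
# The stem applies two consecutive stride-2 3x3 convolutions (overall
# stride 4) so the pyramid levels sit at strides 4, 8, 16, 32.

#' Encoder configuration
#'
#' @param depths layers per stage (4 stages).
#' @param widths embedding width per stage (non-decreasing).
#' @param heads attention heads per stage; each must divide the stage
#'   width.
#' @param ffn_ratio feed-forward expansion factor.
#' @param use_decomposed logical per stage; the default follows the
#'   four-stage design (decomposed attention in stages 1-3, full 2D decay
#'   in stage 4).
#' @param stem `"patch4"` (two stride-2 convolutions, overall stride 4,
#'   the default) or `"conv2"` (a single stride-2 convolution).
#' @param gammas optional list of per-stage decay-rate vectors (one per
#'   head); defaults to [masa_gammas()] per stage.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(depths = c(3L, 4L, 18L, 4L),
                           widths = c(64L, 128L, 256L, 512L),
                           heads = c(4L, 4L, 8L, 16L),
                           ffn_ratio = 4L,
                           use_decomposed = c(TRUE, TRUE, TRUE, FALSE),
                           stem = c("patch4", "conv2"),
                           gammas = NULL) {
  stem <- match.arg(stem)
  stop_if(length(depths) != 4L || length(widths) != 4L || length(heads) != 4L,
          "depths, widths and heads must each have 4 entries")
  stop_if(any(depths < 1L), "stage depths must be positive")
  stop_if(any(diff(widths) < 0), "widths must be non-decreasing")
  stop_if(any(widths %% heads != 0),
          "heads must divide the stage width (widths %s, heads %s)",
          paste(widths, collapse = ","), paste(heads, collapse = ","))
  if (is.null(gammas)) gammas <- lapply(heads, masa_gammas)
  for (g in unlist(gammas)) check_gamma(g)
  structure(list(depths = as.integer(depths), widths = as.integer(widths),
                 heads = as.integer(heads), ffn_ratio = as.integer(ffn_ratio),
                 use_decomposed = use_decomposed, stem = stem,
                 gammas = gammas),
            class = "encoder_config")
}

#' Initialise encoder parameters
#'
#' @param cfg an [encoder_config()].
#' @param in_channels channels of the input image.
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
encoder_init <- function(cfg, in_channels, seed = 1L) {
  local_seed(seed, {
    p <- list()
    w1 <- cfg$widths[1L]
    if (cfg$stem == "patch4") {
      p$stem1.w <- he_init(c(3L, 3L, in_channels, w1))
      p$stem1.b <- numeric(w1)
      p$stem2.w <- he_init(c(3L, 3L, w1, w1))
      p$stem2.b <- numeric(w1)
    } else {
      p$stem1.w <- he_init(c(3L, 3L, in_channels, w1))
      p$stem1.b <- numeric(w1)
    }
    for (s in 1:4) {
      C <- cfg$widths[s]
      if (s > 1L) {
        p[[sprintf("down%d.w", s)]] <- he_init(c(3L, 3L, cfg$widths[s - 1L], C))
        p[[sprintf("down%d.b", s)]] <- numeric(C)
      }
      for (l in seq_len(cfg$depths[s])) {
        pre <- sprintf("s%d.l%d.", s, l)
        p[[paste0(pre, "cpe.w")]] <- he_init(c(3L, 3L, C), fan_in = 9)
        p[[paste0(pre, "cpe.b")]] <- numeric(C)
        p[[paste0(pre, "ln1.g")]] <- rep(1, C)
        p[[paste0(pre, "ln1.b")]] <- numeric(C)
        for (nm in c("wq", "wk", "wv", "wo"))
          p[[paste0(pre, nm)]] <- he_init(c(C, C))
        for (nm in c("bq", "bk", "bv", "bo"))
          p[[paste0(pre, nm)]] <- numeric(C)
        p[[paste0(pre, "lce.w")]] <- he_init(c(5L, 5L, C), fan_in = 25)
        p[[paste0(pre, "lce.b")]] <- numeric(C)
        p[[paste0(pre, "ln2.g")]] <- rep(1, C)
        p[[paste0(pre, "ln2.b")]] <- numeric(C)
        p[[paste0(pre, "f1.w")]] <- he_init(c(C, C * cfg$ffn_ratio))
        p[[paste0(pre, "f1.b")]] <- numeric(C * cfg$ffn_ratio)
        p[[paste0(pre, "f2.w")]] <- he_init(c(C * cfg$ffn_ratio, C))
        p[[paste0(pre, "f2.b")]] <- numeric(C)
      }
    }
    p
  })
}

#' Conditional positional encoding
#'
#' Residual depth-wise 3x3 convolution (zero padding 1):
#' `x + DWConv3x3(x)`. With a zero kernel and bias the output equals the
#' input exactly.
#'
#' @param x feature map `(H, W, C)`.
#' @param w depth-wise kernel `(3, 3, C)`.
#' @param b bias vector length `C`.
#' @return feature map `(H, W, C)`.
#' @export
cpe <- function(x, w, b) {
  stop_if(dim(x)[3L] != dim(w)[3L],
          "cpe: input has %d channels, kernel has %d", dim(x)[3L], dim(w)[3L])
  x + conv2d_fwd(x, dw_dense(w), b, 1L, 1L)$y
}

#' Local context enhancement
#'
#' Depth-wise 5x5 convolution with zero padding 2 applied to the value
#' path; no internal residual (the residual lives in the attention block
#' sum).
#'
#' @param v value feature map `(H, W, C)`.
#' @param w depth-wise kernel `(5, 5, C)`.
#' @param b bias vector length `C`.
#' @return feature map `(H, W, C)`.
#' @export
lce <- function(v, w, b) {
  stop_if(dim(v)[3L] != dim(w)[3L],
          "lce: input has %d channels, kernel has %d", dim(v)[3L], dim(w)[3L])
  conv2d_fwd(v, dw_dense(w), b, 1L, 2L)$y
}

#' Stride-2 downsampling between stages
#'
#' 3x3 convolution, stride 2, zero padding 1; spatial dimensions are
#' floor-halved (`floor((n + 2 - 3)/2) + 1`) and the channel width mapped
#' to the next stage width.
#'
#' @param x feature map `(H, W, C_in)` with `H, W >= 2`.
#' @param w kernel `(3, 3, C_in, C_out)`.
#' @param b bias vector length `C_out`.
#' @return feature map at half resolution.
#' @export
downsample <- function(x, w, b) {
  d <- dim(x)
  stop_if(d[1L] < 2L || d[2L] < 2L,
          "downsample needs spatial size >= 2, got %dx%d", d[1L], d[2L])
  conv2d_fwd(x, w, b, 2L, 1L)$y
}

# ---- autodiff forward -----------------------------------------------------

# Multi-head Manhattan self-attention on (H, W, C) q/k/v nodes.
# recorder (env or NULL) logs which decay kinds are instantiated.
#' @noRd
masa_fwd <- function(q, k, v, gammas, decomposed, recorder = NULL,
                     stage = NA_integer_) {
  d <- dim(q$value)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  nh <- length(gammas)
  dh <- C %/% nh
  heads <- vector("list", nh)
  for (hh in seq_len(nh)) {
    idx <- (hh - 1L) * dh + seq_len(dh)
    qh <- ad_channels(q, idx); kh <- ad_channels(k, idx)
    vh <- ad_channels(v, idx)
    gam <- gammas[hh]
    if (!decomposed) {
      if (!is.null(recorder)) rec_decay(recorder, stage, "manhattan_2d")
      D <- decay_2d(H, W, gam)
      flat <- function(a) ad_reshape(ad_aperm(a, c(2L, 1L, 3L)), c(H * W, dh))
      A <- ad_mul_const(
        ad_rowsoftmax(ad_matmul(flat(qh), ad_transpose(flat(kh)))), D)
      o <- ad_matmul(A, flat(vh))
      heads[[hh]] <- ad_aperm(ad_reshape(o, c(W, H, dh)), c(2L, 1L, 3L))
    } else {
      if (!is.null(recorder)) {
        rec_decay(recorder, stage, "vertical")
        rec_decay(recorder, stage, "horizontal")
      }
      Dv <- decay_axis(H, gam, "vertical")
      Dh <- decay_axis(W, gam, "horizontal")
      cols <- vector("list", W)
      for (j in seq_len(W)) {
        Qc <- ad_slab_col(qh, j); Kc <- ad_slab_col(kh, j)
        A <- ad_mul_const(ad_rowsoftmax(ad_matmul(Qc, ad_transpose(Kc))), Dv)
        cols[[j]] <- ad_matmul(A, ad_slab_col(vh, j))
      }
      tmp <- ad_stack_cols(cols)
      rows <- vector("list", H)
      for (i in seq_len(H)) {
        Qr <- ad_slab_row(qh, i); Kr <- ad_slab_row(kh, i)
        A <- ad_mul_const(ad_rowsoftmax(ad_matmul(Qr, ad_transpose(Kr))), Dh)
        rows[[i]] <- ad_matmul(A, ad_slab_row(tmp, i))
      }
      heads[[hh]] <- ad_stack_rows(rows)
    }
  }
  if (nh == 1L) heads[[1L]] else ad_cat_channels(heads)
}

#' @noRd
rec_decay <- function(recorder, stage, kind) {
  key <- sprintf("stage%d", stage)
  recorder[[key]] <- unique(c(recorder[[key]], kind))
}

# One encoder layer on an (H, W, C) node.
#' @noRd
retnet_layer_fwd <- function(x, pn, pre, gammas, decomposed, ffn_ratio,
                             recorder = NULL, stage = NA_integer_) {
  d <- dim(x$value)
  x <- ad_add(x, ad_dwconv2d(x, pn[[paste0(pre, "cpe.w")]],
                             pn[[paste0(pre, "cpe.b")]], pad = 1L))
  hw <- d[1L] * d[2L]
  xm <- ad_reshape(x, c(hw, d[3L]))
  xn <- ad_reshape(
    ad_layernorm(xm, pn[[paste0(pre, "ln1.g")]], pn[[paste0(pre, "ln1.b")]]),
    d)
  q <- ad_proj(xn, pn[[paste0(pre, "wq")]], pn[[paste0(pre, "bq")]])
  k <- ad_proj(xn, pn[[paste0(pre, "wk")]], pn[[paste0(pre, "bk")]])
  v <- ad_proj(xn, pn[[paste0(pre, "wv")]], pn[[paste0(pre, "bv")]])
  att <- masa_fwd(q, k, v, gammas, decomposed, recorder, stage)
  att <- ad_add(att, ad_dwconv2d(v, pn[[paste0(pre, "lce.w")]],
                                 pn[[paste0(pre, "lce.b")]], pad = 2L))
  x <- ad_add(x, ad_proj(att, pn[[paste0(pre, "wo")]],
                         pn[[paste0(pre, "bo")]]))
  xm2 <- ad_reshape(x, c(hw, d[3L]))
  xn2 <- ad_layernorm(xm2, pn[[paste0(pre, "ln2.g")]],
                      pn[[paste0(pre, "ln2.b")]])
  f <- ad_bias_rows(ad_matmul(ad_gelu(
    ad_bias_rows(ad_matmul(xn2, pn[[paste0(pre, "f1.w")]]),
                 pn[[paste0(pre, "f1.b")]])),
    pn[[paste0(pre, "f2.w")]]), pn[[paste0(pre, "f2.b")]])
  ad_add(x, ad_reshape(f, d))
}

#' @noRd
encode_fwd <- function(x, pn, cfg, recorder = NULL) {
  x <- ad_conv2d(x, pn$stem1.w, pn$stem1.b, stride = 2L, pad = 1L)
  if (cfg$stem == "patch4")
    x <- ad_conv2d(x, pn$stem2.w, pn$stem2.b, stride = 2L, pad = 1L)
  pyramid <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1L)
      x <- ad_conv2d(x, pn[[sprintf("down%d.w", s)]],
                     pn[[sprintf("down%d.b", s)]], stride = 2L, pad = 1L)
    for (l in seq_len(cfg$depths[s])) {
      x <- retnet_layer_fwd(x, pn, sprintf("s%d.l%d.", s, l),
                            cfg$gammas[[s]], cfg$use_decomposed[s],
                            cfg$ffn_ratio, recorder, s)
    }
    pyramid[[s]] <- x
  }
  pyramid
}

# ---- numeric public wrappers ---------------------------------------------

#' One retentive encoder layer (forward only)
#'
#' Conditional positional encoding, pre-norm multi-head Manhattan
#' self-attention with local context enhancement on the value path
#' (residual), and a pre-norm feed-forward network (residual). Shape is
#' preserved.
#'
#' @param x feature map `(H, W, C)`.
#' @param params parameter list from [encoder_init()].
#' @param cfg an [encoder_config()].
#' @param stage,layer which stage/layer's parameters to apply.
#' @return feature map `(H, W, C)`.
#' @export
retnet_layer <- function(x, params, cfg, stage = 1L, layer = 1L) {
  run_tape(function(tp) {
    retnet_layer_fwd(ad_leaf(tp, x), params_to_nodes(tp, params),
                     sprintf("s%d.l%d.", stage, layer),
                     cfg$gammas[[stage]], cfg$use_decomposed[stage],
                     cfg$ffn_ratio)
  })
}

#' Encode an image into a four-level feature pyramid
#'
#' @param image numeric array `(H, W, C_in)` with `H, W >= 32`.
#' @param params parameter list from [encoder_init()].
#' @param cfg an [encoder_config()].
#' @return list of 4 feature maps at strides 4, 8, 16 and 32 (floor
#'   arithmetic), widths per `cfg$widths`; attribute `decay_kinds` records
#'   which decay-matrix kinds each stage instantiated.
#' @export
encode <- function(image, params, cfg) {
  d <- dim(image)
  stop_if(is.null(d) || length(d) != 3L, "image must be an (H, W, C) array")
  stop_if(d[1L] < 32L || d[2L] < 32L,
          "input %dx%d too small: the four-stage encoder needs >= 32 px per side",
          d[1L], d[2L])
  recorder <- new.env(parent = emptyenv())
  tp <- ad_tape()
  pyr <- encode_fwd(ad_leaf(tp, image), params_to_nodes(tp, params), cfg,
                    recorder)
  out <- lapply(pyr, `[[`, "value")
  attr(out, "decay_kinds") <- as.list(recorder)
  out
}

#' Number of parameters of a parameter list or model
#'
#' @param x a parameter list, or an `echoretnet_model`.
#' @return total count of scalar parameters.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "echoretnet_model"))
    return(sum(vapply(x$params, function(pl) sum(lengths(pl)), numeric(1))))
  sum(lengths(x))
}
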