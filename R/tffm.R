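# Temporal Feature Fusion Module (TFFM).
#
# A clip of T frames with C channels is fused along the temporal-channel
# axis (T*C channels), embedded and spatially compressed by an r-stride
# convolution into 3*r^2*D channels (the query, key and value blocks
# arranged sequentially along that axis), grouped into non-overlapping
# windows of three sizes along the temporal-channel axis, attended within
# each window over the flattened spatial axis, restored (ungroup, then an
# expansion back to T*C channels at full resolution), summed over window
# sizes (TCSA), and finally passed through channel aggregation (CA) which
# injects complementary inter-frame features.
#
# Public clip layout is (T, C, H, W); internally maps are (H, W, channels).

#' TFFM configuration
#'
#' @param r spatial compression ratio; must divide the frame height and
#'   width.
#' @param D embedded dimensionality per compressed cell; the fused
#'   temporal-channel axis is embedded into `3 * r^2 * D` channels
#'   (query, key and value blocks of `r^2 * D` each).
#' @param window_sizes exactly three window lengths; each must divide
#'   `r^2 * D`. Windows partition the temporal-channel axis (stride equal
#'   to the window length) so grouping is exactly invertible.
#' @param ca_expansion channel expansion rate of the aggregation stage.
#' @return an object of class `tffm_config`.
#' @export
tffm_config <- function(r = 2L, D = 16L, window_sizes = c(2L, 4L, 8L),
                        ca_expansion = 2L) {
  stop_if(length(window_sizes) != 3L, "exactly three window sizes required")
  per <- r * r * D
  bad <- window_sizes[per %% window_sizes != 0]
  stop_if(length(bad) > 0,
          "window sizes {%s} must divide r^2 * D = %d",
          paste(bad, collapse = ","), per)
  stop_if(ca_expansion < 1, "ca_expansion must be >= 1")
  structure(list(r = as.integer(r), D = as.integer(D),
                 window_sizes = as.integer(window_sizes),
                 ca_expansion = as.integer(ca_expansion)),
            class = "tffm_config")
}

#' Fuse the temporal and channel axes of a clip
#'
#' Stacks the frames of a `(T, C, H, W)` clip along the channel axis in
#' temporal order, giving a `(T*C, H, W)` array: fused channel
#' `(t-1)*C + c` is channel `c` of frame `t`. Exactly invertible by
#' [unfuse_temporal_channel()].
#'
#' @param clip numeric array `(T, C, H, W)`.
#' @return numeric array `(T*C, H, W)`.
#' @export
fuse_temporal_channel <- function(clip) {
  stop_if(length(dim(clip)) != 4L, "clip must be a (T, C, H, W) array")
  d <- dim(clip)
  # (T, C, H, W) -> fused channel index c + C*(t-1) fastest: permute so C
  # then T lead, then collapse.
  x <- aperm(clip, c(2L, 1L, 3L, 4L))
  dim(x) <- c(d[1L] * d[2L], d[3L], d[4L])
  x
}

#' Invert [fuse_temporal_channel()]
#'
#' @param fused numeric array `(T*C, H, W)`.
#' @param T_frames,C original temporal and channel extents.
#' @return numeric array `(T, C, H, W)`.
#' @export
unfuse_temporal_channel <- function(fused, T_frames, C) {
  d <- dim(fused)
  stop_if(d[1L] != T_frames * C, "fused axis %d != T*C = %d", d[1L],
          T_frames * C)
  dim(fused) <- c(C, T_frames, d[2L], d[3L])
  aperm(fused, c(2L, 1L, 3L, 4L))
}

# Internal layout change: (TC, H, W) <-> (H, W, TC)
#' @noRd
chw_to_hwc <- function(x) aperm(x, c(2L, 3L, 1L))
#' @noRd
hwc_to_chw <- function(x) aperm(x, c(3L, 1L, 2L))

#' Initialise TFFM parameters
#'
#' @param cfg a [tffm_config()].
#' @param T_frames,C clip temporal length and per-frame channels.
#' @param seed RNG seed for the (He-scaled normal) initialisation.
#' @return named list of parameter arrays.
#' @export
tffm_init <- function(cfg, T_frames, C, seed = 1L) {
  tc <- T_frames * C
  r <- cfg$r; per <- r * r * cfg$D
  ex <- cfg$ca_expansion * tc
  local_seed(seed, {
    p <- list()
    p$embed.w <- he_init(c(r, r, tc, 3L * per))
    p$embed.b <- numeric(3L * per)
    for (i in seq_along(cfg$window_sizes)) {
      p[[paste0("restore", i, ".w")]] <- he_init(c(1L, 1L, per, r * r * tc))
      p[[paste0("restore", i, ".b")]] <- numeric(r * r * tc)
    }
    p$ca.ln.g <- rep(1, tc)
    p$ca.ln.b <- numeric(tc)
    p$ca.c1.w <- he_init(c(1L, 1L, tc, ex))
    p$ca.c1.b <- numeric(ex)
    p$ca.dw.w <- he_init(c(3L, 3L, ex), fan_in = 9)
    p$ca.dw.b <- numeric(ex)
    p$ca.s <- numeric(ex)              # starts at 0: CA(Y) = Y initially
    p$ca.u.w <- he_init(c(1L, 1L, ex, 1L))
    p$ca.u.b <- numeric(1L)
    p$ca.o.w <- he_init(c(1L, 1L, ex, tc))
    p$ca.o.b <- numeric(tc)
    p
  })
}

#' @noRd
he_init <- function(dims, fan_in = NULL) {
  if (is.null(fan_in)) {
    nd <- length(dims)
    fan_in <- if (nd == 4L) dims[1L] * dims[2L] * dims[3L]
    else if (nd == 2L) dims[1L]
    else prod(dims[-length(dims)])
  }
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Embed and spatially compress the fused clip into Q/K/V blocks
#'
#' An `r`-kernel, `r`-stride convolution folds spatial detail into the
#' channel axis, producing `(3*r^2*D, H/r, W/r)`: the first `r^2*D`
#' channels are the query block, then key, then value.
#'
#' @param fused `(T*C, H, W)` array from [fuse_temporal_channel()].
#' @param weights parameter list from [tffm_init()] (uses `embed.w`,
#'   `embed.b`).
#' @param cfg a [tffm_config()].
#' @return array `(3*r^2*D, H/r, W/r)`.
#' @export
embed_compress_qkv <- function(fused, weights, cfg) {
  d <- dim(fused)
  stop_if(d[2L] %% cfg$r != 0 || d[3L] %% cfg$r != 0,
          "spatial size %dx%d not divisible by compression ratio r = %d",
          d[2L], d[3L], cfg$r)
  y <- conv2d_fwd(chw_to_hwc(fused), weights$embed.w, weights$embed.b,
                  stride = cfg$r, pad = 0L)$y
  hwc_to_chw(y)
}

#' Partition an embedded block axis into attention windows
#'
#' Flattens the spatial axes (row-major) and cuts each of the Q, K and V
#' blocks into contiguous non-overlapping windows of length `w` along the
#' temporal-channel axis (stride = `w`, identical offsets across blocks).
#' Exactly invertible by [ungroup_windows()].
#'
#' @param embedded `(3*r^2*D, h, w)` array from [embed_compress_qkv()].
#' @param w_i window length; must divide `r^2*D`.
#' @return list with elements `Q`, `K`, `V` (each a list of `(w_i, h*w)`
#'   matrices), plus the grid shape needed to invert.
#' @export
group_windows <- function(embedded, w_i) {
  d <- dim(embedded)
  stop_if(d[1L] %% 3L != 0, "embedded axis must hold 3 equal blocks")
  per <- d[1L] %/% 3L
  stop_if(per %% w_i != 0, "window %d must divide block size %d", w_i, per)
  L <- d[2L] * d[3L]
  # row-major spatial flatten: after aperm the dims are (c, w, h), so
  # collapsing (w, h) scans each row h left-to-right — the same token
  # order as token_flatten()
  flat <- aperm(embedded, c(1L, 3L, 2L))
  dim(flat) <- c(d[1L], L)
  G <- per %/% w_i
  cut_block <- function(off) {
    lapply(seq_len(G), function(g) {
      rows <- off + ((g - 1L) * w_i + 1L):(g * w_i)
      flat[rows, , drop = FALSE]
    })
  }
  list(Q = cut_block(0L), K = cut_block(per), V = cut_block(2L * per),
       h = d[2L], w = d[3L], w_i = w_i)
}

#' Invert [group_windows()] for one block
#'
#' @param groups list of `(w_i, L)` matrices (one block's windows).
#' @param h,w compressed spatial grid shape.
#' @return array `(r^2*D, h, w)`.
#' @export
ungroup_windows <- function(groups, h, w) {
  flat <- do.call(rbind, groups)
  dim(flat) <- c(nrow(flat), w, h)
  aperm(flat, c(1L, 3L, 2L))
}

#' Temporal-channel self-attention over multi-window groupings
#'
#' For each window size and each window, plain self-attention
#' `softmax(Q K') V` is computed over the temporal-channel axis (scores are
#' `w_i x w_i`); windows are restored to `(T*C, H, W)` by ungrouping and a
#' learned expansion back to full resolution, and the three window-size
#' restorations are summed.
#'
#' @param clip numeric array `(T, C, H, W)`.
#' @param cfg a [tffm_config()].
#' @param weights parameters from [tffm_init()].
#' @return numeric array `(T, C, H, W)`.
#' @export
tcsa <- function(clip, cfg, weights) {
  d <- dim(clip)
  run_tape(function(tp) {
    xf <- ad_leaf(tp, chw_to_hwc(fuse_temporal_channel(clip)))
    pn <- params_to_nodes(tp, weights)
    tcsa_fwd(xf, pn, cfg, d[1L], d[2L])
  }) |> hwc_to_chw() |> unfuse_temporal_channel(d[1L], d[2L])
}

# Autodiff TCSA forward: xf is an (H, W, T*C) node; returns (H, W, T*C).
#' @noRd
tcsa_fwd <- function(xf, pn, cfg, T_frames, C) {
  d <- dim(xf$value)
  H <- d[1L]; W <- d[2L]; tc <- d[3L]
  r <- cfg$r; per <- r * r * cfg$D
  stop_if(H %% r != 0 || W %% r != 0,
          "frame size %dx%d not divisible by r = %d", H, W, r)
  emb <- ad_conv2d(xf, pn$embed.w, pn$embed.b, stride = r, pad = 0L)
  h <- H %/% r; w <- W %/% r; L <- h * w
  # blocks -> (per, L) matrices in row-major spatial order
  block_mat <- function(idx) {
    blk <- ad_channels(emb, idx)                  # (h, w, per)
    ad_transpose(ad_reshape(ad_aperm(blk, c(2L, 1L, 3L)), c(L, per)))
  }
  Qm <- block_mat(seq_len(per))
  Km <- block_mat(per + seq_len(per))
  Vm <- block_mat(2L * per + seq_len(per))
  outs <- vector("list", length(cfg$window_sizes))
  for (i in seq_along(cfg$window_sizes)) {
    wsz <- cfg$window_sizes[i]
    G <- per %/% wsz
    grp_out <- vector("list", G)
    for (g in seq_len(G)) {
      rows <- ((g - 1L) * wsz + 1L):(g * wsz)
      Qg <- ad_rows(Qm, rows); Kg <- ad_rows(Km, rows); Vg <- ad_rows(Vm, rows)
      A <- ad_rowsoftmax(ad_matmul(Qg, ad_transpose(Kg)))
      grp_out[[g]] <- ad_matmul(A, Vg)
    }
    om <- ad_rbind(grp_out)                       # (per, L)
    # back to (h, w, per)
    o3 <- ad_aperm(ad_reshape(ad_transpose(om), c(w, h, per)), c(2L, 1L, 3L))
    # expansion to full resolution: 1x1 conv to r^2*TC then depth-to-space
    e <- ad_conv2d(o3, pn[[paste0("restore", i, ".w")]],
                   pn[[paste0("restore", i, ".b")]], stride = 1L, pad = 0L)
    e5 <- ad_reshape(e, c(h, w, r, r, tc))
    e5 <- ad_aperm(e5, c(3L, 1L, 4L, 2L, 5L))     # (r, h, r, w, tc)
    outs[[i]] <- ad_reshape(e5, c(H, W, tc))
  }
  ad_add_n(outs)
}

#' Channel aggregation
#'
#' Expands the fused temporal-channel axis (`Y = GELU(DWConv3x3(Conv1x1(
#' Norm(X))))`), extracts a single-channel universal feature with a 1x1
#' convolution, subtracts it from every expanded channel to obtain
#' complementary features, reinjects them scaled by the learnable
#' per-channel parameter `s` (`CA(Y) = Y + s * (Y - GELU(Conv1x1(Y)))`),
#' and projects back to `T*C` channels with a residual connection.
#' With `s = 0` the aggregation collapses to `CA(Y) = Y` exactly.
#'
#' @param x_tcsa numeric array `(T, C, H, W)` (TCSA output).
#' @param cfg a [tffm_config()].
#' @param weights parameters from [tffm_init()].
#' @return numeric array `(T, C, H, W)`.
#' @export
channel_aggregate <- function(x_tcsa, cfg, weights) {
  d <- dim(x_tcsa)
  run_tape(function(tp) {
    xf <- ad_leaf(tp, chw_to_hwc(fuse_temporal_channel(x_tcsa)))
    pn <- params_to_nodes(tp, weights)
    ca_fwd(xf, pn, cfg)
  }) |> hwc_to_chw() |> unfuse_temporal_channel(d[1L], d[2L])
}

#' @noRd
ca_fwd <- function(xf, pn, cfg) {
  d <- dim(xf$value)
  hw <- d[1L] * d[2L]
  xm <- ad_reshape(xf, c(hw, d[3L]))
  xn <- ad_reshape(ad_layernorm(xm, pn$ca.ln.g, pn$ca.ln.b), d)
  y <- ad_gelu(ad_dwconv2d(ad_conv2d(xn, pn$ca.c1.w, pn$ca.c1.b),
                           pn$ca.dw.w, pn$ca.dw.b, pad = 1L))
  u <- ad_gelu(ad_conv2d(y, pn$ca.u.w, pn$ca.u.b))
  cay <- ad_add(y, ad_chan_scale(ad_bcast_sub(y, u), pn$ca.s))
  ad_add(ad_conv2d(cay, pn$ca.o.w, pn$ca.o.b), xf)
}

#' Full TFFM forward pass
#'
#' [tcsa()] followed by [channel_aggregate()]; the clip shape is preserved
#' so the enhanced key frame can be extracted by its index.
#'
#' @inheritParams tcsa
#' @return numeric array `(T, C, H, W)`.
#' @export
tffm_forward <- function(clip, cfg, weights) {
  d <- dim(clip)
  run_tape(function(tp) {
    xf <- ad_leaf(tp, chw_to_hwc(fuse_temporal_channel(clip)))
    pn <- params_to_nodes(tp, weights)
    tffm_fwd(xf, pn, cfg, d[1L], d[2L])
  }) |> hwc_to_chw() |> unfuse_temporal_channel(d[1L], d[2L])
}

#' @noRd
tffm_fwd <- function(xf, pn, cfg, T_frames, C)
  ca_fwd(tcsa_fwd(xf, pn, cfg, T_frames, C), pn, cfg)

# Run a forward-only computation on a throwaway tape, returning the value.
#' @noRd
run_tape <- function(f) {
  tp <- ad_tape()
  f(tp)$value
}

# Wrap a flat parameter list as constant nodes (forward-only use).
#' @noRd
params_to_nodes <- function(tape, params, leaf = FALSE) {
  f <- if (leaf) ad_leaf else ad_const
  out <- lapply(params, function(p) f(tape, p))
  names(out) <- names(params)
  out
}
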