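# Model assembly, forward pass, training (AdamW + MAE) and prediction.

#' Full model configuration
#'
#' Bundles the TFFM, encoder and decoder configurations with the clip
#' contract (T frames, C channels per frame).
#'
#' @param tffm a [tffm_config()].
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()].
#' @param frames clip length T (the training protocol uses 8: four frames
#'   before the key frame, the key frame, three after).
#' @param in_channels channels per frame (1 for grayscale echo).
#' @return an object of class `model_config`.
#' @export
model_config <- function(tffm = tffm_config(),
                         encoder = encoder_config(),
                         decoder = decoder_config(),
                         frames = 8L, in_channels = 1L) {
  stop_if(frames < 1L, "frames must be >= 1")
  structure(list(tffm = tffm, encoder = encoder, decoder = decoder,
                 frames = as.integer(frames),
                 in_channels = as.integer(in_channels)),
            class = "model_config")
}

#' Reduced configuration for desk-scale experiments
#'
#' Widths `[16, 32, 64, 128]`, depths `[1, 1, 2, 1]`, TFFM `r = 2`,
#' `D = 8`, windows `{2, 4, 8}`: the same architecture at a size that
#' trains in minutes on one CPU.
#'
#' @inheritParams model_config
#' @return a `model_config`.
#' @export
reduced_config <- function(frames = 8L, in_channels = 1L) {
  model_config(
    tffm = tffm_config(r = 2L, D = 8L, window_sizes = c(2L, 4L, 8L)),
    encoder = encoder_config(depths = c(1L, 1L, 2L, 1L),
                             widths = c(16L, 32L, 64L, 128L),
                             heads = c(2L, 2L, 4L, 4L),
                             ffn_ratio = 2L),
    decoder = decoder_config(fpn_width = 32L),
    frames = frames, in_channels = in_channels)
}

#' Assemble a segmentation model
#'
#' Pipeline: TFFM over the clip -> extract the enhanced key frame ->
#' retentive encoder -> feature pyramid decoder -> segmentation head.
#' Parameter shapes are checked at build time; a parameter count is
#' attached.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for initialisation (rebuilds with the same seed
#'   are identical).
#' @return an object of class `echoretnet_model`.
#' @export
assemble_model <- function(config, seed = 1L) {
  tc <- config$frames * config$in_channels
  params <- list(
    tffm = tffm_init(config$tffm, config$frames, config$in_channels,
                     seed = seed),
    enc = encoder_init(config$encoder, config$in_channels, seed = seed + 1L),
    dec = decoder_init(config$decoder, config$encoder$widths,
                       seed = seed + 2L))
  m <- structure(list(config = config, params = params, seed = seed),
                 class = "echoretnet_model")
  m
}

#' @export
print.echoretnet_model <- function(x, ...) {
  cfg <- x$config
  cat("<echoretnet_model>\n")
  cat(sprintf("  clip: T=%d frames x %d channel(s)\n", cfg$frames,
              cfg$in_channels))
  cat(sprintf("  encoder: depths [%s], widths [%s], heads [%s]\n",
              paste(cfg$encoder$depths, collapse = ","),
              paste(cfg$encoder$widths, collapse = ","),
              paste(cfg$encoder$heads, collapse = ",")))
  cat(sprintf("  tffm: r=%d D=%d windows {%s}\n", cfg$tffm$r, cfg$tffm$D,
              paste(cfg$tffm$window_sizes, collapse = ",")))
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

# Full forward on the tape. clip: (T, C, H, W) array; returns logits node
# (H, W, 1). pn: list(tffm=, enc=, dec=) of node lists.
#' @noRd
model_fwd <- function(clip_node, key_index, pn, config, recorder = NULL) {
  dims <- attr(clip_node, "clip_dims")
  T_frames <- dims[1L]; C <- dims[2L]; H <- dims[3L]; W <- dims[4L]
  enh <- tffm_fwd(clip_node, pn$tffm, config$tffm, T_frames, C)
  key <- ad_channels(enh, (key_index - 1L) * C + seq_len(C))
  pyr <- encode_fwd(key, pn$enc, config$encoder, recorder)
  fused <- fpn_fwd(pyr, pn$dec, config$decoder)
  seg_head_fwd(fused, pn$dec, H, W)
}

#' @noRd
clip_to_node <- function(tape, clip, leaf = FALSE) {
  d <- dim(clip)
  v <- chw_to_hwc(fuse_temporal_channel(clip))
  nd <- if (leaf) ad_leaf(tape, v) else ad_const(tape, v)
  attr(nd, "clip_dims") <- d
  nd
}

#' Forward pass: clip to key-frame logits
#'
#' @param model an [assemble_model()] result.
#' @param clip numeric array `(T, C, H, W)`.
#' @param key_index 1-based index of the key frame within the clip.
#' @return logits matrix `(H, W)`.
#' @export
model_forward <- function(model, clip, key_index = 5L) {
  d <- dim(clip)
  stop_if(length(d) != 4L, "clip must be a (T, C, H, W) array")
  stop_if(d[1L] != model$config$frames || d[2L] != model$config$in_channels,
          "clip is %dx%d (T x C); model expects %dx%d", d[1L], d[2L],
          model$config$frames, model$config$in_channels)
  stop_if(key_index < 1L || key_index > d[1L], "key_index out of range")
  tp <- ad_tape()
  pn <- lapply(model$params, function(pl) params_to_nodes(tp, pl))
  node <- clip_to_node(tp, clip)
  out <- model_fwd(node, key_index, pn, model$config)
  matrix(out$value, d[3L], d[4L])
}

#' Predict a binary mask from a clip
#'
#' `sigmoid(logits) >= threshold`; with the default threshold 0.5 this is
#' logits `>= 0`.
#'
#' @inheritParams model_forward
#' @param threshold probability threshold.
#' @param probabilities also return the probability map.
#' @return logical mask `(H, W)`; if `probabilities`, a list
#'   `(mask, prob)`.
#' @export
predict_mask <- function(model, clip, key_index = 5L, threshold = 0.5,
                         probabilities = FALSE) {
  logits <- model_forward(model, clip, key_index)
  prob <- 1 / (1 + exp(-logits))
  mask <- prob >= threshold
  if (probabilities) list(mask = mask, prob = prob) else mask
}

#' Training configuration
#'
#' The protocol: mean absolute error between sigmoid probabilities and the
#' binary key-frame mask, AdamW, initial learning rate 1e-4 with step
#' decay (x0.1 at epochs 30 and 45 of a 50-epoch run), batch size 8,
#' 8-frame clips.
#'
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param batch_size clips per optimisation step.
#' @param weight_decay AdamW decoupled weight decay.
#' @param adam_eps AdamW denominator constant. With a hard-saturating
#'   absolute-error loss, a larger eps (1e-3 .. 1e-2) keeps step sizes
#'   proportional to the (vanishing) gradient instead of sign-like,
#'   preventing a runaway march into sigmoid saturation.
#' @param lr_drop_epochs epochs at which the rate is multiplied by
#'   `lr_drop_factor`.
#' @param lr_drop_factor step-decay factor.
#' @param max_steps optional hard cap on optimisation steps.
#' @param augment apply the train-time augmentations of [augment_clip()].
#' @param seed RNG seed covering shuffling and augmentation.
#' @param verbose print per-epoch mean loss.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 50L, batch_size = 8L,
                         weight_decay = 0.01, adam_eps = 1e-3,
                         lr_drop_epochs = c(30L, 45L), lr_drop_factor = 0.1,
                         max_steps = Inf, augment = FALSE, seed = 1L,
                         verbose = FALSE) {
  stop_if(lr < 0 || batch_size < 1L || epochs < 1L,
          "lr, epochs and batch_size must be positive")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, adam_eps = adam_eps,
                 lr_drop_epochs = lr_drop_epochs,
                 lr_drop_factor = lr_drop_factor,
                 max_steps = max_steps, augment = augment,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Train a model on clip/mask items
#'
#' Items are `(clip, mask, key_index)` triples, e.g. from
#' [dataset_items()]. The loss is the mean absolute error between the
#' sigmoid probability map of the key frame and its binary mask. Training
#' is fully seeded: the same seed, config and data order give the same
#' loss curve.
#'
#' @param model an `echoretnet_model`.
#' @param items list of items, each `list(clip, mask, key_index)`.
#' @param cfg a [train_config()].
#' @return list with the trained `model`, the per-step `loss_log`, and the
#'   per-step learning rates `lr_log`.
#' @export
train_model <- function(model, items, cfg = train_config()) {
  stop_if(length(items) == 0L, "empty training set")
  flat <- flatten_params(model$params)
  opt <- adamw_state(flat)
  loss_log <- numeric(0)
  lr_log <- numeric(0)
  step <- 0L
  local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$lr * cfg$lr_drop_factor^sum(ep > cfg$lr_drop_epochs)
      ord <- sample.int(length(items))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bt in batches) {
        if (step >= cfg$max_steps) break
        step <- step + 1L
        tp <- ad_tape()
        pn_flat <- params_to_nodes(tp, flat, leaf = TRUE)
        pn <- unflatten_nodes(pn_flat)
        losses <- vector("list", length(bt))
        for (ii in seq_along(bt)) {
          it <- items[[bt[ii]]]
          clip <- it$clip; mask <- it$mask
          if (isTRUE(cfg$augment)) {
            aug <- augment_clip(clip, mask, seed = sample.int(2^30, 1L))
            clip <- aug$clip; mask <- aug$mask
          }
          node <- clip_to_node(tp, clip)
          logits <- model_fwd(node, it$key_index, pn, model$config)
          prob <- ad_sigmoid(logits)
          tgt <- ad_const(tp, array(as.numeric(mask), dim(prob$value)))
          losses[[ii]] <- ad_mean(ad_abs(ad_sub(prob, tgt)))
        }
        loss <- ad_scale(ad_add_n(losses), 1 / length(losses))
        stop_if(!is.finite(loss$value),
                "non-finite loss at step %d (epoch %d); aborting", step, ep)
        ad_backward(tp, loss)
        flat <- adamw_step(flat, pn_flat, opt, lr, cfg$weight_decay,
                           eps = cfg$adam_eps)
        loss_log <- c(loss_log, loss$value)
        lr_log <- c(lr_log, lr)
      }
      if (isTRUE(cfg$verbose))
        message(sprintf("epoch %d: mean loss %.5f", ep,
                        mean(utils::tail(loss_log, length(batches)))))
      if (step >= cfg$max_steps) break
    }
  })
  model$params <- unflatten_params(flat)
  list(model = model, loss_log = loss_log, lr_log = lr_log)
}

# ---- parameter bookkeeping ------------------------------------------------

#' @noRd
flatten_params <- function(params) {
  out <- list()
  for (grp in names(params)) {
    pl <- params[[grp]]
    names(pl) <- paste(grp, names(pl), sep = "/")
    out <- c(out, pl)
  }
  out
}

#' @noRd
unflatten_params <- function(flat) {
  grps <- sub("/.*$", "", names(flat))
  out <- lapply(split(seq_along(flat), grps), function(idx) {
    pl <- flat[idx]
    names(pl) <- sub("^[^/]*/", "", names(pl))
    pl
  })
  out[unique(grps)]
}

#' @noRd
unflatten_nodes <- function(pn_flat) {
  grps <- sub("/.*$", "", names(pn_flat))
  out <- lapply(split(seq_along(pn_flat), grps), function(idx) {
    pl <- pn_flat[idx]
    names(pl) <- sub("^[^/]*/", "", names(pl))
    pl
  })
  out[unique(grps)]
}

#' @noRd
adamw_state <- function(flat) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(flat, function(p) p * 0)
  st$v <- lapply(flat, function(p) p * 0)
  st$t <- 0L
  st
}

#' @noRd
adamw_step <- function(flat, pn_flat, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(flat)) {
    g <- pn_flat[[nm]]$grad
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    flat[[nm]] <- flat[[nm]] - lr * (upd + wd * flat[[nm]])
  }
  flat
}
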