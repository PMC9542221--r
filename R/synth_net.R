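#' Synthesis network configuration
#'
#' Configuration of the self-supervised contrast-synthesis network: two
#' convolutional encoders (one per input contrast), pixel-wise max fusion of
#' the latent representations, three decoders emitting T1, T2 and PD map
#' slices, and a non-trainable physics layer turning predicted maps into
#' weighted intensities through the ideal signal equations.
#'
#' Self-supervision reconstructs acquired images from the shared set of
#' predicted maps through the physics layer; the loss is the average MAE
#' over all images entering the batch. By default only the target contrast
#' is reconstructed. Adding the two input contrasts to `loss_contrasts`
#' (each through its own acquisition parameters) makes the three maps
#' jointly identifiable from weighted images alone — the setting used for
#' parameter-recovery experiments.
#'
#' @param input_contrasts ordered pair of input contrast labels.
#' @param target_contrast the contrast to synthesize (not an input).
#' @param width channel width of the hidden convolution layers.
#' @param depth number of 3x3 convolution layers per encoder (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size slices per optimization step.
#' @param max_epochs,early_stop_patience training schedule; patience is on
#'   the validation loss, with best weights restored.
#' @param clip_norm global gradient-norm clipping threshold; guards the
#'   scaled-sigmoid map heads against early-training saturation.
#' @param val_fraction fraction of training subjects held out for early
#'   stopping (about 20%).
#' @param seed seed for initialization, splits and batch shuffling.
#' @param map_ranges list of `(min, max)` physical ranges (ms, ms, a.u.)
#'   enforced by a scaled sigmoid on each decoder output. By default the PD
#'   range is \[0, 1.1\] on raw forward-model intensities but \[0, 12\] on
#'   reference-normalized inputs, where the effective proton density must
#'   absorb the per-contrast normalization gain (WM signal maps to 1).
#' @param protocol acquisition protocol giving each contrast's parameters.
#' @param loss_contrasts contrasts reconstructed by the loss; default the
#'   target only.
#' @param normalize_inputs when `TRUE` (default) the network consumes and
#'   reconstructs the reference-normalized images, the space the radiomic
#'   pipeline operates in; predicted "maps" then absorb the per-contrast
#'   normalization constants. Set `FALSE` to work on raw forward-model
#'   intensities, where the relaxometry maps are physically identifiable —
#'   the setting used for parameter-recovery experiments.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(input_contrasts = c("T1w", "T2w"),
                         target_contrast = "FLAIR",
                         width = 8, depth = 2,
                         learning_rate = 1e-4, batch_size = 32,
                         clip_norm = 1,
                         max_epochs = 40, early_stop_patience = 10,
                         val_fraction = 0.2, seed = 1,
                         map_ranges = NULL,
                         protocol = default_protocol(),
                         loss_contrasts = NULL,
                         normalize_inputs = TRUE) {
  stopifnot(length(input_contrasts) == 2,
            !(target_contrast %in% input_contrasts),
            width >= 1, depth >= 1)
  if (is.null(loss_contrasts))
    loss_contrasts <- target_contrast
  if (is.null(map_ranges))
    map_ranges <- list(t1 = c(50, 4800), t2 = c(10, 2600),
                       pd = c(0, if (normalize_inputs) 12 else 1.1))
  structure(as.list(environment()), class = "synth_config")
}

# ---- parameter tree utilities -------------------------------------------

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

conv_layer <- function(cin, cout, k = 3) {
  list(W = he_init(k, k, cin, cout), b = rep(0, cout))
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) return(mapply(tree_map2, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}

tree_sum <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, tree_sum, 0, f = f)))
  f(a)
}

#' Build an untrained synthesis network
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_model` with deterministic (seeded)
#'   He-initialized weights; `$n_params` reports the trainable parameter
#'   count (the physics layer contributes none).
#' @export
build_network <- function(config) {
  set.seed(config$seed)
  C <- config$width
  make_encoder <- function() {
    layers <- list(conv_layer(1, C))
    for (d in seq_len(config$depth - 1)) layers <- c(layers, list(conv_layer(C, C)))
    layers
  }
  make_decoder <- function(head_bias = 0) {
    d <- list(h = conv_layer(C, C), out = conv_layer(C, 1))
    d$out$b[] <- head_bias
    d
  }
  # Physiological head initialization: each map head starts near
  # tissue-typical values (T1 ~ 900 ms, T2 ~ 90 ms, PD low since most
  # pixels of a slice are background) instead of mid-range. Mid-range
  # starts put the initial predictions far off scale, and the uniform L1
  # push can then saturate a head at its range floor — a dead basin the
  # sigmoid gradient cannot leave.
  # starts are clamped into the healthy-slope zone of the sigmoid so no
  # head begins with a near-dead gradient
  head_start <- function(map, value) {
    rg <- config$map_ranges[[map]]
    stats::qlogis(min(max((value - rg[1]) / (rg[2] - rg[1]), 0.10), 0.90))
  }
  params <- list(enc1 = make_encoder(), enc2 = make_encoder(),
                 dec = list(t1 = make_decoder(head_start("t1", 900)),
                            t2 = make_decoder(head_start("t2", 90)),
                            pd = make_decoder(head_start("pd",
                              0.1 * diff(config$map_ranges$pd)))))
  structure(list(params = params, config = config,
                 n_params = tree_sum(length, params),
                 history = NULL),
            class = "synth_model")
}

#' Pixel-wise max fusion of two latent tensors
#'
#' Element-wise maximum; commutative and idempotent. Used to merge the two
#' encoder representations.
#'
#' @param a,b numeric arrays of identical shape.
#' @return Array of the same shape.
#' @export
fuse_latents <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape error: latent shapes differ")
  pmax(a, b)
}

#' Non-trainable physics layer
#'
#' Evaluates the ideal signal equation of `params` on predicted map arrays
#' — exactly the forward model of [simulate_contrast()], sharing its kernel
#' code — so the layer has zero trainable parameters and is differentiable
#' in the maps.
#'
#' @param pd,t1,t2 numeric arrays (any shared shape), nonnegative.
#' @param params an [acquisition_params()].
#' @return Array of predicted weighted intensities.
#' @export
physics_layer <- function(pd, t1, t2, params) {
  if (params$sequence == "IR_SE")
    ir_se_signal(pd, t1, t2, params$te, params$tr, params$ti)
  else
    se_signal(pd, t1, t2, params$te, params$tr)
}

# Analytic gradients of the signal w.r.t. (pd, t1, t2); gs is dL/dS.
physics_layer_bwd <- function(gs, pd, t1, t2, params) {
  te <- params$te; tr <- params$tr
  B <- exp(-te / t2)
  if (params$sequence == "IR_SE") {
    ti <- params$ti
    ei <- exp(-ti / t1); er <- exp(-tr / t1)
    f <- 1 - 2 * ei + er
    A <- abs(f)
    dA_dt1 <- sign(f) * (-2 * ei * ti / t1^2 + er * tr / t1^2)
  } else {
    er <- exp(-tr / t1)
    A <- 1 - er
    dA_dt1 <- -er * tr / t1^2
  }
  list(gpd = gs * A * B,
       gt1 = gs * pd * B * dA_dt1,
       gt2 = gs * pd * A * B * te / t2^2)
}

# ---- forward / backward over a batch of slices --------------------------

# Forward through one encoder, keeping each layer's im2col workspace so
# the backward pass can reuse it.
encoder_fwd <- function(layers, x) {
  acts <- list(x)
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    fw <- .conv2d_fwd_ws(acts[[l]], layers[[l]]$W, layers[[l]]$b)
    caches[[l]] <- fw
    acts[[l + 1]] <- fw$y * (fw$y > 0)   # ReLU
  }
  list(acts = acts, caches = caches)
}

encoder_bwd <- function(layers, enc, ga) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    gz <- ga * (enc$acts[[l + 1]] > 0)
    bw <- .conv2d_bwd_ws(enc$caches[[l]]$xc, enc$caches[[l]]$xdim,
                         layers[[l]]$W, gz)
    grads[[l]] <- list(W = bw$gw, b = bw$gb)
    ga <- bw$gx
  }
  list(grads = grads, gx = ga)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full forward pass; returns maps, synthesized images and a cache for
# backprop. x1, x2: arrays (H, W, 1, N).
net_forward <- function(model, x1, x2) {
  p <- model$params; cfg <- model$config
  e1 <- encoder_fwd(p$enc1, x1)
  e2 <- encoder_fwd(p$enc2, x2)
  a1 <- e1$acts[[length(e1$acts)]]; a2 <- e2$acts[[length(e2$acts)]]
  fused <- fuse_latents(a1, a2)
  maps <- list(); cache_dec <- list()
  for (m in c("t1", "t2", "pd")) {
    d <- p$dec[[m]]
    fh <- .conv2d_fwd_ws(fused, d$h$W, d$h$b)
    ah <- fh$y * (fh$y > 0)
    fo <- .conv2d_fwd_ws(ah, d$out$W, d$out$b)
    s <- sigmoid(fo$y)
    rg <- cfg$map_ranges[[m]]
    maps[[m]] <- rg[1] + (rg[2] - rg[1]) * s
    cache_dec[[m]] <- list(fh = fh, ah = ah, fo = fo, s = s)
  }
  synth <- lapply(cfg$loss_contrasts, function(cn)
    physics_layer(maps$pd, maps$t1, maps$t2, cfg$protocol[[cn]]))
  names(synth) <- cfg$loss_contrasts
  list(maps = maps, synth = synth,
       cache = list(e1 = e1, e2 = e2, a1 = a1, a2 = a2, fused = fused,
                    dec = cache_dec))
}

# L1 loss over all pixels of all images in the batch (Eq-style average of
# per-image MAEs; images share one pixel count so the two readings agree).
net_loss <- function(synth, targets) {
  tot <- 0
  for (cn in names(synth)) tot <- tot + mean(abs(synth[[cn]] - targets[[cn]]))
  tot / length(synth)
}

net_backward <- function(model, fw, targets) {
  p <- model$params; cfg <- model$config
  K <- length(cfg$loss_contrasts)
  gmap <- list(t1 = 0, t2 = 0, pd = 0)
  for (cn in cfg$loss_contrasts) {
    s <- fw$synth[[cn]]
    gs <- sign(s - targets[[cn]]) / (length(s) * K)
    pb <- physics_layer_bwd(gs, fw$maps$pd, fw$maps$t1, fw$maps$t2,
                            cfg$protocol[[cn]])
    gmap$pd <- gmap$pd + pb$gpd
    gmap$t1 <- gmap$t1 + pb$gt1
    gmap$t2 <- gmap$t2 + pb$gt2
  }
  gfused <- 0
  dec_grads <- list()
  for (m in c("t1", "t2", "pd")) {
    d <- p$dec[[m]]; cd <- fw$cache$dec[[m]]
    rg <- cfg$map_ranges[[m]]
    gzo <- gmap[[m]] * (rg[2] - rg[1]) * cd$s * (1 - cd$s)
    bw_out <- .conv2d_bwd_ws(cd$fo$xc, cd$fo$xdim, d$out$W, gzo)
    gah <- bw_out$gx * (cd$fh$y > 0)
    bw_h <- .conv2d_bwd_ws(cd$fh$xc, cd$fh$xdim, d$h$W, gah)
    dec_grads[[m]] <- list(h = list(W = bw_h$gw, b = bw_h$gb),
                           out = list(W = bw_out$gw, b = bw_out$gb))
    gfused <- gfused + bw_h$gx
  }
  # max-fusion subgradient: ties routed to the first encoder
  take1 <- fw$cache$a1 >= fw$cache$a2
  g1 <- gfused * take1
  g2 <- gfused * !take1
  b1 <- encoder_bwd(p$enc1, fw$cache$e1, g1)
  b2 <- encoder_bwd(p$enc2, fw$cache$e2, g2)
  list(enc1 = b1$grads, enc2 = b2$grads, dec = dec_grads)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) tree_map2(function(a, b) list(m = a * 0, v = a * 0),
                                        params, params)

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_leaf <- function(p_g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * p_g$g
    st$v <- beta2 * st$v + (1 - beta2) * p_g$g^2
    mh <- st$m / (1 - beta1^t); vh <- st$v / (1 - beta2^t)
    list(p = p_g$p - lr * mh / (sqrt(vh) + eps), st = st)
  }
  walk <- function(p, g, st) {
    if (is.list(p) && is.null(p$W) && !is.numeric(p)) {
      out <- mapply(walk, p, g, st, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), st = lapply(out, `[[`, "st")))
    }
    if (is.list(p)) {   # a conv layer {W, b}
      out <- mapply(function(pp, gg, ss) step_leaf(list(p = pp, g = gg), ss),
                    p, g, st, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), st = lapply(out, `[[`, "st")))
    }
    step_leaf(list(p = p, g = g), st)
  }
  walk(params, grads, state)
}

# ---- dataset assembly ----------------------------------------------------

# Axial slices of the requested contrasts for one record, in the input
# space the config asks for (reference-normalized or raw).
record_slices <- function(record, contrasts, normalize = TRUE) {
  imgs <- if (normalize) normalize_record(record, contrasts)
          else record$weighted[contrasts]
  nz <- dim(record$labels)[3]
  lapply(seq_len(nz), function(z)
    lapply(imgs, function(w) w$intensities[, , z]))
}

stack_batch <- function(slice_list, contrast) {
  H <- nrow(slice_list[[1]][[contrast]]); W <- ncol(slice_list[[1]][[contrast]])
  arr <- array(0, c(H, W, 1, length(slice_list)))
  for (i in seq_along(slice_list)) arr[, , 1, i] <- slice_list[[i]][[contrast]]
  arr
}

eval_loss_on <- function(model, slices, chunk = 32) {
  cfg <- model$config
  tot <- 0; n <- 0
  for (start in seq(1, length(slices), by = chunk)) {
    sl <- slices[start:min(length(slices), start + chunk - 1)]
    x1 <- stack_batch(sl, cfg$input_contrasts[1])
    x2 <- stack_batch(sl, cfg$input_contrasts[2])
    fw <- net_forward(model, x1, x2)
    targets <- lapply(cfg$loss_contrasts, function(cn) stack_batch(sl, cn))
    names(targets) <- cfg$loss_contrasts
    tot <- tot + net_loss(fw$synth, targets) * length(sl)
    n <- n + length(sl)
  }
  tot / n
}

#' Train the synthesis network self-supervised
#'
#' Optimizes the batch synthesis loss (average MAE between acquired and
#' physics-synthesized images) with Adam. Subjects are split about 80/20
#' into training and early-stopping validation; the epoch with the lowest
#' validation loss is kept. Only weighted images are read — relaxometry
#' ground truth never enters this function.
#'
#' @param records list of `subject_record`s with acquired weighted images.
#' @param config a [synth_config()].
#' @param verbose print per-epoch losses.
#' @return A `synth_model` with `$history` (per-epoch train/validation
#'   loss) and `$split` (subject ids of the train and validation sets).
#' @export
train_self_supervised <- function(records, config, verbose = FALSE) {
  needed <- unique(c(config$input_contrasts, config$loss_contrasts))
  for (r in records)
    if (!all(needed %in% names(r$weighted)))
      stop("data error: subject missing a required contrast")
  sp <- split_train_val(length(records), config$val_fraction, config$seed)
  tr_ix <- sp$train; val_ix <- sp$validation

  tr_slices <- unlist(lapply(records[tr_ix], record_slices, contrasts = needed,
                             normalize = config$normalize_inputs),
                      recursive = FALSE)
  va_slices <- unlist(lapply(records[val_ix], record_slices, contrasts = needed,
                             normalize = config$normalize_inputs),
                      recursive = FALSE)

  model <- build_network(config)
  state <- adam_init(model$params)
  t_step <- 0
  best <- list(loss = Inf, params = model$params, epoch = 0)
  hist <- data.frame(epoch = integer(), train_loss = double(),
                     val_loss = double())
  for (epoch in seq_len(config$max_epochs)) {
    ixs <- sample(length(tr_slices))
    ep_loss <- 0; n_b <- 0
    for (start in seq(1, length(ixs), by = config$batch_size)) {
      bix <- ixs[start:min(length(ixs), start + config$batch_size - 1)]
      sl <- tr_slices[bix]
      x1 <- stack_batch(sl, config$input_contrasts[1])
      x2 <- stack_batch(sl, config$input_contrasts[2])
      targets <- lapply(config$loss_contrasts, function(cn) stack_batch(sl, cn))
      names(targets) <- config$loss_contrasts
      fw <- net_forward(model, x1, x2)
      loss <- net_loss(fw$synth, targets)
      grads <- net_backward(model, fw, targets)
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(tree_sum(function(g) sum(g^2), grads))
        if (gnorm > config$clip_norm)
          grads <- tree_map2(function(g, .) g * (config$clip_norm / gnorm),
                             grads, grads)
      }
      t_step <- t_step + 1
      upd <- adam_step(model$params, grads, state, config$learning_rate, t_step)
      model$params <- upd$p; state <- upd$st
      ep_loss <- ep_loss + loss; n_b <- n_b + 1
    }
    val_loss <- eval_loss_on(model, va_slices)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n_b,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / n_b, val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
    if (epoch - best$epoch >= config$early_stop_patience) break
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$split <- list(train = vapply(records[tr_ix], `[[`, "", "subject_id"),
                      validation = vapply(records[val_ix], `[[`, "", "subject_id"))
  model
}

# Seeded train / early-stopping-validation split over n subjects
# (about (1 - val_fraction) / val_fraction, e.g. 18/5 out of 23).
split_train_val <- function(n, val_fraction, seed) {
  n_val <- max(1L, round(val_fraction * n))
  if (n - n_val < 1)
    stop("data error: cohort smaller than train+validation split")
  set.seed(seed)
  ord <- sample(n)
  list(train = sort(ord[-seq_len(n_val)]),
       validation = sort(ord[seq_len(n_val)]))
}

#' Leave-one-out fold plan
#'
#' The per-fold subject assignment used by [leave_one_out_synthesize()]:
#' one fold per subject, in which that subject is the test case and the
#' remaining subjects are split about 80/20 into training and
#' early-stopping validation — e.g. 18/5/1 for a 24-subject cohort. The
#' same seeded split code runs inside training, so this plan is an exact
#' audit of the fold hygiene.
#'
#' @param ids character vector of subject ids.
#' @param config a [synth_config()] (its seed and `val_fraction` are used).
#' @return List of folds, each with `test`, `train`, `validation` id sets.
#' @export
loo_fold_plan <- function(ids, config) {
  lapply(seq_along(ids), function(k) {
    rest <- ids[-k]
    sp <- split_train_val(length(rest), config$val_fraction, config$seed + k)
    list(test = ids[k], train = rest[sp$train],
         validation = rest[sp$validation])
  })
}

#' Predict relaxometry maps for one subject
#'
#' Slice-wise inference stacked back into volumes. Inputs must be the
#' reference-normalized weighted images used in training (a range check
#' rejects raw-intensity input); outputs are clipped to the configured
#' physical ranges by construction of the map activation.
#'
#' @param model a trained `synth_model`.
#' @param input_volumes named list of [weighted_image()] covering the
#'   config's input contrasts.
#' @return A [relaxometry_maps()] object.
#' @export
predict_maps <- function(model, input_volumes) {
  cfg <- model$config
  ins <- lapply(cfg$input_contrasts, function(cn) {
    w <- input_volumes[[cn]]
    if (is.null(w)) stop("input error: missing input contrast ", cn)
    w
  })
  fg <- ins[[1]]$intensities[ins[[1]]$mask]
  if (length(fg) && stats::median(fg) > 10)
    stop("input error: intensities look unnormalized (median foreground > 10)")
  dims <- dim(ins[[1]]$intensities)
  out <- list(t1 = array(0, dims), t2 = array(0, dims), pd = array(0, dims))
  for (start in seq(1, dims[3], by = cfg$batch_size)) {
    zix <- start:min(dims[3], start + cfg$batch_size - 1)
    x1 <- array(ins[[1]]$intensities[, , zix], c(dims[1], dims[2], 1, length(zix)))
    x2 <- array(ins[[2]]$intensities[, , zix], c(dims[1], dims[2], 1, length(zix)))
    fw <- net_forward(model, x1, x2)
    for (m in c("t1", "t2", "pd"))
      out[[m]][, , zix] <- fw$maps[[m]][, , 1, ]
  }
  mask <- ins[[1]]$mask | ins[[2]]$mask
  relaxometry_maps(out$t1, out$t2, out$pd, mask)
}

#' Synthesize the target contrast for one subject
#'
#' [predict_maps()] followed by the physics forward model at the target
#' contrast's acquisition parameters.
#'
#' @inheritParams predict_maps
#' @return A [weighted_image()] of the target contrast.
#' @export
synthesize_target <- function(model, input_volumes) {
  maps <- predict_maps(model, input_volumes)
  simulate_contrast(maps, model$config$target_contrast, model$config$protocol)
}

#' Leave-one-out synthesis over a cohort
#'
#' For each subject, a model is trained with that subject excluded (the
#' remaining subjects split about 80/20 into training and early-stopping
#' validation) and the held-out subject's target contrast is synthesized by
#' its own fold's model only.
#'
#' @param records list of `subject_record`s (>= 4).
#' @param config a [synth_config()].
#' @param verbose print fold progress.
#' @return A list with `synth` (named list: subject id -> synthesized
#'   [weighted_image()]), `maps` (predicted [relaxometry_maps()]), and
#'   `folds` (per-fold id sets for hygiene audits).
#' @export
leave_one_out_synthesize <- function(records, config, verbose = FALSE) {
  if (length(records) < 4) stop("data error: need at least 4 subjects")
  ids <- vapply(records, `[[`, "", "subject_id")
  synth <- list(); maps <- list(); folds <- list()
  for (k in seq_along(records)) {
    fold_cfg <- config
    fold_cfg$seed <- config$seed + k
    model <- train_self_supervised(records[-k], fold_cfg)
    test_in <- if (config$normalize_inputs)
      normalize_record(records[[k]], config$input_contrasts)
    else records[[k]]$weighted[config$input_contrasts]
    pm <- predict_maps(model, test_in)
    sy <- simulate_contrast(pm, config$target_contrast, config$protocol)
    synth[[ids[k]]] <- sy
    maps[[ids[k]]] <- pm
    folds[[k]] <- list(test = ids[k], train = model$split$train,
                       validation = model$split$validation)
    if (verbose) message("fold ", k, "/", length(records), " done")
  }
  list(synth = synth, maps = maps, folds = folds)
}
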