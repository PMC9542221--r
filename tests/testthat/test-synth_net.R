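test_that("latent max fusion is idempotent, commutative and element-wise", {
  a <- array(c(1, -2, 0, 4), c(2, 2, 1, 1))
  b <- array(c(0, 5, -1, 4), c(2, 2, 1, 1))
  expect_identical(fuse_latents(a, a), a)
  expect_identical(fuse_latents(a, b), fuse_latents(b, a))
  expect_equal(as.vector(fuse_latents(a, b)), c(1, 5, 0, 4))
  expect_error(fuse_latents(a, array(0, c(2, 2, 1, 2))), "shape error")
})

test_that("network construction is deterministic and counts parameters analytically", {
  cfg <- synth_config(width = 6, depth = 2, seed = 9)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$params, m2$params)

  # analytic count for this topology: two encoders (1->C, C->C), three
  # decoders (C->C hidden + C->1 head), all 3x3 kernels with biases
  C <- 6
  enc <- (9 * 1 * C + C) + (9 * C * C + C)
  dec <- (9 * C * C + C) + (9 * C * 1 + 1)
  expect_equal(m1$n_params, 2 * enc + 3 * dec)

  wide <- build_network(synth_config(width = 12, depth = 2, seed = 9))
  expect_gt(wide$n_params, m1$n_params)
})

test_that("a forward pass maps two slices to three finite map slices of the same shape", {
  cfg <- synth_config(width = 4, depth = 2, seed = 2)
  model <- build_network(cfg)
  x <- array(0, c(16, 16, 1, 3))
  fw <- synthrs:::net_forward(model, x, x)
  for (m in c("t1", "t2", "pd")) {
    expect_identical(dim(fw$maps[[m]]), c(16L, 16L, 1L, 3L))
    expect_true(all(is.finite(fw$maps[[m]])))
    rg <- cfg$map_ranges[[m]]
    expect_true(all(fw$maps[[m]] >= rg[1] & fw$maps[[m]] <= rg[2]))
  }
})

test_that("the physics layer is the forward model and has no trainable parameters", {
  rec <- generate_phantom(7, c(24, 24, 6))
  for (cn in c("T1w", "T2w", "FLAIR")) {
    p <- default_protocol()[[cn]]
    via_layer <- physics_layer(rec$maps$pd, rec$maps$t1, rec$maps$t2, p)
    via_model <- simulate_contrast(rec$maps, cn)$intensities
    expect_identical(via_layer, via_model)   # same kernel code path
  }

  # the layer adds nothing to the trainable parameter count
  cfg <- synth_config(width = 4, seed = 1)
  expect_equal(build_network(cfg)$n_params,
               synthrs:::tree_sum(length, build_network(cfg)$params))
})

test_that("physics-layer gradients match finite differences", {
  pd <- 0.8; t1 <- 1200; t2 <- 140
  for (p in list(default_protocol()$T2w, default_protocol()$FLAIR)) {
    gr <- synthrs:::physics_layer_bwd(1, pd, t1, t2, p)
    num <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
    expect_equal(gr$gpd, num(function(v) physics_layer(v, t1, t2, p), pd, 1e-6),
                 tolerance = 1e-6)
    expect_equal(gr$gt1, num(function(v) physics_layer(pd, v, t2, p), t1, 1e-3),
                 tolerance = 1e-6)
    expect_equal(gr$gt2, num(function(v) physics_layer(pd, t1, v, p), t2, 1e-3),
                 tolerance = 1e-6)
    # linearity in PD: the PD gradient is exactly the relaxation factor
    expect_equal(gr$gpd, physics_layer(1, t1, t2, p), tolerance = 1e-12)
  }
})

test_that("whole-network gradients match finite differences on a tiny problem", {
  cfg <- synth_config(width = 3, depth = 1, seed = 5, batch_size = 2)
  model <- build_network(cfg)
  set.seed(8)
  x1 <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  x2 <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  targets <- lapply(cfg$loss_contrasts, function(cn)
    array(runif(8 * 8 * 1 * 2, 0, 0.4), c(8, 8, 1, 2)))
  names(targets) <- cfg$loss_contrasts
  fw <- synthrs:::net_forward(model, x1, x2)
  grads <- synthrs:::net_backward(model, fw, targets)

  loss_at <- function(params) {
    m <- model; m$params <- params
    synthrs:::net_loss(synthrs:::net_forward(m, x1, x2)$synth, targets)
  }
  h <- 1e-6
  fd_check <- function(get_grad, perturb) {
    p_plus <- perturb(model$params, h)
    fd <- (loss_at(p_plus) - loss_at(model$params)) / h
    expect_equal(get_grad(grads), fd, tolerance = 1e-3)
  }
  fd_check(function(g) g$enc1[[1]]$W[7],
           function(p, h) { p$enc1[[1]]$W[7] <- p$enc1[[1]]$W[7] + h; p })
  fd_check(function(g) g$enc2[[1]]$b[2],
           function(p, h) { p$enc2[[1]]$b[2] <- p$enc2[[1]]$b[2] + h; p })
  fd_check(function(g) g$dec$t2$h$W[11],
           function(p, h) { p$dec$t2$h$W[11] <- p$dec$t2$h$W[11] + h; p })
  fd_check(function(g) g$dec$pd$out$b[1],
           function(p, h) { p$dec$pd$out$b[1] <- p$dec$pd$out$b[1] + h; p })
})

test_that("self-supervised smoke training lowers validation loss, reproducibly", {
  co <- small_noiseless_cohort()
  cfg <- synth_config(width = 6, depth = 2, max_epochs = 8, batch_size = 8,
                      learning_rate = 2e-3, seed = 3,
                      normalize_inputs = FALSE, early_stop_patience = 8)
  m <- train_self_supervised(co$records, cfg)
  expect_lt(tail(m$history$val_loss, 1), m$history$val_loss[1])
  expect_lte(nrow(m$history), cfg$max_epochs)

  # best-epoch validation loss is the minimum of the curve
  expect_equal(min(m$history$val_loss), m$history$val_loss[m$best_epoch])

  # bitwise reproducibility of the loss curve (deterministic kernels)
  m2 <- train_self_supervised(co$records, cfg)
  expect_identical(m$history, m2$history)

  # the loss is zero when the predicted maps are perfect
  rec <- co$records[[1]]
  syn <- lapply(cfg$loss_contrasts, function(cn)
    simulate_contrast(rec$maps, cn)$intensities)
  names(syn) <- cfg$loss_contrasts
  acq <- lapply(cfg$loss_contrasts, function(cn) rec$weighted[[cn]]$intensities)
  names(acq) <- cfg$loss_contrasts
  expect_equal(synthrs:::net_loss(syn, acq), 0)
})

test_that("training never reads relaxometry ground truth", {
  co <- small_noiseless_cohort()
  cfg <- synth_config(width = 3, depth = 1, max_epochs = 1, batch_size = 16,
                      seed = 4, normalize_inputs = FALSE)
  stripped <- lapply(co$records, function(r) {
    r$maps$t1[] <- NA_real_; r$maps$t2[] <- NA_real_; r$maps$pd[] <- NA_real_
    r
  })
  expect_error(m <- train_self_supervised(stripped, cfg), NA)
  expect_true(all(is.finite(m$history$train_loss)))
})

test_that("leave-one-out folds are disjoint with 18/5/1 splits at n = 24", {
  ids <- sprintf("subj_%03d", 1:24)
  cfg <- synth_config(seed = 6)
  plan <- loo_fold_plan(ids, cfg)
  expect_length(plan, 24)
  for (k in seq_along(plan)) {
    f <- plan[[k]]
    expect_identical(f$test, ids[k])
    expect_length(f$train, 18)
    expect_length(f$validation, 5)
    expect_false(f$test %in% c(f$train, f$validation))
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$test, f$train, f$validation), ids)
  }
})

test_that("LOO synthesis excludes each test subject from its own fold", {
  co <- small_noiseless_cohort()
  cfg <- synth_config(width = 3, depth = 1, max_epochs = 2, batch_size = 16,
                      learning_rate = 2e-3, seed = 12, normalize_inputs = FALSE)
  loo <- leave_one_out_synthesize(co$records[1:4], cfg)
  expect_length(loo$folds, 4)
  for (f in loo$folds) {
    expect_false(f$test %in% c(f$train, f$validation))
    expect_length(c(f$train, f$validation), 3)
  }
  # plan and executed folds agree (same seeded split code)
  plan <- loo_fold_plan(vapply(co$records[1:4], `[[`, "", "subject_id"), cfg)
  for (k in 1:4) {
    expect_setequal(loo$folds[[k]]$train, plan[[k]]$train)
    expect_setequal(loo$folds[[k]]$validation, plan[[k]]$validation)
  }
  expect_s3_class(loo$synth[[1]], "weighted_image")
})

test_that("predicted maps are physical and background maps to near-zero PD", {
  co <- small_noiseless_cohort()
  cfg <- synth_config(width = 6, depth = 2, max_epochs = 12, batch_size = 8,
                      learning_rate = 2e-3, seed = 13, normalize_inputs = FALSE,
                      early_stop_patience = 12)
  m <- train_self_supervised(co$records[1:5], cfg)
  rec <- co$records[[6]]
  pm <- predict_maps(m, rec$weighted[cfg$input_contrasts])
  expect_true(all(pm$t1 >= 0) && all(pm$t2 >= 0) && all(pm$pd >= 0))
  bg <- !rec$maps$mask
  expect_lt(mean(pm$pd[bg]), 0.15)

  # raw-intensity input triggers the unnormalized-input guard
  bad <- rec$weighted[cfg$input_contrasts]
  bad[[1]]$intensities <- bad[[1]]$intensities * 1000
  expect_error(predict_maps(m, bad), "unnormalized")
})
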