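#' Experiment I: all channels acquired
#'
#' Tests the full-channel radiomic system with every contrast acquired
#' (in the synthetic world: the Rician-noised forward simulations).
#'
#' @param rs_full a `trained_rs` trained on the 4-contrast feature table.
#' @param test_table 4-contrast feature table of the test cohort.
#' @return [evaluate_rs()] result.
#' @export
run_experiment_I <- function(rs_full, test_table) {
  evaluate_rs(rs_full, test_table)
}

#' Experiment II: one channel replaced by its synthesized version
#'
#' The same trained system is tested with the replaced contrast's features
#' recomputed from the leave-one-out synthesized volume; the other three
#' channels are untouched. A hard contamination audit verifies that no
#' test subject entered the training or early-stopping split of its own
#' synthesis fold.
#'
#' @param rs_full the full-channel `trained_rs` (trained on acquired
#'   images only).
#' @param test_records test-cohort `subject_record`s.
#' @param loo result of [leave_one_out_synthesize()] on the test cohort.
#' @param replaced_contrast `"FLAIR"` or `"T2w"`.
#' @param threshold_days,censor_policy label policy.
#' @return [evaluate_rs()] result.
#' @export
run_experiment_II <- function(rs_full, test_records, loo, replaced_contrast,
                              threshold_days = 480, censor_policy = "exclude") {
  for (fold in loo$folds)
    if (fold$test %in% c(fold$train, fold$validation))
      stop("contamination error: subject ", fold$test,
           " overlaps its own synthesis fold")
  rec_by_id <- stats::setNames(test_records,
                               vapply(test_records, `[[`, "", "subject_id"))
  overrides <- lapply(names(loo$synth), function(id) {
    # the synthesized volume goes through the same reference normalization
    # as any pipeline image, removing residual scale offsets of its fold
    rec <- rec_by_id[[id]]
    w <- normalize_by_reference(loo$synth[[id]], rec$labels,
                                rec$hemisphere_of_tumor)
    stats::setNames(list(w), replaced_contrast)
  })
  names(overrides) <- names(loo$synth)
  tbl <- build_feature_table(test_records,
                             survival = survival_table(test_records),
                             threshold_days = threshold_days,
                             censor_policy = censor_policy,
                             overrides = overrides)
  evaluate_rs(rs_full, tbl)
}

#' Experiment III: one channel absent
#'
#' Tests a system trained from scratch on three input channels only; its
#' recipe must not reference the dropped contrast.
#'
#' @param rs_reduced a `trained_rs` trained on the 3-contrast table.
#' @param test_records test-cohort records.
#' @param dropped_contrast the absent channel.
#' @param threshold_days,censor_policy label policy.
#' @return [evaluate_rs()] result.
#' @export
run_experiment_III <- function(rs_reduced, test_records, dropped_contrast,
                               threshold_days = 480, censor_policy = "exclude") {
  tags <- parse_feature_name(rs_reduced$features)$contrast
  if (dropped_contrast %in% tags)
    stop("recipe error: reduced model selects features of the dropped contrast")
  contrasts <- setdiff(c("T1w", "T2w", "FLAIR", "T1w_c"), dropped_contrast)
  tbl <- build_feature_table(test_records, contrast_set = contrasts,
                             survival = survival_table(test_records),
                             threshold_days = threshold_days,
                             censor_policy = censor_policy)
  evaluate_rs(rs_reduced, tbl)
}

#' Agreement between two experiments' predicted probabilities
#'
#' Pairs the per-subject survival probabilities of two experiment runs by
#' subject id (intersection only) and reports the identity-regression R²,
#' the absolute-agreement ICC, and summaries of the paired differences
#' (median, IQR) for boxplot reconstruction.
#'
#' @param eval_a,eval_b [evaluate_rs()] results.
#' @return List with `r2`, `icc`, `median_diff`, `iqr_diff`, `differences`,
#'   `n`.
#' @export
compare_probabilities <- function(eval_a, eval_b) {
  common <- intersect(eval_a$subject_id, eval_b$subject_id)
  if (length(common) < 3) stop("domain error: fewer than 3 shared subjects")
  pa <- eval_a$probabilities[match(common, eval_a$subject_id)]
  pb <- eval_b$probabilities[match(common, eval_b$subject_id)]
  d <- pb - pa
  list(r2 = r2_identity(pa, pb),
       icc = icc_agreement(cbind(pa, pb)),
       median_diff = stats::median(d),
       iqr_diff = stats::IQR(d),
       differences = stats::setNames(d, common),
       n = length(common))
}

#' Run the full replacement study on synthetic cohorts
#'
#' End-to-end orchestration: generate a training and a test cohort, train
#' the full and reduced radiomic systems on acquired images of the
#' training cohort, run leave-one-out self-supervised synthesis on the
#' test cohort, and evaluate Experiments I (all acquired), II (one channel
#' synthesized) and III (channel absent), with probability-agreement
#' statistics for the pairs I-II and I-III and image-quality metrics of
#' the synthesized volumes. One master seed fans out to every stage.
#'
#' @param seed master seed.
#' @param n_train,n_test cohort sizes (training cohort feeds the radiomic
#'   system; the test cohort feeds leave-one-out synthesis + evaluation).
#' @param grid_shape phantom grid.
#' @param replaced_contrast `"FLAIR"` or `"T2w"`.
#' @param noise_sigma acquisition noise.
#' @param radius_range whole-tumor radius range passed to the cohort spec;
#'   on coarse grids larger lesions keep the tumor ROIs populated.
#' @param families,k_values,outer_folds,inner_folds radiomic-system
#'   selection settings.
#' @param synth_width,synth_epochs,synth_lr,synth_patience,synth_batch
#'   synthesis network settings (learning rate and batch defaults suit
#'   desk-scale runs of tens of epochs over tens of slices).
#' @param threshold_days survival threshold.
#' @return An `experiment_report` list.
#' @export
run_replacement_study <- function(seed = 1, n_train = 120, n_test = 24,
                                  grid_shape = c(64, 64, 32),
                                  replaced_contrast = "FLAIR",
                                  noise_sigma = 0.02,
                                  radius_range = c(0.30, 0.55),
                                  families = default_model_grid(),
                                  k_values = c(8, 16),
                                  outer_folds = 5, inner_folds = 10,
                                  synth_width = 8, synth_epochs = 40,
                                  synth_lr = 2e-3, synth_patience = 40,
                                  synth_batch = 8,
                                  threshold_days = 480) {
  stopifnot(replaced_contrast %in% c("FLAIR", "T2w"))
  set.seed(seed)
  seeds <- sample.int(2^31 - 10L, 4)

  train_cohort <- generate_cohort(cohort_spec(
    n_subjects = n_train, grid_shape = grid_shape, seed = seeds[1],
    noise_sigma = noise_sigma, radius_range = radius_range,
    threshold_days = threshold_days))
  test_cohort <- generate_cohort(cohort_spec(
    n_subjects = n_test, grid_shape = grid_shape, seed = seeds[2],
    noise_sigma = noise_sigma, radius_range = radius_range,
    threshold_days = threshold_days))

  all4 <- c("T1w", "T2w", "FLAIR", "T1w_c")
  train_tbl4 <- build_feature_table(train_cohort$records, all4,
                                    threshold_days = threshold_days)
  train_tbl3 <- build_feature_table(train_cohort$records,
                                    setdiff(all4, replaced_contrast),
                                    threshold_days = threshold_days)
  rs_full <- nested_cv_select(train_tbl4, families = families,
                              k_values = k_values, outer_folds = outer_folds,
                              inner_folds = inner_folds, seed = seeds[3])
  rs_reduced <- nested_cv_select(train_tbl3, families = families,
                                 k_values = k_values, outer_folds = outer_folds,
                                 inner_folds = inner_folds, seed = seeds[3])

  inputs <- if (replaced_contrast == "FLAIR") c("T1w", "T2w") else c("T1w", "FLAIR")
  scfg <- synth_config(input_contrasts = inputs,
                       target_contrast = replaced_contrast,
                       width = synth_width, max_epochs = synth_epochs,
                       learning_rate = synth_lr, batch_size = synth_batch,
                       early_stop_patience = synth_patience,
                       seed = seeds[4])
  loo <- leave_one_out_synthesize(test_cohort$records, scfg)

  test_tbl4 <- build_feature_table(test_cohort$records, all4,
                                   threshold_days = threshold_days)
  ex1 <- run_experiment_I(rs_full, test_tbl4)
  ex2 <- run_experiment_II(rs_full, test_cohort$records, loo,
                           replaced_contrast, threshold_days)
  ex3 <- run_experiment_III(rs_reduced, test_cohort$records,
                            replaced_contrast, threshold_days)

  # quality of the synthesized volumes vs. the acquired (normalized) ones
  qual <- do.call(rbind, lapply(test_cohort$records, function(rec) {
    acq <- normalize_record(rec, replaced_contrast)[[replaced_contrast]]
    syn <- loo$synth[[rec$subject_id]]
    dom <- foreground_box(list(acq, syn))
    data.frame(subject_id = rec$subject_id,
               mse = mse_metric(acq, syn, dom),
               ssim = ssim_metric(acq, syn, dom),
               psnr = psnr_metric(acq, syn, dom))
  }))
  structure(list(
    seed = seed, replaced_contrast = replaced_contrast,
    rs_full = rs_full, rs_reduced = rs_reduced,
    experiment_I = ex1, experiment_II = ex2, experiment_III = ex3,
    agreement_I_II = compare_probabilities(ex1, ex2),
    agreement_I_III = compare_probabilities(ex1, ex3),
    quality = summarize_cohort(qual),
    loo_folds = loo$folds,
    threshold_days = threshold_days,
    sizes = c(n_train = n_train, n_test = n_test)
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Replacement study (replaced contrast:", x$replaced_contrast, ")\n")
  for (e in c("experiment_I", "experiment_II", "experiment_III")) {
    m <- x[[e]]$metrics
    cat(sprintf("  %-15s AUC %.3f  acc %.3f  prec %.3f  rec %.3f  F1 %.3f\n",
                e, m["auc"], m["accuracy"], m["precision"], m["recall"],
                m["f1"]))
  }
  cat(sprintf("  agreement I-II : R2 %.3f  ICC %.3f\n",
              x$agreement_I_II$r2, x$agreement_I_II$icc))
  cat(sprintf("  agreement I-III: R2 %.3f  ICC %.3f\n",
              x$agreement_I_III$r2, x$agreement_I_III$icc))
  q <- x$quality$summary
  for (i in seq_len(nrow(q)))
    cat(sprintf("  synth %-5s mean %.4f (sd %.4f)\n", q$metric[i], q$mean[i],
                q$sd[i]))
  invisible(x)
}

#' Relaxometry parameter-recovery experiment
#'
#' Trains the self-supervised network on noiseless phantoms in raw
#' intensity space (where the maps are physically identifiable from the
#' three reconstructed contrasts) and measures, on held-out phantoms, the
#' median relative foreground error of each predicted map and the SSIM
#' between the synthesized target volume and its ideal forward simulation.
#'
#' @param seed master seed.
#' @param n_train,n_holdout phantom counts.
#' @param grid_shape phantom grid (default 64 x 64 x 16).
#' @param target_contrast synthesized contrast.
#' @param width,epochs,lr,batch_size network settings for the desk-scale
#'   run; small batches give more optimization steps per pass over the few
#'   training slices.
#' @return List with `errors` (per-holdout data frame of median relative
#'   T1/T2/PD errors), `ssim` (per-holdout SSIM of synthesized vs. ideal
#'   target), and the trained `model`.
#' @export
parameter_recovery_experiment <- function(seed = 1, n_train = 10,
                                          n_holdout = 2,
                                          grid_shape = c(64, 64, 16),
                                          target_contrast = "FLAIR",
                                          width = 8, epochs = 40, lr = 2e-3,
                                          batch_size = 2) {
  spec <- cohort_spec(n_subjects = n_train + n_holdout,
                      grid_shape = grid_shape, seed = seed,
                      noise_sigma = 0, cyst_max = 0)
  cohort <- generate_cohort(spec)
  inputs <- if (target_contrast == "FLAIR") c("T1w", "T2w") else c("T1w", "FLAIR")
  cfg <- synth_config(input_contrasts = inputs,
                      target_contrast = target_contrast,
                      width = width, max_epochs = epochs,
                      learning_rate = lr, batch_size = batch_size,
                      early_stop_patience = epochs,
                      seed = seed, normalize_inputs = FALSE,
                      loss_contrasts = unique(c(inputs, target_contrast)))
  train_rec <- cohort$records[seq_len(n_train)]
  hold_rec <- cohort$records[n_train + seq_len(n_holdout)]
  model <- train_self_supervised(train_rec, cfg)
  errors <- list(); ssims <- numeric(0)
  for (rec in hold_rec) {
    pm <- predict_maps(model, rec$weighted[inputs])
    fg <- rec$maps$mask
    rel_err <- function(map) {
      stats::median(abs(pm[[map]][fg] - rec$maps[[map]][fg]) /
                      rec$maps[[map]][fg])
    }
    errors[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id,
      t1 = rel_err("t1"), t2 = rel_err("t2"), pd = rel_err("pd"))
    syn <- simulate_contrast(pm, target_contrast, cfg$protocol)
    ideal <- rec$ideal[[target_contrast]]
    dom <- foreground_box(list(ideal, syn))
    ssims[rec$subject_id] <- ssim_metric(ideal, syn, dom)
  }
  list(errors = do.call(rbind, c(errors, list(make.row.names = FALSE))),
       ssim = ssims, model = model)
}

# ---- command-line entry --------------------------------------------------

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("usage error: unexpected argument ", a)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      out[[key]] <- argv[i + 1]; i <- i + 2
    }
  }
  out
}

write_manifest <- function(dir, config) {
  manifest <- list(package = "synthrs",
                   version = as.character(utils::packageVersion("synthrs")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   threshold_days = config$threshold_days %||% 480,
                   config = config)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(manifest["config"], tmp, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate-cohort` (write a phantom cohort to disk) and
#' `run-experiments` (full replacement study; writes metrics, per-subject
#' probabilities, probability differences and a run manifest as JSON/CSV).
#'
#' @param argv character vector, e.g.
#'   `c("run-experiments", "--replace", "flair", "--seed", "7", "--out", "run1")`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: synthrs <simulate-cohort|run-experiments> [--options]",
    "  simulate-cohort --n N --seed S --out DIR [--grid 64,64,32] [--noise 0.02]",
    "  run-experiments --replace flair|t2w --seed S --out DIR",
    "      [--n-train N] [--n-test N] [--grid X,Y,Z] [--epochs E]",
    sep = "\n")
  if (length(argv) < 1) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  args <- tryCatch(parse_cli_args(argv[-1]), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(args)) { message(usage); return(invisible(2L)) }
  getnum <- function(key, default) as.numeric(args[[key]] %||% default)
  status <- tryCatch({
    if (cmd == "simulate-cohort") {
      out <- args$out %||% stop("usage error: --out required")
      grid <- as.integer(strsplit(as.character(args$grid %||% "64,64,32"),
                                  ",")[[1]])
      spec <- cohort_spec(n_subjects = getnum("n", 24), grid_shape = grid,
                          seed = getnum("seed", 1),
                          noise_sigma = getnum("noise", 0.02))
      cohort <- generate_cohort(spec)
      write_cohort(cohort, out)
      write_manifest(out, list(command = "simulate-cohort",
                               n = spec$n_subjects, seed = spec$seed,
                               grid = grid, threshold_days = spec$threshold_days))
      0L
    } else if (cmd == "run-experiments") {
      out <- args$out %||% stop("usage error: --out required")
      replace <- toupper(as.character(args$replace %||%
                                        stop("usage error: --replace required")))
      replace <- if (replace == "T2W") "T2w" else "FLAIR"
      grid <- as.integer(strsplit(as.character(args$grid %||% "32,32,12"),
                                  ",")[[1]])
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      rep <- run_replacement_study(
        seed = getnum("seed", 1), n_train = getnum("n-train", 60),
        n_test = getnum("n-test", 12), grid_shape = grid,
        replaced_contrast = replace, synth_epochs = getnum("epochs", 25))
      metrics <- do.call(rbind, lapply(
        c("experiment_I", "experiment_II", "experiment_III"),
        function(e) data.frame(experiment = e, t(rep[[e]]$metrics))))
      utils::write.csv(metrics, file.path(out, "classifier_metrics.csv"),
                       row.names = FALSE)
      probs <- data.frame(subject_id = rep$experiment_I$subject_id,
                          prob_I = rep$experiment_I$probabilities,
                          prob_II = rep$experiment_II$probabilities,
                          prob_III = rep$experiment_III$probabilities)
      utils::write.csv(probs, file.path(out, "probabilities.csv"),
                       row.names = FALSE)
      agr <- list(I_II = rep$agreement_I_II[c("r2", "icc", "median_diff",
                                              "iqr_diff", "n")],
                  I_III = rep$agreement_I_III[c("r2", "icc", "median_diff",
                                                "iqr_diff", "n")],
                  quality = rep$quality$summary)
      jsonlite::write_json(agr, file.path(out, "agreement.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      write_manifest(out, list(command = "run-experiments",
                               replace = replace, seed = getnum("seed", 1),
                               grid = grid, n_train = getnum("n-train", 60),
                               n_test = getnum("n-test", 12),
                               threshold_days = rep$threshold_days))
      print(rep)
      0L
    } else {
      message(usage); 2L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
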