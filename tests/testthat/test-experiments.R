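# A tiny trained RS + test cohort shared across experiment tests.
experiment_fixture <- function() {
  fixture("experiment_fixture", function() {
    train <- generate_cohort(cohort_spec(n_subjects = 30,
                                         grid_shape = c(24, 24, 8),
                                         seed = 71, noise_sigma = 0.01))
    test <- generate_cohort(cohort_spec(n_subjects = 8,
                                        grid_shape = c(24, 24, 8),
                                        seed = 72, noise_sigma = 0.01))
    all4 <- c("T1w", "T2w", "FLAIR", "T1w_c")
    tbl4 <- build_feature_table(train$records, all4)
    tbl3 <- build_feature_table(train$records, setdiff(all4, "FLAIR"))
    rs_full <- nested_cv_select(tbl4, families = "lr", k_values = 4,
                                outer_folds = 3, inner_folds = 3, seed = 5)
    rs_red <- nested_cv_select(tbl3, families = "lr", k_values = 4,
                               outer_folds = 3, inner_folds = 3, seed = 5)
    list(train = train, test = test, rs_full = rs_full, rs_red = rs_red,
         test_tbl4 = build_feature_table(test$records, all4))
  })
}

test_that("replacing a channel with its own acquired copy reproduces Experiment I", {
  fx <- experiment_fixture()
  ex1 <- run_experiment_I(fx$rs_full, fx$test_tbl4)

  identity_loo <- list(
    synth = stats::setNames(
      lapply(fx$test$records, function(r)
        synthrs:::normalize_record(r, "FLAIR")$FLAIR),
      vapply(fx$test$records, `[[`, "", "subject_id")),
    folds = lapply(vapply(fx$test$records, `[[`, "", "subject_id"),
                   function(id) list(test = id, train = character(),
                                     validation = character())))
  ex2 <- run_experiment_II(fx$rs_full, fx$test$records, identity_loo, "FLAIR")
  expect_equal(ex2$probabilities, ex1$probabilities, tolerance = 1e-12)
  expect_equal(ex2$metrics, ex1$metrics, tolerance = 1e-12)
})

test_that("channels other than the replaced one are bit-identical between I and II", {
  fx <- experiment_fixture()
  rec <- fx$test$records[[1]]
  perturbed <- synthrs:::normalize_record(rec, "FLAIR")$FLAIR
  perturbed$intensities <- perturbed$intensities * 0.9
  ov <- list(); ov[[rec$subject_id]] <- list(FLAIR = perturbed)
  tbl_repl <- build_feature_table(fx$test$records, overrides = ov)
  parsed <- parse_feature_name(setdiff(names(tbl_repl),
                                       c("subject_id", "label")))
  same_cols <- names(tbl_repl)[c(FALSE, FALSE, parsed$contrast != "FLAIR")]
  flair_cols <- names(tbl_repl)[c(FALSE, FALSE, parsed$contrast == "FLAIR")]
  base <- fx$test_tbl4
  expect_identical(tbl_repl[, same_cols], base[, same_cols])
  r1 <- which(tbl_repl$subject_id == rec$subject_id)
  expect_false(isTRUE(all.equal(unlist(tbl_repl[r1, flair_cols]),
                                unlist(base[r1, flair_cols]))))
})

test_that("synthesis-fold contamination is a hard failure", {
  fx <- experiment_fixture()
  bad_loo <- list(
    synth = stats::setNames(
      lapply(fx$test$records, function(r)
        synthrs:::normalize_record(r, "FLAIR")$FLAIR),
      vapply(fx$test$records, `[[`, "", "subject_id")),
    folds = list(list(test = fx$test$records[[1]]$subject_id,
                      train = fx$test$records[[1]]$subject_id,
                      validation = character())))
  expect_error(run_experiment_II(fx$rs_full, fx$test$records, bad_loo, "FLAIR"),
               "contamination error")
})

test_that("the reduced system never references the dropped contrast", {
  fx <- experiment_fixture()
  tags <- parse_feature_name(fx$rs_red$features)$contrast
  expect_false("FLAIR" %in% tags)
  ex3 <- run_experiment_III(fx$rs_red, fx$test$records, "FLAIR")
  expect_length(ex3$probabilities, nrow(fx$test_tbl4))

  # a model that selects a dropped-contrast feature is rejected
  poisoned <- fx$rs_red
  poisoned$features <- c(poisoned$features, "FLAIR.ED.glcm.entropy")
  expect_error(run_experiment_III(poisoned, fx$test$records, "FLAIR"),
               "recipe error")
})

test_that("probability agreement of an experiment with itself is exact", {
  fx <- experiment_fixture()
  ex1 <- run_experiment_I(fx$rs_full, fx$test_tbl4)
  agr <- compare_probabilities(ex1, ex1)
  expect_equal(agr$r2, 1)
  expect_equal(agr$icc, 1, tolerance = 1e-9)
  expect_true(all(agr$differences == 0))
  expect_equal(agr$median_diff, 0)
})

test_that("null-effect cohorts give chance-level classification", {
  null_spec <- cohort_spec(n_subjects = 60, grid_shape = c(24, 24, 8),
                           seed = 81, effect_volume = 0, effect_ratio = 0,
                           effect_texture = 0, censor_rate = 0,
                           noise_sigma = 0.01)
  co <- generate_cohort(null_spec)
  tbl <- build_feature_table(co$records)
  rs <- nested_cv_select(tbl, families = "lr", k_values = 4,
                         outer_folds = 5, inner_folds = 5, seed = 9)
  aucs <- vapply(rs$cv, `[[`, 0, "outer_auc")
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})

test_that("the command-line interface validates arguments and writes a manifest", {
  expect_identical(cli_main(character()), 2L)
  expect_identical(cli_main(c("no-such-command")), 2L)
  expect_identical(suppressMessages(cli_main(c("run-experiments", "--seed", "1"))), 1L)

  out <- file.path(tempdir(), "cli_cohort")
  status <- cli_main(c("simulate-cohort", "--n", "2", "--seed", "3",
                       "--out", out, "--grid", "16,16,6"))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "survival.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$threshold_days, 480)
  expect_true(nzchar(man$config_hash))
  surv <- read.csv(file.path(out, "survival.csv"))
  expect_equal(nrow(surv), 2)
  unlink(out, recursive = TRUE)
})
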