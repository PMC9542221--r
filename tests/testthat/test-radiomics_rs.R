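test_that("reference normalization is an exact fixed point on contralateral WM", {
  rec <- fixture("norm_rec", function() {
    simulate_subject_images(generate_phantom(61, c(32, 32, 10)),
                            noise_sigma = 0.02, seed = 61)
  })
  w <- normalize_by_reference(rec$weighted$T1w, rec$labels,
                              rec$hemisphere_of_tumor)
  nx <- dim(rec$labels)[1]
  xs <- slice.index(rec$labels, 1)
  contra <- if (rec$hemisphere_of_tumor == "left") xs > nx / 2 else xs <= nx / 2
  ref <- rec$labels == 1 & contra & w$mask
  expect_equal(mean(w$intensities[ref]), 1, tolerance = 1e-9)

  # scaling: doubling the reference mean halves every intensity
  half <- rec$weighted$T1w
  half$intensities <- half$intensities * 2
  w2 <- normalize_by_reference(half, rec$labels, rec$hemisphere_of_tumor)
  expect_equal(w2$intensities, w$intensities, tolerance = 1e-12)

  # reference voxels all sit in the opposite hemisphere
  tum_x <- which(array(rec$labels %in% 4:6, dim(rec$labels)),
                 arr.ind = TRUE)[, 1]
  ref_x <- which(ref, arr.ind = TRUE)[, 1]
  if (rec$hemisphere_of_tumor == "left") {
    expect_true(all(tum_x <= nx / 2) && all(ref_x > nx / 2))
  } else {
    expect_true(all(tum_x > nx / 2) && all(ref_x <= nx / 2))
  }
})

test_that("first-order features degenerate correctly on constant ROIs", {
  x <- rep(2.5, 40)
  fo <- synthrs:::firstorder_features(x)
  expect_equal(unname(fo["sd"]), 0)
  expect_equal(unname(fo["entropy"]), 0)
  expect_equal(unname(fo["mean"]), 2.5)
  P <- synthrs:::glcm_matrix(array(1, c(4, 4, 2)), array(TRUE, c(4, 4, 2)))
  gl <- synthrs:::glcm_features(P)
  expect_equal(unname(gl["energy"]), 1)
  expect_equal(unname(gl["entropy"]), 0)
  expect_equal(unname(gl["contrast"]), 0)
})

test_that("GLCM contrast on a 2-level checkerboard matches brute-force tallies", {
  # 4x4 checkerboard, single slice, offset (1,0,0) only
  v <- array(0, c(4, 4, 1))
  v[, , 1] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  m <- array(TRUE, c(4, 4, 1))
  P <- synthrs:::glcm_matrix(v, m, levels = 2, offsets = list(c(1, 0, 0)))
  # brute force: count ordered level pairs along +x, symmetrized
  tally <- matrix(0, 2, 2)
  for (j in 1:4) for (i in 1:3) {
    a <- v[i, j, 1] + 1; b <- v[i + 1, j, 1] + 1
    tally[a, b] <- tally[a, b] + 1
    tally[b, a] <- tally[b, a] + 1
  }
  expect_equal(unclass(P), tally / sum(tally), ignore_attr = TRUE)
  # every neighbor pair alternates levels: contrast = 1, homogeneity = 1/2
  gl <- synthrs:::glcm_features(P)
  expect_equal(unname(gl["contrast"]), 1)
  expect_equal(unname(gl["homogeneity"]), 0.5)
})

test_that("sphericity is near 1 for a ball and lower for an elongated ellipsoid", {
  dims <- c(24, 24, 24)
  cx <- 12.5
  co <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  ball <- array((co$x - cx)^2 + (co$y - cx)^2 + (co$z - cx)^2 <= 8^2, dims)
  egg <- array(((co$x - cx) / 10.5)^2 + ((co$y - cx) / 3.5)^2 +
                 ((co$z - cx) / 3.5)^2 <= 1, dims)
  sb <- synthrs:::shape_features(ball)
  se <- synthrs:::shape_features(egg)
  # voxelized surface overestimates the analytic area, so sphericity < 1
  expect_gt(sb[["sphericity"]], 0.6)
  expect_lt(sb[["sphericity"]], 1.05)
  expect_gt(sb[["sphericity"]], se[["sphericity"]])
  expect_equal(sb[["volume"]], sum(ball))
})

test_that("feature rows are deterministic, fully named, and channel-tagged", {
  rec <- fixture("norm_rec", function() {
    simulate_subject_images(generate_phantom(61, c(32, 32, 10)),
                            noise_sigma = 0.02, seed = 61)
  })
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  parsed <- parse_feature_name(names(f1))
  expect_setequal(unique(parsed$contrast), c("T1w", "T2w", "FLAIR", "T1w_c", "mask"))
  expect_setequal(unique(parsed$roi), c("ET", "NET", "ED", "TC", "WT"))
  expect_gte(length(f1), 250)
  # features of populated ROIs are finite; empty-ROI features are NA
  # (flagged for training-fold median imputation)
  roi_n <- vapply(unique(parsed$roi), function(r)
    sum(synthrs:::roi_mask(rec$labels, r)), 0)
  populated <- parsed$roi %in% names(roi_n)[roi_n >= 2]
  expect_true(all(is.finite(f1[populated & parsed$contrast != "mask"])))
  if (any(roi_n < 2))
    expect_true(all(is.na(f1[!populated])))
})

test_that("mRMR picks the informative feature first and shuns duplicates", {
  set.seed(2)
  n <- 80
  y <- rep(0:1, each = n / 2)
  tbl <- data.frame(
    a_noise1 = rnorm(n), b_signal = y + rnorm(n, 0, 0.05),
    c_noise2 = rnorm(n), d_copy = NA, e_noise3 = rnorm(n))
  tbl$d_copy <- tbl$b_signal          # duplicate of the signal column
  sel <- select_features_mrmr(tbl, y, k = 3)
  expect_equal(sel[1], "b_signal")
  expect_false(sel[2] == "d_copy")    # maximal redundancy with the first pick
  expect_length(select_features_mrmr(tbl, y, k = 5), 5)
  expect_error(select_features_mrmr(tbl, y, k = 0), "parameter error")
})

test_that("survival labeling applies the strict 480-day rule and censor policy", {
  surv <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                     survival_days = c(481, 480, 300, 700, 479),
                     censored = c(0, 0, 1, 1, 0))
  labs <- label_subjects(surv)
  expect_equal(labs$label, c(1L, 0L, NA_integer_, 1L, 0L))
  expect_equal(labs$excluded, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  labs2 <- label_subjects(surv, censor_policy = "label_low")
  expect_equal(labs2$label, c(1L, 0L, 0L, 1L, 0L))
  expect_error(label_subjects(data.frame(subject_id = "a", survival_days = 100,
                                         censored = 1)), "label error")
})

test_that("classifier metrics match a hand-built confusion matrix", {
  # TP=3, FP=1, FN=1, TN=3 at threshold 0.5
  probs <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  tbl <- data.frame(subject_id = letters[1:8], label = y,
                    `T1w.WT.firstorder.mean` = probs, check.names = FALSE)
  model <- structure(list(family = "identity", features = "T1w.WT.firstorder.mean",
                          medians = c(`T1w.WT.firstorder.mean` = 0.5),
                          threshold = 0.5,
                          model = list(family = "identity")),
                     class = "trained_rs")
  # identity "family" for the oracle: probability = feature value
  local_predict <- function(model, X) X[[1]]
  testthat::with_mocked_bindings(
    predict_family = local_predict, .package = "synthrs",
    {
      ev <- evaluate_rs(model, tbl)
      prec1 <- 3 / 4; rec1 <- 3 / 4
      prec0 <- 3 / 4; rec0 <- 3 / 4
      expect_equal(unname(ev$metrics["precision"]), (prec1 + prec0) / 2)
      expect_equal(unname(ev$metrics["recall"]), (rec1 + rec0) / 2)
      expect_equal(unname(ev$metrics["f1"]), 3 / 4)
      expect_equal(unname(ev$metrics["accuracy"]), 6 / 8)
      # probabilities equal to labels give all-ones metrics
      tbl2 <- tbl; tbl2[[3]] <- y
      ev2 <- evaluate_rs(model, tbl2)
      expect_true(all(ev2$metrics == 1))
    })
})

test_that("macro-averaged metrics are invariant to a joint class swap", {
  set.seed(14)
  tbl <- toy_feature_table(n = 60, p = 5, planted = TRUE, seed = 14)
  rs <- nested_cv_select(tbl, families = "lr", k_values = 2,
                         outer_folds = 3, inner_folds = 3, seed = 2)
  ev <- evaluate_rs(rs, tbl)
  swapped <- tbl
  swapped$label <- 1L - tbl$label
  swapped[["FLAIR.ED.glcm.planted"]] <- 1 - swapped[["FLAIR.ED.glcm.planted"]]
  rs_sw <- nested_cv_select(swapped, families = "lr", k_values = 2,
                            outer_folds = 3, inner_folds = 3, seed = 2)
  ev_sw <- evaluate_rs(rs_sw, swapped)
  for (m in c("accuracy", "precision", "recall", "f1"))
    expect_equal(unname(ev$metrics[m]), unname(ev_sw$metrics[m]),
                 tolerance = 0.15)
})

test_that("nested CV emits one candidate per outer fold and finds planted signal", {
  tbl <- toy_feature_table(n = 60, p = 10, planted = TRUE, seed = 3)
  rs <- nested_cv_select(tbl, families = c("lr", "xgb"), k_values = c(3, 5),
                         outer_folds = 4, inner_folds = 4, seed = 5)
  expect_length(rs$cv, 4)
  expect_true("FLAIR.ED.glcm.planted" %in% rs$features)
  expect_gte(rs$winner_outer_auc, 0.95)
  ev <- evaluate_rs(rs, tbl)
  expect_gte(unname(ev$metrics["auc"]), 0.95)

  # selection hygiene: each fold's candidate was chosen without its own rows
  for (cand in rs$cv) expect_true(all(c("family", "k", "outer_auc",
                                        "features") %in% names(cand)))
})

test_that("missing feature columns raise a schema error at evaluation", {
  tbl <- toy_feature_table(n = 40, p = 4, planted = TRUE, seed = 6)
  rs <- nested_cv_select(tbl, families = "lr", k_values = 2,
                         outer_folds = 3, inner_folds = 3, seed = 7)
  bad <- tbl[, setdiff(names(tbl), rs$features[1])]
  expect_error(evaluate_rs(rs, bad), "schema error")
})
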