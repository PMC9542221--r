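#' Normalize a weighted image by contralateral white matter
#'
#' Divides every intensity by the mean intensity over the white-matter
#' voxels of the hemisphere opposite the tumor, making that region's mean
#' exactly 1. This ratio normalization puts all contrasts of all subjects
#' on a common tissue-referenced scale and is the input space of both the
#' radiomic system and the synthesis network.
#'
#' @param image a [weighted_image()].
#' @param labels integer label volume (WM = 1).
#' @param tumor_hemisphere `"left"` or `"right"`; the reference region is
#'   the opposite half of the first axis.
#' @return The normalized [weighted_image()].
#' @export
normalize_by_reference <- function(image, labels, tumor_hemisphere) {
  stopifnot(inherits(image, "weighted_image"),
            tumor_hemisphere %in% c("left", "right"))
  nx <- dim(labels)[1]
  xs <- slice.index(labels, 1)
  contra <- if (tumor_hemisphere == "left") xs > nx / 2 else xs <= nx / 2
  ref <- labels == LABELS[["WM"]] & contra & image$mask
  if (!any(ref)) stop("normalization error: empty contralateral WM region")
  m <- mean(image$intensities[ref])
  if (m <= 0) stop("normalization error: nonpositive reference mean")
  weighted_image(image$intensities / m, image$contrast, image$params,
                 image$mask)
}

# Normalized images of one record for a set of contrasts (named list).
normalize_record <- function(record, contrasts = names(record$weighted)) {
  out <- lapply(contrasts, function(cn) {
    w <- record$weighted[[cn]]
    if (is.null(w)) stop("data error: contrast ", cn, " missing")
    normalize_by_reference(w, record$labels, record$hemisphere_of_tumor)
  })
  names(out) <- contrasts
  out
}

# ---- feature primitives --------------------------------------------------

roi_mask <- function(labels, roi) {
  switch(roi,
         ET = labels == LABELS[["ET"]],
         NET = labels == LABELS[["NET"]],
         ED = labels == LABELS[["ED"]],
         TC = labels == LABELS[["ET"]] | labels == LABELS[["NET"]],
         WT = labels >= LABELS[["ET"]],
         stop("unknown ROI ", roi))
}

firstorder_features <- function(x, nbins = 32) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, 9))
  rng <- range(x)
  if (diff(rng) > 0) {
    p <- tabulate(cut(x, seq(rng[1], rng[2], length.out = nbins + 1),
                      include.lowest = TRUE, labels = FALSE), nbins) / n
    ent <- -sum(ifelse(p > 0, p * log(p), 0))
  } else ent <- 0
  c(mean = mean(x), sd = stats::sd(x),
    skewness = if (stats::sd(x) > 0) e1071::skewness(x) else 0,
    kurtosis = if (stats::sd(x) > 0) e1071::kurtosis(x) else 0,
    energy = mean(x^2), entropy = ent,
    p10 = unname(stats::quantile(x, 0.10)),
    p50 = unname(stats::quantile(x, 0.50)),
    p90 = unname(stats::quantile(x, 0.90)))
}

# Gray-level co-occurrence matrix over the three axis-aligned unit offsets,
# symmetric, accumulated and normalized; equal-width quantization over the
# ROI's own intensity range.
glcm_matrix <- function(vol, mask, levels = 16,
                        offsets = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
  x <- vol[mask]
  rng <- range(x)
  lev <- array(0L, dim(vol))
  if (diff(rng) > 0) {
    q <- pmin(floor((vol - rng[1]) / diff(rng) * levels) + 1L, levels)
    lev[mask] <- q[mask]
  } else lev[mask] <- 1L
  d <- dim(vol)
  P <- matrix(0, levels, levels)
  for (off in offsets) {
    a_ix <- lapply(1:3, function(k)
      if (off[k] >= 0) seq_len(d[k] - off[k]) else (1 - off[k]):d[k])
    b_ix <- lapply(1:3, function(k) a_ix[[k]] + off[k])
    A <- lev[a_ix[[1]], a_ix[[2]], a_ix[[3]], drop = FALSE]
    B <- lev[b_ix[[1]], b_ix[[2]], b_ix[[3]], drop = FALSE]
    ok <- A > 0L & B > 0L
    if (!any(ok)) next
    av <- A[ok]; bv <- B[ok]
    tb <- matrix(tabulate((av - 1L) * levels + bv, levels * levels),
                 nrow = levels, ncol = levels)   # [b, a] counts
    P <- P + tb + t(tb)          # symmetric co-occurrence
  }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

glcm_features <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L); j <- t(i)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(seq_len(L) * pi_); mu_j <- sum(seq_len(L) * pj_)
  s_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  s_j <- sqrt(sum((seq_len(L) - mu_j)^2 * pj_))
  corr <- if (s_i > 0 && s_j > 0)
    sum(P * (i - mu_i) * (j - mu_j)) / (s_i * s_j) else 1
  c(contrast = sum(P * (i - j)^2),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = -sum(ifelse(P > 0, P * log(P), 0)))
}

shape_features <- function(mask) {
  V <- sum(mask)
  if (V == 0) return(c(volume = NA_real_, surface = NA_real_,
                       sphericity = NA_real_))
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  faces <- 0
  for (k in 1:3) for (s in c(-1, 1)) {
    sh <- pad
    ix <- lapply(1:3, function(a) seq_len(d[a] + 2))
    ix[[k]] <- pmin(pmax(ix[[k]] + s, 1), d[k] + 2)
    neigh <- pad[ix[[1]], ix[[2]], ix[[3]]]
    faces <- faces + sum(pad & !neigh)
  }
  c(volume = V, surface = faces,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / faces)
}

#' Extract the radiomic feature row of one subject
#'
#' For each (contrast, ROI) pair: nine first-order statistics of the
#' normalized intensities and five gray-level co-occurrence texture
#' features (16 levels, the three axis-aligned unit offsets, symmetric);
#' per ROI once: three shape features. Column names carry the full
#' provenance 4-tuple `contrast.ROI.family.feature` (shape features use the
#' contrast tag `mask`), which is what makes channel ablation and
#' channel-replacement audits possible. Deterministic; empty-ROI features
#' are `NA` and imputed downstream from training-fold medians.
#'
#' @param record a `subject_record`.
#' @param contrast_set contrast labels to extract from.
#' @param roi_set ROI labels among ET, NET, ED, TC (= ET+NET), WT (= TC+ED).
#' @param images optional named list of normalized [weighted_image()]s to
#'   use instead of normalizing `record$weighted` (used when a channel is
#'   replaced by its synthesized version).
#' @param glcm_levels,fo_bins quantization settings.
#' @return Named numeric vector (one feature-table row).
#' @export
extract_features <- function(record, contrast_set = c("T1w", "T2w", "FLAIR", "T1w_c"),
                             roi_set = c("ET", "NET", "ED", "TC", "WT"),
                             images = NULL, glcm_levels = 16, fo_bins = 32) {
  if (is.null(images)) images <- normalize_record(record, contrast_set)
  out <- c()
  for (cn in contrast_set) {
    vol <- images[[cn]]$intensities
    for (roi in roi_set) {
      m <- roi_mask(record$labels, roi)
      if (sum(m) >= 2) {
        fo <- firstorder_features(vol[m], fo_bins)
        gl <- glcm_features(glcm_matrix(vol, m, glcm_levels))
      } else {
        fo <- rep(NA_real_, 9)
        names(fo) <- c("mean", "sd", "skewness", "kurtosis", "energy",
                       "entropy", "p10", "p50", "p90")
        gl <- rep(NA_real_, 5)
        names(gl) <- c("contrast", "correlation", "energy", "homogeneity",
                       "entropy")
      }
      names(fo) <- paste(cn, roi, "firstorder", names(fo), sep = ".")
      names(gl) <- paste(cn, roi, "glcm", names(gl), sep = ".")
      out <- c(out, fo, gl)
    }
  }
  for (roi in roi_set) {
    sh <- shape_features(roi_mask(record$labels, roi))
    names(sh) <- paste("mask", roi, "shape", names(sh), sep = ".")
    out <- c(out, sh)
  }
  out
}

#' Parse a feature name into its provenance 4-tuple
#' @param names character vector of feature-column names.
#' @return data frame with columns contrast, roi, family, feature.
#' @export
parse_feature_name <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  stopifnot(all(lengths(parts) == 4))
  data.frame(contrast = vapply(parts, `[`, "", 1),
             roi = vapply(parts, `[`, "", 2),
             family = vapply(parts, `[`, "", 3),
             feature = vapply(parts, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Dichotomize survival at a threshold
#'
#' Label 1 iff survival strictly exceeds the threshold (480 days = 16
#' months by default). Censored subjects whose follow-up is shorter than
#' the threshold carry no usable label and are excluded under the default
#' policy; censored subjects followed beyond the threshold are known
#' survivors and labeled 1.
#'
#' @param survival data frame with columns `subject_id`, `survival_days`,
#'   `censored`.
#' @param threshold_days dichotomization threshold.
#' @param censor_policy `"exclude"` (default) or `"label_low"` (count
#'   short-censored subjects as label 0, a stress-test policy).
#' @return data frame with columns `subject_id`, `label` (0/1 or NA for
#'   excluded), `excluded`.
#' @export
label_subjects <- function(survival, threshold_days = 480,
                           censor_policy = c("exclude", "label_low")) {
  censor_policy <- match.arg(censor_policy)
  lab <- ifelse(survival$survival_days > threshold_days, 1L, 0L)
  short_cens <- survival$censored == 1 & survival$survival_days <= threshold_days
  excluded <- short_cens & censor_policy == "exclude"
  lab[excluded] <- NA_integer_
  if (all(is.na(lab))) stop("label error: empty labeled set")
  data.frame(subject_id = survival$subject_id, label = lab,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Build the cohort feature table
#'
#' @param records list of `subject_record`s.
#' @param contrast_set contrasts to extract.
#' @param survival survival table; default rebuilt from the records.
#' @param threshold_days,censor_policy passed to [label_subjects()].
#' @param overrides optional named list (subject id -> named list of
#'   [weighted_image()]) replacing specific normalized channels, e.g. by a
#'   synthesized version, at feature-extraction time only.
#' @return data frame: `subject_id`, `label`, then one numeric column per
#'   feature; excluded subjects are dropped.
#' @export
build_feature_table <- function(records, contrast_set = c("T1w", "T2w", "FLAIR", "T1w_c"),
                                survival = survival_table(records),
                                threshold_days = 480,
                                censor_policy = "exclude",
                                overrides = NULL) {
  labs <- label_subjects(survival, threshold_days, censor_policy)
  rows <- list()
  for (rec in records) {
    lab <- labs$label[labs$subject_id == rec$subject_id]
    if (length(lab) != 1 || is.na(lab)) next
    imgs <- normalize_record(rec, contrast_set)
    ov <- overrides[[rec$subject_id]]
    for (cn in names(ov)) imgs[[cn]] <- ov[[cn]]
    rows[[rec$subject_id]] <- c(label = lab, extract_features(rec, contrast_set,
                                                              images = imgs))
  }
  X <- do.call(rbind, rows)
  data.frame(subject_id = names(rows), label = as.integer(X[, "label"]),
             X[, -1, drop = FALSE], check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label", "cohort"))
}

# ---- mutual information and mRMR ----------------------------------------

# Equal-frequency discretization into at most `bins` levels.
discretize_ef <- function(x, bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, br, include.lowest = TRUE, labels = FALSE)
}

mutual_info_disc <- function(a, b) {
  a <- as.integer(a); a <- a - min(a) + 1L
  b <- as.integer(b); b <- b - min(b) + 1L
  na <- max(a); nb <- max(b)
  p <- matrix(tabulate((a - 1L) * nb + b, na * nb), nrow = nb, ncol = na)
  p <- p / sum(p)
  e <- outer(rowSums(p), colSums(p))
  sum(ifelse(p > 0, p * log(p / e), 0))
}

#' Greedy mRMR feature selection
#'
#' Maximum-relevance minimum-redundancy: the first feature maximizes mutual
#' information with the label (after equal-frequency discretization into 8
#' bins); each subsequent pick maximizes relevance minus the mean MI with
#' the already-selected set. Ties break by column-name lexicographic order
#' (C collation), making the ranking deterministic.
#'
#' @param table data frame or matrix of numeric features (columns named).
#' @param labels binary vector (0/1).
#' @param k number of features to return (the greedy order is nested, so
#'   the first j names are the mRMR-j selection).
#' @param bins discretization bins.
#' @return Character vector of k ordered feature names.
#' @export
select_features_mrmr <- function(table, labels, k, bins = 8) {
  if (k <= 0) stop("parameter error: k must be positive")
  cols <- colnames(table)
  k <- min(k, length(cols))
  med <- vapply(cols, function(cn) stats::median(table[[cn]], na.rm = TRUE), 0)
  disc <- lapply(cols, function(cn) {
    x <- table[[cn]]
    x[is.na(x)] <- med[cn]
    discretize_ef(x, bins)
  })
  names(disc) <- cols
  y <- as.integer(labels)
  rel <- vapply(cols, function(cn) mutual_info_disc(disc[[cn]], y), 0)
  ord <- order(-rel, cols, method = "radix")   # lexicographic tie-break
  selected <- cols[ord[1]]
  red_sum <- vapply(cols, function(cn)
    mutual_info_disc(disc[[cn]], disc[[selected]]), 0)
  while (length(selected) < k) {
    cand <- setdiff(cols, selected)
    score <- rel[cand] - red_sum[cand] / length(selected)
    best <- cand[order(-score, cand, method = "radix")[1]]
    selected <- c(selected, best)
    if (length(selected) < k)
      red_sum <- red_sum + vapply(cols, function(cn)
        mutual_info_disc(disc[[cn]], disc[[best]]), 0)
  }
  selected
}

# ---- classifier families -------------------------------------------------

#' Default model grid for the nested cross-validation
#'
#' Five classifier families: logistic regression, linear SVM with
#' probability calibration, gradient-boosted trees, random forest, and
#' k-nearest neighbors.
#'
#' @return Character vector of family names.
#' @export
default_model_grid <- function() c("lr", "svm", "xgb", "rf", "knn")

fit_family <- function(family, X, y, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd); sg[sg == 0] <- 1
  Xs <- scale(X, mu, sg)
  fit <- switch(family,
    lr = suppressWarnings(stats::glm.fit(cbind(1, Xs), y,
                                         family = stats::binomial())),
    svm = e1071::svm(Xs, factor(y, levels = 0:1), kernel = "linear",
                     cost = 1, probability = TRUE, scale = FALSE),
    xgb = {
      set.seed(seed)
      xgboost::xgboost(x = X, y = factor(y, levels = 0:1), nrounds = 40,
                       max_depth = 3, learning_rate = 0.3,
                       nthreads = 1, verbosity = 0)
    },
    rf = ranger::ranger(x = X, y = factor(y, levels = 0:1),
                        probability = TRUE, num.trees = 200,
                        seed = seed, num.threads = 1),
    knn = list(X = Xs, y = y, k = 7),
    stop("unknown family ", family))
  list(family = family, fit = fit, mu = mu, sg = sg)
}

predict_family <- function(model, X) {
  X <- as.matrix(X)
  Xs <- scale(X, model$mu, model$sg)
  switch(model$family,
    lr = {
      co <- model$fit$coefficients
      co[is.na(co)] <- 0          # dropped collinear columns contribute 0
      stats::plogis(drop(cbind(1, Xs) %*% co))
    },
    svm = {
      pr <- stats::predict(model$fit, Xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    xgb = stats::predict(model$fit, X),
    rf = stats::predict(model$fit, data = X, num.threads = 1)$predictions[, "1"],
    knn = {
      pred <- class::knn(model$fit$X, Xs, factor(model$fit$y, levels = 0:1),
                         k = model$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    })
}

# Stratified fold assignment; every fold gets members of each class when
# the class has at least `nfolds` members.
make_folds <- function(y, nfolds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(nfolds), length(ix))
  }
  fold
}

impute_medians <- function(X, med = NULL) {
  if (is.null(med))
    med <- vapply(X, function(col) stats::median(col, na.rm = TRUE), 0)
  for (j in seq_along(X)) {
    nas <- is.na(X[[j]])
    if (any(nas)) X[[j]][nas] <- med[j]
  }
  list(X = X, med = med)
}

brier_score <- function(prob, y) mean((prob - as.numeric(y))^2)

auc_score <- function(prob, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Nested cross-validated model selection
#'
#' The full selection protocol: stratified outer folds (default 5); within
#' each outer fold, feature selection (mRMR) is re-run on that fold's
#' training portion only, and a stratified inner cross-validation (default
#' 10-fold) scores every (family, feature-count) candidate by mean Brier
#' loss; the inner winner becomes that outer fold's candidate and is scored
#' by AUC on the outer validation part. The candidate with the best outer
#' AUC wins, and its recipe (family + feature count) is refit on all rows,
#' with feature selection re-run on all rows.
#'
#' @param table feature table from [build_feature_table()].
#' @param labels optional label vector; default the table's `label` column.
#' @param families classifier families, see [default_model_grid()].
#' @param k_values candidate numbers of selected features.
#' @param outer_folds,inner_folds fold counts; reduced with a warning when
#'   a class is too small to stratify.
#' @param seed seed controlling fold assignment and stochastic learners.
#' @return An object of class `trained_rs`: final fitted model, ordered
#'   selected features, the per-outer-fold CV records and the winner's
#'   outer AUC.
#' @export
nested_cv_select <- function(table, labels = NULL,
                             families = default_model_grid(),
                             k_values = c(8, 16),
                             outer_folds = 5, inner_folds = 10, seed = 1) {
  if (is.null(labels)) labels <- table$label
  y <- as.integer(labels)
  feats <- feature_columns(table)
  Xall <- table[, feats, drop = FALSE]
  n_min <- min(table(y))
  if (n_min < outer_folds) {
    outer_folds <- max(2L, n_min)
    warning("class too small: outer folds reduced to ", outer_folds)
  }
  fold <- make_folds(y, outer_folds, seed)
  candidates <- list()
  for (f in seq_len(outer_folds)) {
    tr <- fold != f; va <- fold == f
    imp <- impute_medians(Xall[tr, , drop = FALSE])
    sel_all <- select_features_mrmr(imp$X, y[tr], max(k_values))
    inner_n_min <- min(table(y[tr]))
    inf <- inner_folds
    if (inner_n_min < inf) {
      inf <- max(2L, inner_n_min)
      warning("class too small: inner folds reduced to ", inf)
    }
    ifold <- make_folds(y[tr], inf, seed + f)
    ytr <- y[tr]
    best <- NULL
    for (fam in families) for (k in k_values) {
      sel <- sel_all[seq_len(min(k, length(sel_all)))]
      briers <- numeric(inf)
      for (g in seq_len(inf)) {
        itr <- ifold != g; iva <- ifold == g
        Xi <- imp$X[itr, sel, drop = FALSE]
        m <- fit_family(fam, Xi, ytr[itr], seed = seed + f * 100 + g)
        p <- predict_family(m, imp$X[iva, sel, drop = FALSE])
        briers[g] <- brier_score(p, ytr[iva])
      }
      rec <- list(family = fam, k = k, brier = mean(briers))
      if (is.null(best) || rec$brier < best$brier ||
          (rec$brier == best$brier && rec$k < best$k)) best <- rec
    }
    sel <- sel_all[seq_len(min(best$k, length(sel_all)))]
    m <- fit_family(best$family, imp$X[, sel, drop = FALSE], ytr,
                    seed = seed + f)
    Xva <- impute_medians(Xall[va, sel, drop = FALSE], imp$med[sel])$X
    pva <- predict_family(m, Xva)
    candidates[[f]] <- list(fold = f, family = best$family, k = best$k,
                            inner_brier = best$brier,
                            outer_auc = auc_score(pva, y[va]),
                            features = sel)
  }
  aucs <- vapply(candidates, `[[`, 0, "outer_auc")
  winner <- candidates[[order(-aucs,
                              vapply(candidates, `[[`, 0, "inner_brier"))[1]]]
  imp <- impute_medians(Xall)
  sel <- select_features_mrmr(imp$X, y, winner$k)
  final <- fit_family(winner$family, imp$X[, sel, drop = FALSE], y, seed = seed)
  structure(list(family = winner$family, k = winner$k, features = sel,
                 model = final, medians = imp$med[sel], threshold = 0.5,
                 contrast_set = unique(parse_feature_name(feats)$contrast),
                 cv = candidates, winner_outer_auc = winner$outer_auc,
                 seed = seed),
            class = "trained_rs")
}

#' Evaluate a trained radiomic system on a test table
#'
#' Predicted probabilities, AUC, and threshold metrics (accuracy plus
#' macro-averaged precision, recall and F1 over the two classes) at the
#' model's decision threshold (0.5).
#'
#' @param model a `trained_rs`.
#' @param test_table feature table with the model's selected feature
#'   columns and a `label` column.
#' @return List with `metrics` (named numeric vector), `probabilities`,
#'   `subject_id`, `label`.
#' @export
evaluate_rs <- function(model, test_table) {
  missing_cols <- setdiff(model$features, names(test_table))
  if (length(missing_cols))
    stop("schema error: test table lacks columns ",
         paste(missing_cols, collapse = ", "))
  X <- impute_medians(test_table[, model$features, drop = FALSE],
                      model$medians)$X
  prob <- unname(predict_family(model$model, X))
  y <- as.integer(test_table$label)
  pred <- as.integer(prob > model$threshold)
  if (length(unique(prob)) == 1)
    warning("degenerate probabilities: all predictions equal")
  per_class <- function(cl) {
    tp <- sum(pred == cl & y == cl); fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  m0 <- per_class(0); m1 <- per_class(1)
  metrics <- c(auc = auc_score(prob, y),
               accuracy = mean(pred == y),
               precision = (m0["precision"] + m1["precision"]) / 2,
               recall = (m0["recall"] + m1["recall"]) / 2,
               f1 = (m0["f1"] + m1["f1"]) / 2)
  names(metrics) <- c("auc", "accuracy", "precision", "recall", "f1")
  list(metrics = metrics, probabilities = prob,
       subject_id = test_table$subject_id, label = y)
}
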