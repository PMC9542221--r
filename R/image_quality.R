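#' Smallest box containing the foreground
#'
#' Computes the minimal axis-aligned box (inclusive lower corner, exclusive
#' upper corner per axis) containing every nonzero voxel of one volume or of
#' the union of several, and a mask restricting that box to the domain of
#' the reference (acquired) volume. All quality metrics are evaluated on
#' this domain.
#'
#' @param volumes a numeric array, a [weighted_image()], or a list of them.
#' @return An object of class `evaluation_domain` with elements `lower`,
#'   `upper` (integer vectors) and `mask` (logical array on the full grid,
#'   TRUE inside the box where the first volume is nonzero).
#' @export
foreground_box <- function(volumes) {
  if (!is.list(volumes) || inherits(volumes, "weighted_image"))
    volumes <- list(volumes)
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "weighted_image")) v$intensities else v)
  fg <- Reduce(`|`, lapply(arrs, function(a) a != 0))
  if (!any(fg)) stop("domain error: all-zero volume has no foreground")
  idx <- which(fg, arr.ind = TRUE)
  if (is.null(dim(fg))) idx <- cbind(idx)   # 1-D edge case
  lower <- unname(apply(idx, 2, min))
  upper <- unname(apply(idx, 2, max)) + 1L
  box <- array(FALSE, dim = dim(fg))
  slices <- lapply(seq_along(lower), function(d) lower[d]:(upper[d] - 1L))
  box[as.matrix(expand.grid(slices))] <- TRUE
  mask <- box & (arrs[[1]] != 0)
  structure(list(lower = lower, upper = upper, mask = mask, box = box),
            class = "evaluation_domain")
}

domain_mask <- function(domain) {
  if (inherits(domain, "evaluation_domain")) domain$mask else domain
}

#' Mean squared error on an evaluation domain
#' @param a,b numeric arrays or [weighted_image()]s on a shared grid.
#' @param domain an [foreground_box()] result or a logical mask.
#' @return Scalar MSE.
#' @export
mse_metric <- function(a, b, domain) {
  a <- if (inherits(a, "weighted_image")) a$intensities else a
  b <- if (inherits(b, "weighted_image")) b$intensities else b
  m <- domain_mask(domain)
  if (!any(m)) stop("domain error: empty evaluation domain")
  mean((a[m] - b[m])^2)
}

#' Peak signal-to-noise ratio on an evaluation domain
#'
#' \eqn{PSNR = 10 \log_{10}(L^2 / MSE)} with data range L taken as the
#' maximum of the reference image `a` over the domain (the images have no
#' fixed bit depth after ratio normalization). Identical images give an
#' `Inf` sentinel with a warning.
#'
#' @inheritParams mse_metric
#' @param L data range; default max of `a` on the domain.
#' @return Scalar PSNR in dB (possibly `Inf`).
#' @export
psnr_metric <- function(a, b, domain, L = NULL) {
  av <- if (inherits(a, "weighted_image")) a$intensities else a
  m <- domain_mask(domain)
  if (is.null(L)) L <- max(av[m])
  mse <- mse_metric(a, b, domain)
  if (mse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(L^2 / mse)
}

# 1-D Gaussian window, normalized.
gauss_win <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable 2-D Gaussian filtering with edge-renormalization (filter weights
# falling outside the image are dropped and the kernel renormalized), so a
# constant image filters to itself exactly.
filt2_sep <- function(img, w) {
  k <- length(w); half <- (k - 1) / 2
  ones <- matrix(1, nrow(img), ncol(img))
  pass <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- m * 0
    for (j in seq_len(k)) {
      off <- j - 1 - half
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      if (along == 1) out[ok, ] <- out[ok, ] + w[j] * m[src[ok], ]
      else            out[, ok] <- out[, ok] + w[j] * m[, src[ok]]
    }
    out
  }
  num <- pass(pass(img, 1), 2)
  den <- pass(pass(ones, 1), 2)
  num / den
}

# Local SSIM map for one 2-D slice (standard stabilized form).
ssim_map_2d <- function(a, b, L, window = gauss_win()) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- filt2_sep(a, window); mu_b <- filt2_sep(b, window)
  s_aa <- filt2_sep(a * a, window) - mu_a^2
  s_bb <- filt2_sep(b * b, window) - mu_b^2
  s_ab <- filt2_sep(a * b, window) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2))
}

#' Structural similarity index on an evaluation domain
#'
#' Mean local SSIM with the standard Gaussian-weighted 11-pixel window and
#' stabilizers K1 = 0.01, K2 = 0.03, computed slice-wise on the third axis
#' over the evaluation box and averaged over domain voxels. Data range L
#' defaults to the maximum of either image over the domain, which keeps the
#' metric exactly symmetric. `ssim_metric(a, a, d)` is exactly 1.
#'
#' @inheritParams psnr_metric
#' @return Scalar SSIM in \[-1, 1\].
#' @export
ssim_metric <- function(a, b, domain, L = NULL) {
  av <- if (inherits(a, "weighted_image")) a$intensities else a
  bv <- if (inherits(b, "weighted_image")) b$intensities else b
  if (!identical(dim(av), dim(bv)))
    stop("grid error: images must share one grid shape")
  if (inherits(domain, "evaluation_domain")) {
    lo <- domain$lower; up <- domain$upper; m <- domain$mask
  } else {
    d <- foreground_box(list(domain + 0))   # mask given directly
    lo <- d$lower; up <- d$upper; m <- domain
  }
  if (is.null(L)) L <- max(av[m], bv[m])
  if (length(dim(av)) == 2) { av <- array(av, c(dim(av), 1)); bv <- array(bv, c(dim(bv), 1))
                              m <- array(m, dim(av)); lo <- c(lo, 1); up <- c(up, 2) }
  w <- gauss_win()
  ix <- lo[1]:(up[1] - 1); iy <- lo[2]:(up[2] - 1)
  total <- 0; nvox <- 0
  for (z in lo[3]:(up[3] - 1)) {
    sa <- av[ix, iy, z, drop = FALSE][, , 1]
    sb <- bv[ix, iy, z, drop = FALSE][, , 1]
    sm <- m[ix, iy, z, drop = FALSE][, , 1]
    if (!any(sm)) next
    smap <- ssim_map_2d(sa, sb, L, w)
    total <- total + sum(smap[sm]); nvox <- nvox + sum(sm)
  }
  if (nvox == 0) stop("domain error: empty evaluation domain")
  total / nvox
}

#' Intra-class correlation coefficient, two-way absolute agreement
#'
#' ICC(A,1): single-measurement, two-way random-effects, absolute-agreement
#' form, computed from the ANOVA mean squares of the subjects x methods
#' table. This form penalizes systematic offsets between methods, the
#' appropriate criterion when asking whether one measurement method can
#' replace another.
#'
#' @param pairs two-column numeric matrix or data frame (method 1, method 2),
#'   or a list of length-2 vectors; n >= 3 rows.
#' @return Scalar ICC; `NA` with a warning when total variance is zero.
#' @export
icc_agreement <- function(pairs) {
  x <- if (is.list(pairs) && !is.data.frame(pairs)) do.call(rbind, pairs)
       else as.matrix(pairs)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stop("domain error: need >= 3 pairs of >= 2 methods")
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps^0.5 * max(1, abs(msr))) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

# Consistency-form ICC(C,1), used as an internal contrast to the
# absolute-agreement form (offsets are forgiven here).
icc_consistency <- function(pairs) {
  x <- as.matrix(pairs); n <- nrow(x); k <- ncol(x); mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Coefficient of determination of the identity regression
#'
#' Measures how far paired predictions deviate from the identity line:
#' \deqn{R^2 = 1 - \sum_i (y_i - x_i)^2 / \sum_i (y_i - \bar y)^2.}
#' Equals 1 iff `y == x` (with nonconstant `y`); can be negative when the
#' deviation from identity exceeds the variance of `y`.
#'
#' @param x,y equal-length numeric vectors (reference, comparison).
#' @return Scalar; `NA` with a warning for constant `y`.
#' @export
r2_identity <- function(x, y) {
  if (length(x) != length(y)) stop("domain error: unequal lengths")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant values: identity R-squared undefined")
    return(NA_real_)
  }
  1 - sum((y - x)^2) / ss_tot
}

#' Summarize per-subject quality metrics across a cohort
#'
#' @param per_subject data frame with a `subject_id` column and one numeric
#'   column per metric.
#' @return An object of class `quality_report`: the per-subject table plus a
#'   `summary` data frame with mean and (n-1)-denominator sd per metric.
#' @export
summarize_cohort <- function(per_subject) {
  stopifnot(is.data.frame(per_subject), nrow(per_subject) >= 1)
  metric_cols <- names(per_subject)[vapply(per_subject, is.numeric, TRUE)]
  metric_cols <- setdiff(metric_cols, "subject_id")
  n <- nrow(per_subject)
  if (n == 1) warning("single subject: sd reported as 0")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_subject[[m]]), 0),
    sd = vapply(metric_cols, function(m)
      if (n > 1) stats::sd(per_subject[[m]]) else 0, 0),
    row.names = NULL
  )
  structure(list(per_subject = per_subject, summary = summ, n = n),
            class = "quality_report")
}
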