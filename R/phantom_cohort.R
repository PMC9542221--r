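#' Tissue parameter priors
#'
#' Per-class means of T1/T2 (ms) and PD (fraction) with between-subject
#' coefficients of variation and a within-subject texture amplitude.
#' Values are literature-typical for 1.5 T brain tissue; lesion classes
#' (ET, NET, ED) have elevated T2 and PD. The `t1_enhanced` entry of ET is
#' the post-contrast (gadolinium-shortened) T1 used only when simulating
#' the T1w-c channel.
#'
#' @return A data frame with one row per tissue class.
#' @export
tissue_model <- function() {
  data.frame(
    class = c("WM", "GM", "CSF", "ET", "NET", "ED"),
    code  = c(1L, 2L, 3L, 4L, 5L, 6L),
    t1 = c(600, 1000, 4000, 1350, 1200, 1600),
    t2 = c(80, 100, 2000, 130, 110, 160),
    pd = c(0.70, 0.85, 1.00, 0.90, 0.85, 0.95),
    cv = c(0.04, 0.04, 0.03, 0.07, 0.07, 0.07),
    texture_amp = c(0.03, 0.04, 0.02, 0.08, 0.08, 0.08),
    t1_enhanced = c(NA, NA, NA, 450, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Label codes used in all label volumes.
LABELS <- c(background = 0L, WM = 1L, GM = 2L, CSF = 3L,
            ET = 4L, NET = 5L, ED = 6L)

#' Lesion geometry specification
#'
#' @param radius_frac whole-tumor radius as a fraction of the smaller
#'   in-plane semi-axis of the brain (0 gives a lesion-free phantom).
#' @param hemisphere `"left"` or `"right"` (first-axis halves).
#' @param cyst_density per-voxel probability that an edema voxel is a
#'   fluid-filled microcyst (long T1/T2, high PD). Fluid pockets are nearly
#'   nulled on FLAIR but roughly iso-intense on T2w, so this density is a
#'   texture covariate carried predominantly by the FLAIR channel.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(radius_frac = 0.45, hemisphere = "left",
                        cyst_density = 0) {
  stopifnot(radius_frac >= 0, radius_frac <= 0.95,
            hemisphere %in% c("left", "right"),
            cyst_density >= 0, cyst_density < 1)
  structure(list(radius_frac = radius_frac, hemisphere = hemisphere,
                 cyst_density = cyst_density), class = "lesion_spec")
}

# Smooth random field on a grid: a sum of a few low/mid-frequency 3-D
# sinusoids with random wave vectors and phases; zero mean, unit-ish scale.
smooth_field <- function(dims, n_waves = 6, freq_range = c(1.5, 4)) {
  cx <- (seq_len(dims[1]) - 0.5) / dims[1]
  cy <- (seq_len(dims[2]) - 0.5) / dims[2]
  cz <- (seq_len(dims[3]) - 0.5) / dims[3]
  f <- array(0, dims)
  for (w in seq_len(n_waves)) {
    k <- stats::runif(3, freq_range[1], freq_range[2]) *
      sample(c(-1, 1), 3, replace = TRUE) * 2 * pi
    ph <- stats::runif(1, 0, 2 * pi)
    phase <- outer(outer(k[1] * cx, k[2] * cy, `+`), k[3] * cz, `+`) + ph
    f <- f + sin(phase)
  }
  f / sqrt(n_waves / 2)   # approx unit variance
}

#' Generate one brain-like relaxometry phantom
#'
#' Builds a piecewise-constant-plus-texture T1/T2/PD phantom: an ellipsoidal
#' head with a cortical GM rim, WM interior and CSF ventricles, and a tumor
#' made of nested deformed ellipsoids — NET core, ET shell, ED halo — placed
#' in one hemisphere. Per-subject tissue means are drawn from the priors;
#' smooth sinusoidal texture modulates each map. Edema voxels may be
#' replaced by fluid-like microcysts at the rate given in the lesion spec.
#'
#' @param seed integer seed; the phantom is voxel-identical for equal seeds.
#' @param grid_shape integer vector (nx, ny, nz).
#' @param tissue a [tissue_model()] data frame.
#' @param lesion a [lesion_spec()].
#' @return An object of class `subject_record` with `maps`
#'   ([relaxometry_maps()]), `labels` (integer array), lesion statistics
#'   (`wt_volume`, `ed_tc_ratio`, `cyst_density`), and
#'   `hemisphere_of_tumor`; weighted images and survival are filled by later
#'   stages.
#' @export
generate_phantom <- function(seed, grid_shape = c(64, 64, 32),
                             tissue = tissue_model(),
                             lesion = lesion_spec()) {
  stopifnot(length(grid_shape) == 3)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  set.seed(seed)

  # normalized coordinates in [-1, 1] per axis
  X <- array(rep((seq_len(nx) - (nx + 1) / 2) / (nx / 2), times = ny * nz), grid_shape)
  Y <- array(rep(rep((seq_len(ny) - (ny + 1) / 2) / (ny / 2), each = nx), times = nz), grid_shape)
  Z <- array(rep((seq_len(nz) - (nz + 1) / 2) / (nz / 2), each = nx * ny), grid_shape)

  r_head <- sqrt((X / 0.92)^2 + (Y / 0.92)^2 + (Z / 0.95)^2)
  head <- r_head <= 1
  labels <- array(LABELS[["background"]], grid_shape)
  labels[head] <- LABELS[["WM"]]
  labels[head & r_head > 0.80] <- LABELS[["GM"]]
  # two ventricles, mirrored across the midline
  for (sx in c(-1, 1)) {
    vent <- sqrt(((X - sx * 0.22) / 0.12)^2 + (Y / 0.38)^2 + (Z / 0.35)^2) <= 1
    labels[vent & head] <- LABELS[["CSF"]]
  }

  # tumor: nested deformed ellipsoids in one hemisphere
  side <- if (lesion$hemisphere == "left") -1 else 1
  if (lesion$radius_frac > 0) {
    R <- lesion$radius_frac * 0.5            # in normalized units
    if (R * nx / 2 < 3 && lesion$radius_frac > 0)
      R <- max(R, 3 / (nx / 2))              # at least a 3-voxel radius
    if (R > 0.45) stop("spec error: lesion larger than hemisphere")
    cx <- side * 0.45
    cy <- stats::runif(1, -0.15, 0.15)
    cz <- stats::runif(1, -0.15, 0.15)
    ax <- R * exp(stats::runif(3, -0.2, 0.2)) # anisotropic semi-axes
    rt <- sqrt(((X - cx) / ax[1])^2 + ((Y - cy) / ax[2])^2 + ((Z - cz) / ax[3])^2)
    rt <- rt + 0.12 * smooth_field(grid_shape, freq_range = c(2, 5))  # deformation
    tum <- rt <= 1 & head
    labels[tum] <- LABELS[["ED"]]
    labels[rt <= 0.62 & head] <- LABELS[["ET"]]
    labels[rt <= 0.40 & head] <- LABELS[["NET"]]
    # keep the lesion in its hemisphere so contralateral WM exists
    wrong_side <- if (side < 0) X > 0 else X < 0
    spill <- tum & wrong_side
    labels[spill] <- LABELS[["WM"]]
  }

  # per-subject tissue means and textured maps
  t1 <- array(0, grid_shape); t2 <- array(0, grid_shape); pd <- array(0, grid_shape)
  tex <- list(t1 = smooth_field(grid_shape), t2 = smooth_field(grid_shape),
              pd = smooth_field(grid_shape))
  for (i in seq_len(nrow(tissue))) {
    cls <- tissue[i, ]
    vox <- labels == cls$code
    if (!any(vox)) next
    m_t1 <- cls$t1 * exp(stats::rnorm(1, 0, cls$cv))
    m_t2 <- cls$t2 * exp(stats::rnorm(1, 0, cls$cv))
    m_pd <- min(cls$pd * exp(stats::rnorm(1, 0, cls$cv / 2)), 1)
    t1[vox] <- m_t1 * (1 + cls$texture_amp * tex$t1[vox])
    t2[vox] <- m_t2 * (1 + cls$texture_amp * tex$t2[vox])
    pd[vox] <- pmin(pmax(m_pd * (1 + cls$texture_amp * tex$pd[vox]), 0.05), 1)
  }

  # Proteinaceous microcysts inside edema: very long T1 (nulled on FLAIR),
  # moderately long T2 (close to T2w-isointense against edema), full PD.
  # They are conspicuous on the fluid-suppressed contrast and faint
  # elsewhere, so their volume fraction is a FLAIR-dominant texture
  # covariate. Cysts are small clusters (a center voxel plus its 6-neighbor
  # shell inside edema), matching their ~2 mm physical extent.
  ed_vox <- which(labels == LABELS[["ED"]])
  n_cyst <- 0L
  if (lesion$cyst_density > 0 && length(ed_vox) > 0) {
    mean_cluster <- 7          # voxels per cyst (center + 6-neighborhood)
    n_seeds <- stats::rbinom(1, length(ed_vox),
                             lesion$cyst_density / mean_cluster)
    if (n_seeds > 0) {
      centers <- sample(ed_vox, n_seeds)
      strides <- c(1L, -1L, nx, -nx, nx * ny, -nx * ny)
      cyst_mask <- logical(length(labels))
      cyst_mask[centers] <- TRUE
      for (s in strides) {
        nb <- centers + s
        nb <- nb[nb >= 1 & nb <= length(labels)]
        cyst_mask[nb] <- TRUE
      }
      cv_ix <- which(cyst_mask & labels == LABELS[["ED"]])
      n_cyst <- length(cv_ix)
      t1[cv_ix] <- 3800 * exp(stats::rnorm(n_cyst, 0, 0.03))
      t2[cv_ix] <- 205 * exp(stats::rnorm(n_cyst, 0, 0.03))
      pd[cv_ix] <- pmin(1, 1.0 * exp(stats::rnorm(n_cyst, 0, 0.02)))
    }
  }

  maps <- relaxometry_maps(t1, t2, pd, mask = labels > 0)
  n_fg <- sum(labels > 0)
  n_wt <- sum(labels %in% LABELS[c("ET", "NET", "ED")])
  n_tc <- sum(labels %in% LABELS[c("ET", "NET")])
  structure(list(
    subject_id = sprintf("subj_%08d", seed %% 99999989L),
    seed = seed,
    maps = maps,
    labels = labels,
    weighted = list(),
    hemisphere_of_tumor = lesion$hemisphere,
    wt_volume = n_wt,
    ed_tc_ratio = if (n_tc > 0) (n_wt - n_tc) / n_tc else NA_real_,
    cyst_density = lesion$cyst_density,
    survival_days = NA_integer_,
    censored = NA_integer_
  ), class = "subject_record")
}

# Maps with the post-contrast (gadolinium) T1 shortening applied to ET.
enhanced_maps <- function(record, tissue = tissue_model()) {
  m <- record$maps
  et <- record$labels == LABELS[["ET"]]
  if (any(et)) {
    scale <- tissue$t1_enhanced[tissue$class == "ET"] /
      tissue$t1[tissue$class == "ET"]
    t1 <- m$t1; t1[et] <- t1[et] * scale
    m <- relaxometry_maps(t1, m$t2, m$pd, m$mask)
  }
  m
}

#' Simulate the acquired weighted images of one subject
#'
#' Runs each contrast of the protocol through the ideal forward model and
#' corrupts it with Rician noise, the magnitude-image noise law:
#' \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}} with
#' \eqn{\epsilon_i \sim N(0, \sigma)}. With `noise_sigma = 0` the ideal
#' image is reproduced exactly. T1w-c is simulated from the
#' contrast-enhanced maps (ET T1 shortened); all other contrasts use the
#' native maps.
#'
#' @param record a [generate_phantom()] output.
#' @param protocol named list of [acquisition_params()].
#' @param noise_sigma Rician sigma on the raw signal scale (WM T1w signal is
#'   about 0.4).
#' @param seed integer seed for the noise draws only.
#' @return The record with `$weighted` filled (named list of
#'   [weighted_image()]) and `$ideal` holding the noiseless versions.
#' @export
simulate_subject_images <- function(record, protocol = default_protocol(),
                                    noise_sigma = 0.02, seed = record$seed + 1L) {
  stopifnot(inherits(record, "subject_record"))
  set.seed(seed)
  record$ideal <- list()
  record$weighted <- list()
  for (contrast in names(protocol)) {
    maps <- if (contrast == "T1w_c") enhanced_maps(record) else record$maps
    ideal <- simulate_contrast(maps, contrast, protocol)
    record$ideal[[contrast]] <- ideal
    s <- ideal$intensities
    if (noise_sigma > 0) {
      e1 <- array(stats::rnorm(length(s), 0, noise_sigma), dim(s))
      e2 <- array(stats::rnorm(length(s), 0, noise_sigma), dim(s))
      s <- sqrt((s + e1)^2 + e2^2)
      s[!ideal$mask] <- 0          # background stays identically zero
    }
    record$weighted[[contrast]] <- weighted_image(s, contrast, ideal$params,
                                                  ideal$mask)
  }
  record$noise_sigma <- noise_sigma
  record
}

#' Cohort specification
#'
#' Defines the study conditions of a synthetic cohort: size, grid, noise,
#' the survival generative law and its link to lesion properties, and the
#' classification threshold (480 days = 16 months, chosen to balance the
#' two survival groups).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_shape voxel grid, default 64 x 64 x 32.
#' @param seed master seed.
#' @param baseline_days median survival of the baseline subject; 480 puts
#'   the classes near balance at the 480-day threshold.
#' @param effect_volume,effect_ratio,effect_texture log-scale accelerated
#'   failure-time coefficients on standardized whole-tumor volume, the
#'   ED/TC volume ratio, and the planted cyst-severity covariate.
#' @param sigma_log residual log-survival sd.
#' @param censor_rate independent censoring probability in \[0, 1).
#' @param noise_sigma Rician sigma of the simulated acquisitions.
#' @param radius_range whole-tumor radius range (fraction, see
#'   [lesion_spec()]) sampled uniformly per subject.
#' @param cyst_max maximum microcyst density; a subject's density is
#'   `cyst_max * plogis(severity)` with severity ~ N(0, 1).
#' @param threshold_days survival dichotomization threshold.
#' @param protocol acquisition protocol.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24, grid_shape = c(64, 64, 32), seed = 1,
                        baseline_days = 480, effect_volume = -0.20,
                        effect_ratio = 0.00, effect_texture = -0.55,
                        sigma_log = 0.28, censor_rate = 0.07,
                        noise_sigma = 0.02, radius_range = c(0.30, 0.55),
                        cyst_max = 0.30, threshold_days = 480,
                        protocol = default_protocol()) {
  stopifnot(n_subjects >= 2, censor_rate >= 0, censor_rate < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Attach survival metadata to phantom records
#'
#' Survival follows a log-normal accelerated-failure-time law whose linear
#' predictor contains the configured lesion covariates: standardized log
#' whole-tumor volume, ED/TC ratio, and the planted cyst-severity
#' covariate. Censoring is independent: a censored subject's recorded time
#' is a uniform fraction (25-90%) of the latent death time.
#'
#' @param records list of [generate_phantom()] outputs carrying a
#'   `$severity` field (set by [generate_cohort()]; defaults to 0).
#' @param spec a [cohort_spec()].
#' @param seed seed for the survival draws.
#' @return The records with `survival_days` and `censored` filled.
#' @export
assign_survival <- function(records, spec, seed = spec$seed + 7L) {
  if (spec$censor_rate >= 1) stop("spec error: all-censored configuration")
  set.seed(seed)
  vol <- vapply(records, function(r) log1p(r$wt_volume), 0)
  rat <- vapply(records, function(r) ifelse(is.na(r$ed_tc_ratio), 0, r$ed_tc_ratio), 0)
  sev <- vapply(records, function(r) if (is.null(r$severity)) 0 else r$severity, 0)
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  lp <- spec$effect_volume * zs(vol) + spec$effect_ratio * zs(rat) +
    spec$effect_texture * sev
  days <- exp(log(spec$baseline_days) + lp +
                stats::rnorm(length(records), 0, spec$sigma_log))
  cens <- stats::runif(length(records)) < spec$censor_rate
  obs <- ifelse(cens, days * stats::runif(length(records), 0.25, 0.90), days)
  for (i in seq_along(records)) {
    records[[i]]$survival_days <- max(1L, as.integer(round(obs[i])))
    records[[i]]$censored <- as.integer(cens[i])
  }
  records
}

#' Survival metadata table of a cohort
#' @param records list of subject records with survival filled.
#' @return data frame with columns subject_id, survival_days, censored.
#' @export
survival_table <- function(records) {
  data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    survival_days = vapply(records, `[[`, 0L, "survival_days"),
    censored = vapply(records, `[[`, 0L, "censored"),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' Composes [generate_phantom()], [simulate_subject_images()] and
#' [assign_survival()] under one master seed: per-subject seeds, lesion
#' sizes, hemispheres and cyst severities are drawn once from the spec
#' seed, so an identical spec reproduces the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `records` (list of `subject_record`),
#'   `survival` (data frame) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  sub_seeds <- sample.int(2^31 - 10L, n)
  radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  hemis <- sample(c("left", "right"), n, replace = TRUE)
  severity <- stats::rnorm(n)
  noise_seeds <- sample.int(2^31 - 10L, n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    les <- lesion_spec(radius_frac = radii[i], hemisphere = hemis[i],
                       cyst_density = spec$cyst_max * stats::plogis(severity[i]))
    rec <- generate_phantom(sub_seeds[i], spec$grid_shape, lesion = les)
    rec$subject_id <- sprintf("subj_%03d", i)
    rec$severity <- severity[i]
    rec <- simulate_subject_images(rec, spec$protocol, spec$noise_sigma,
                                   seed = noise_seeds[i])
    records[[i]] <- rec
  }
  records <- assign_survival(records, spec)
  list(records = records, survival = survival_table(records), spec = spec)
}

#' Write a cohort to disk
#'
#' Volumes go out as NIfTI (maps, labels and each weighted contrast per
#' subject), survival as CSV, and the spec as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records) {
    sd <- file.path(dir, rec$subject_id)
    dir.create(sd, showWarnings = FALSE)
    RNifti::writeNifti(rec$maps$t1, file.path(sd, "t1_map.nii.gz"))
    RNifti::writeNifti(rec$maps$t2, file.path(sd, "t2_map.nii.gz"))
    RNifti::writeNifti(rec$maps$pd, file.path(sd, "pd_map.nii.gz"))
    RNifti::writeNifti(rec$labels + 0, file.path(sd, "labels.nii.gz"))
    for (cn in names(rec$weighted))
      RNifti::writeNifti(rec$weighted[[cn]]$intensities,
                         file.path(sd, paste0(cn, ".nii.gz")))
  }
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  sp <- cohort$spec; sp$protocol <- lapply(sp$protocol, unclass)
  jsonlite::write_json(unclass(sp), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
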