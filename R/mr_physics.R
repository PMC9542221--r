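#' Relaxometry map container
#'
#' Bundles voxel-wise quantitative tissue parameters: longitudinal relaxation
#' time T1 (ms), transverse relaxation time T2 (ms) and proton density PD
#' (arbitrary units, nominally in \[0, 1\]), on a shared grid, with a logical
#' foreground mask. Background voxels are forced to exactly zero in all three
#' maps. On the foreground T1 >= T2 is enforced by clipping T2, the physical
#' ordering for tissue at clinical field strengths.
#'
#' @param t1,t2,pd numeric arrays of identical dimension.
#' @param mask logical array of the same dimension; `NULL` means every voxel
#'   with positive PD is foreground.
#' @return An object of class `relaxometry_maps`: a list with elements
#'   `t1`, `t2`, `pd`, `mask`.
#' @export
relaxometry_maps <- function(t1, t2, pd, mask = NULL) {
  if (!identical(dim(t1), dim(t2)) || !identical(dim(t1), dim(pd)))
    stop("grid error: t1, t2, pd must share one grid shape")
  if (is.null(mask)) mask <- pd > 0
  if (!identical(dim(mask), dim(t1)))
    stop("grid error: mask shape differs from maps")
  mask <- array(as.logical(mask), dim = dim(t1))
  bad <- mask & (t1 <= 0 | t2 <= 0)
  if (any(bad))
    stop("parameter error: T1 and T2 must be strictly positive on foreground")
  t2 <- pmin(t2, t1)            # physical constraint T1 >= T2
  t1[!mask] <- 0; t2[!mask] <- 0; pd[!mask] <- 0
  structure(list(t1 = t1, t2 = t2, pd = pd, mask = mask),
            class = "relaxometry_maps")
}

#' Acquisition parameter set
#'
#' Sequence timing parameters for the ideal signal equations: echo time TE,
#' repetition time TR and, for inversion-recovery spin echo, inversion time
#' TI, all in milliseconds.
#'
#' @param sequence `"SE"` (spin echo) or `"IR_SE"` (inversion-recovery spin
#'   echo).
#' @param te,tr,ti timing in ms; `ti` is required iff `sequence == "IR_SE"`.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(sequence = c("SE", "IR_SE"), te, tr, ti = NULL) {
  sequence <- match.arg(sequence)
  if (!is.numeric(te) || !is.numeric(tr) || te <= 0 || tr <= 0)
    stop("parameter error: TE and TR must be positive")
  if (te >= tr) stop("parameter error: TE must be smaller than TR")
  if (sequence == "IR_SE") {
    if (is.null(ti)) stop("parameter error: TI required for IR_SE")
    if (ti <= 0 || ti >= tr) stop("parameter error: need 0 < TI < TR")
  } else {
    ti <- NULL
  }
  structure(list(sequence = sequence, te = te, tr = tr, ti = ti),
            class = "acquisition_params")
}

#' Weighted image container
#'
#' A simulated or acquired weighted MR volume together with its contrast
#' label, the acquisition parameters that produced it and the pixel/voxel
#' domain mask on which losses and metrics are evaluated.
#'
#' @param intensities nonnegative numeric array.
#' @param contrast one of `"T1w"`, `"T2w"`, `"FLAIR"`, `"T1w_c"`.
#' @param params an [acquisition_params()] object (may be `NULL` for images
#'   of external origin).
#' @param mask logical array; intensities are zeroed outside it.
#' @return An object of class `weighted_image`.
#' @export
weighted_image <- function(intensities, contrast, params = NULL, mask = NULL) {
  if (any(!is.finite(intensities)))
    stop("value error: intensities must be finite")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(intensities))
  if (!identical(dim(mask), dim(intensities)))
    stop("grid error: mask shape differs from intensities")
  mask <- array(as.logical(mask), dim = dim(intensities))
  intensities[!mask] <- 0
  structure(list(intensities = intensities, contrast = contrast,
                 params = params, mask = mask),
            class = "weighted_image")
}

# Voxel-wise SE kernel; vectorized, safe at background voxels (t1 = t2 = 0).
se_signal <- function(pd, t1, t2, te, tr) {
  s <- pd * (1 - exp(-tr / pmax(t1, .Machine$double.eps))) *
    exp(-te / pmax(t2, .Machine$double.eps))
  s[pd == 0] <- 0
  s
}

# IR-SE kernel with magnitude reconstruction (clinical FLAIR is a magnitude
# image); nulls tissue at TI = T1 * ln 2 when TR >> T1.
ir_se_signal <- function(pd, t1, t2, te, tr, ti) {
  t1s <- pmax(t1, .Machine$double.eps)
  f <- 1 - 2 * exp(-ti / t1s) + exp(-tr / t1s)
  s <- pd * abs(f) * exp(-te / pmax(t2, .Machine$double.eps))
  s[pd == 0] <- 0
  s
}

#' Ideal spin-echo forward model
#'
#' Evaluates the closed-form spin-echo signal
#' \deqn{S = PD \cdot (1 - e^{-TR/T_1}) \cdot e^{-TE/T_2}}
#' voxel-wise. The signal is linear in PD, strictly increasing in TR and
#' strictly decreasing in TE for positive maps.
#'
#' @param maps a [relaxometry_maps()] object.
#' @param params an [acquisition_params()] with `sequence == "SE"`.
#' @param contrast contrast label attached to the output.
#' @return A [weighted_image()].
#' @export
simulate_spin_echo <- function(maps, params, contrast = "T1w") {
  stopifnot(inherits(maps, "relaxometry_maps"),
            inherits(params, "acquisition_params"))
  if (params$sequence != "SE") stop("parameter error: SE params required")
  s <- se_signal(maps$pd, maps$t1, maps$t2, params$te, params$tr)
  weighted_image(s, contrast, params, maps$mask)
}

#' Ideal inversion-recovery spin-echo forward model
#'
#' Evaluates the magnitude-reconstructed IR-SE signal
#' \deqn{S = PD \cdot |1 - 2 e^{-TI/T_1} + e^{-TR/T_1}| \cdot e^{-TE/T_2}}
#' voxel-wise. With long TR the signal vanishes at the inversion null
#' \eqn{TI = T_1 \ln 2}; a FLAIR protocol chooses TI to null fluid (long-T1
#' CSF).
#'
#' @inheritParams simulate_spin_echo
#' @return A [weighted_image()].
#' @export
simulate_ir_se <- function(maps, params, contrast = "FLAIR") {
  stopifnot(inherits(maps, "relaxometry_maps"),
            inherits(params, "acquisition_params"))
  if (params$sequence != "IR_SE" || is.null(params$ti))
    stop("parameter error: IR_SE params with TI required")
  s <- ir_se_signal(maps$pd, maps$t1, maps$t2, params$te, params$tr, params$ti)
  weighted_image(s, contrast, params, maps$mask)
}

#' Default acquisition protocol
#'
#' Per-contrast sequence timings used throughout the package, patterned on a
#' steady 1.5 T clinical glioblastoma protocol: a short-TE/short-TR SE T1w,
#' a long-TE/long-TR SE T2w, a fluid-suppressing IR-SE FLAIR (TI 2200 ms)
#' and a T1w-like SE for the post-contrast image. Clinical T1w/T1w-c series
#' are often ultrafast gradient echo; SE-equivalent timings with the same
#' weighting are used here because the forward models are SE-family.
#'
#' @return Named list of [acquisition_params()], one per contrast label.
#' @export
default_protocol <- function() {
  list(
    T1w   = acquisition_params("SE",    te = 10,  tr = 500),
    T2w   = acquisition_params("SE",    te = 122, tr = 4162),
    FLAIR = acquisition_params("IR_SE", te = 142, tr = 9350, ti = 2200),
    T1w_c = acquisition_params("SE",    te = 10,  tr = 500)
  )
}

#' Simulate one weighted contrast
#'
#' Dispatches a contrast label to the matching closed-form model: SE for
#' T1w, T2w and T1w-c, IR-SE for FLAIR, using the timings stored in the
#' protocol config.
#'
#' @param maps a [relaxometry_maps()] object.
#' @param contrast contrast label present in `protocol`.
#' @param protocol named list of [acquisition_params()]; see
#'   [default_protocol()].
#' @return A [weighted_image()] with the params used recorded.
#' @export
simulate_contrast <- function(maps, contrast, protocol = default_protocol()) {
  params <- protocol[[contrast]]
  if (is.null(params))
    stop(sprintf("config error: contrast '%s' not in protocol", contrast))
  if (params$sequence == "IR_SE")
    simulate_ir_se(maps, params, contrast)
  else
    simulate_spin_echo(maps, params, contrast)
}

#' Mean absolute error between two weighted images
#'
#' \deqn{MAE(m, m_{syn}) = \frac{1}{|\chi|} \sum_{x \in \chi} |m(x) - m_{syn}(x)|}
#' over the pixel domain \eqn{\chi} given by `domain_mask` (default: the
#' acquired image's own mask).
#'
#' @param acquired,synthesized [weighted_image()] objects (or bare arrays) on
#'   a shared grid.
#' @param domain_mask logical array selecting the evaluation domain.
#' @return Scalar MAE.
#' @export
mae_image <- function(acquired, synthesized, domain_mask = NULL) {
  a <- if (inherits(acquired, "weighted_image")) acquired$intensities else acquired
  b <- if (inherits(synthesized, "weighted_image")) synthesized$intensities else synthesized
  if (!identical(dim(a), dim(b)))
    stop("grid error: images must share one grid shape")
  if (is.null(domain_mask)) {
    domain_mask <- if (inherits(acquired, "weighted_image")) acquired$mask
                   else array(TRUE, dim = dim(a))
  }
  if (!any(domain_mask)) stop("domain error: empty evaluation domain")
  mean(abs(a[domain_mask] - b[domain_mask]))
}

#' Batch synthesis loss
#'
#' The self-supervision loss: the average of per-image MAEs over all M
#' acquired/synthesized image pairs entering the batch,
#' \deqn{L_{syn} = \frac{1}{M} \sum_{k=1}^{M} MAE(m_k, m_{syn}^k).}
#'
#' @param batch_acquired,batch_synth equal-length lists of
#'   [weighted_image()] objects (or arrays).
#' @return Scalar loss; equals [mae_image()] when `M == 1`.
#' @export
synthesis_loss <- function(batch_acquired, batch_synth) {
  if (length(batch_acquired) == 0) stop("domain error: empty batch")
  if (length(batch_acquired) != length(batch_synth))
    stop("domain error: batches must have equal length")
  maes <- mapply(mae_image, batch_acquired, batch_synth)
  mean(maes)
}
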