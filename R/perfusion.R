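#' Discrete convolution matrix of an AIF
#'
#' Lower-triangular Toeplitz matrix `A` with `A[i, j] = dt * aif[i-j+1]`,
#' so that `A %*% r` is the left-Riemann discretization of
#' \eqn{\int AIF(\tau) R(t - \tau) d\tau} on the frame grid. The same
#' quadrature is used by the phantom generator, making noiseless
#' round trips exact up to SVD truncation.
#'
#' @param aif length-f AIF concentration curve.
#' @param dt_s frame interval in seconds.
#' @return f x f matrix.
#' @export
conv_matrix <- function(aif, dt_s) {
  f <- length(aif)
  A <- matrix(0, f, f)
  for (j in seq_len(f)) A[j:f, j] <- aif[seq_len(f - j + 1)]
  A * dt_s
}

#' Deconvolve tissue curves against an AIF (truncated SVD)
#'
#' Solves \eqn{C_{tis} = A r} per voxel, where `A` is the AIF
#' convolution matrix, via the truncated-SVD pseudo-inverse: singular
#' values below `lambda_rel * sigma_max` are zeroed. The recovered
#' residue is CBF-scaled (its peak estimates CBF, its peak time Tmax).
#'
#' @param conc a `concentration_series` (see
#'   [signal_to_concentration()]).
#' @param aif length-f AIF curve with a positive maximum.
#' @param lambda_rel relative truncation threshold in (0, 1); 0.2 is a
#'   conventional choice for noisy data, use e.g. 1e-6 for noiseless
#'   simulations.
#' @return A `residue_map`: `residue` (4D array, zero outside the brain
#'   mask), `dt_s`, `brain_mask`, `voxel_mm`.
#' @export
deconvolve <- function(conc, aif, lambda_rel = 0.2) {
  stopifnot(inherits(conc, "concentration_series"))
  d <- dim(conc$conc)
  if (length(aif) != d[4])
    stop("`aif` must have one value per frame", call. = FALSE)
  dt <- mean(diff(conc$frame_times_s))
  Ainv <- tsvd_pinv(conv_matrix(aif, dt), lambda_rel)
  C <- matrix(conc$conc, ncol = d[4])
  inmask <- as.logical(conc$brain_mask$mask)
  R <- matrix(0, nrow(C), d[4])
  R[inmask, ] <- C[inmask, , drop = FALSE] %*% t(Ainv)
  structure(list(residue = array(R, dim = d), dt_s = dt,
                 brain_mask = conc$brain_mask, voxel_mm = conc$voxel_mm),
            class = "residue_map")
}

#' Deconvolve a matrix of tissue curves (low-level)
#'
#' Same computation as [deconvolve()] on a bare `voxels x frames`
#' matrix; useful for simulation studies.
#'
#' @param C `n x f` matrix of tissue curves (one row per curve).
#' @param aif length-f AIF curve.
#' @param dt_s frame interval.
#' @param lambda_rel relative SVD truncation threshold.
#' @return `n x f` matrix of recovered residues.
#' @export
deconvolve_curves <- function(C, aif, dt_s, lambda_rel = 0.2) {
  C %*% t(tsvd_pinv(conv_matrix(aif, dt_s), lambda_rel))
}

tsvd_pinv <- function(A, lambda_rel) {
  if (max(abs(A)) == 0) stop("all-zero AIF", call. = FALSE)
  if (lambda_rel <= 0 || lambda_rel >= 1)
    stop("`lambda_rel` must be in (0, 1)", call. = FALSE)
  sv <- svd(A)
  keep <- sv$d >= lambda_rel * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Tmax map: time to maximum of the residue function
#'
#' Per voxel, `dt * (argmax - 1)` of the deconvolved residue curve,
#' earliest frame on ties.
#'
#' @param res a `residue_map`.
#' @return 3D map in seconds.
#' @export
tmax_map <- function(res) {
  stopifnot(inherits(res, "residue_map"))
  d <- dim(res$residue)
  R <- matrix(res$residue, ncol = d[4])
  tm <- (max.col(R, ties.method = "first") - 1) * res$dt_s
  array(tm, dim = d[1:3])
}

#' Relative CBF map from the residue peak
#'
#' The per-voxel maximum of the deconvolved residue (the CBF estimate in
#' SVD deconvolution), normalized by the in-mask median of that quantity
#' (`brain_median`) or by the median over the mirrored hemisphere
#' (`contralateral`, mirror along the width axis).
#'
#' @param res a `residue_map`.
#' @param normalization `"brain_median"` or `"contralateral"`.
#' @return 3D map (dimensionless).
#' @export
rcbf_map <- function(res, normalization = c("brain_median",
                                            "contralateral")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(res, "residue_map"))
  d <- dim(res$residue)
  R <- matrix(res$residue, ncol = d[4])
  cbf <- apply(R, 1, max)
  dim(cbf) <- d[1:3]
  inmask <- res$brain_mask$mask > 0
  cbf[!inmask] <- 0
  if (normalization == "brain_median") {
    norm <- median(cbf[inmask])
    if (!is.finite(norm) || norm <= 0)
      stop("zero or invalid normalizer", call. = FALSE)
    out <- cbf / norm
  } else {
    mid <- d[1] / 2
    xs <- slice.index(cbf, 1)
    left <- xs <= mid
    m_left <- median(cbf[inmask & left])
    m_right <- median(cbf[inmask & !left])
    if (!all(is.finite(c(m_left, m_right))) || m_left <= 0 || m_right <= 0)
      stop("zero or invalid contralateral normalizer", call. = FALSE)
    out <- cbf
    out[left] <- cbf[left] / m_right
    out[!left] <- cbf[!left] / m_left
  }
  out[!inmask] <- 0
  out
}

#' CBV and MTT maps
#'
#' CBV is the trapezoid integral of the tissue curve divided by that of
#' the AIF; MTT = CBV / CBF (central volume theorem) with CBF the
#' residue peak, zero where CBF is (numerically) zero.
#'
#' @param conc a `concentration_series`.
#' @param aif length-f AIF curve.
#' @param res the matching `residue_map`.
#' @param eps CBF floor below which MTT is set to 0.
#' @return List with 3D arrays `cbv` and `mtt_s`.
#' @export
cbv_mtt_maps <- function(conc, aif, res, eps = 1e-10) {
  stopifnot(inherits(conc, "concentration_series"),
            inherits(res, "residue_map"))
  tt <- conc$frame_times_s
  aif_area <- trapz(tt, aif)
  if (aif_area <= 0) stop("AIF integral must be > 0", call. = FALSE)
  d <- dim(conc$conc)
  C <- matrix(conc$conc, ncol = d[4])
  w <- trapz_weights(tt)
  cbv <- as.vector(C %*% w) / aif_area
  R <- matrix(res$residue, ncol = d[4])
  cbf <- apply(R, 1, max)
  mtt <- ifelse(cbf > eps, cbv / cbf, 0)
  list(cbv = array(cbv, dim = d[1:3]), mtt_s = array(mtt, dim = d[1:3]))
}

trapz_weights <- function(tt) {
  n <- length(tt)
  w <- numeric(n)
  w[1] <- (tt[2] - tt[1]) / 2
  w[n] <- (tt[n] - tt[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (tt[3:n] - tt[1:(n - 2)]) / 2
  w
}

trapz <- function(tt, y) sum(trapz_weights(tt) * y)

#' Perfusion-diffusion mismatch summary
#'
#' The ischemic region is `Tmax > tmax_thresh` (6 s), the infarct core
#' `ADC < adc_thresh` (620 x 1e-6 mm^2/s). Volumes are voxel counts
#' times voxel volume in mL. The mismatch volume is the difference of
#' the two volumes (set-difference available via `mode`), and the
#' mismatch ratio is mismatch volume / core volume — flagged infinite
#' when the core is empty but ischemic tissue exists, and undefined when
#' both are empty.
#'
#' @param tmax_s 3D Tmax map in seconds.
#' @param adc 3D ADC map in 1e-6 mm^2/s.
#' @param voxel_mm length-3 voxel size in mm.
#' @param tmax_thresh_s,adc_thresh thresholds (defaults 6 s and 620).
#' @param mask optional 0/1 array or [volume_mask] restricting the
#'   analysis (e.g. a brain mask).
#' @param mode `"difference"` (volume difference) or `"setdiff"`
#'   (volume of ischemic voxels outside the core).
#' @return A `mismatch_report` list: `ischemic_volume_ml`,
#'   `core_volume_ml`, `mismatch_volume_ml`, `mismatch_ratio`,
#'   `infinite_ratio`, `undefined_ratio`, `thresholds`.
#' @export
#' @examples
#' tm <- array(0, c(10, 10, 2)); tm[1:5, 1:10, 1] <- 10
#' ad <- array(800, c(10, 10, 2)); ad[1:2, 1:5, 1] <- 500
#' mismatch(tm, ad, voxel_mm = c(1, 1, 1))
mismatch <- function(tmax_s, adc, voxel_mm, tmax_thresh_s = 6,
                     adc_thresh = 620, mask = NULL,
                     mode = c("difference", "setdiff")) {
  mode <- match.arg(mode)
  if (!identical(dim(tmax_s), dim(adc)))
    stop("Tmax and ADC maps must share the same grid", call. = FALSE)
  keep <- if (is.null(mask)) TRUE else
    (if (inherits(mask, "volume_mask")) mask$mask else mask) > 0
  isch <- (tmax_s > tmax_thresh_s) & keep
  core <- (adc < adc_thresh) & keep
  vml <- prod(voxel_mm) / 1000
  v_isch <- sum(isch) * vml
  v_core <- sum(core) * vml
  v_mis <- if (mode == "difference") max(v_isch - v_core, 0) else
    sum(isch & !core) * vml
  infinite <- v_core == 0 && v_mis > 0
  undefined <- v_core == 0 && v_mis == 0
  ratio <- if (infinite) Inf else if (undefined) NA_real_ else
    v_mis / v_core
  structure(list(ischemic_volume_ml = v_isch, core_volume_ml = v_core,
                 mismatch_volume_ml = v_mis, mismatch_ratio = ratio,
                 infinite_ratio = infinite, undefined_ratio = undefined,
                 thresholds = c(tmax_s = tmax_thresh_s, adc = adc_thresh)),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(
    "<mismatch_report> ischemic %.2f mL | core %.2f mL | mismatch %.2f mL | ratio %s\n",
    x$ischemic_volume_ml, x$core_volume_ml, x$mismatch_volume_ml,
    if (x$infinite_ratio) "Inf (empty core)" else
      if (x$undefined_ratio) "undefined" else sprintf("%.2f", x$mismatch_ratio)))
  invisible(x)
}
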