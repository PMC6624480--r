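#' Segmentation confusion metrics and Dice coefficient
#'
#' Voxel-wise accuracy, sensitivity, specificity, precision and the Dice
#' similarity coefficient \eqn{DSC = 2|A \cap B| / (|A| + |B|)} between a
#' predicted and a ground-truth mask. When both masks are empty the DSC
#' is defined as 1. With `mip_axial = TRUE` both masks are first
#' collapsed along the slice axis by maximum-intensity projection, the
#' comparison surface used for vessel masks on axial planes.
#'
#' @param pred,truth [volume_mask]s or 0/1 3D arrays on the same grid.
#' @param mip_axial compare axial MIPs instead of volumes.
#' @return A `segmentation_scores` list: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `dsc`, and the confusion counts.
#' @export
#' @examples
#' a <- array(0L, c(4, 4, 2)); a[1:2, 1, 1] <- 1L
#' segmentation_scores(a, a)$dsc  # 1
segmentation_scores <- function(pred, truth, mip_axial = FALSE) {
  p <- if (inherits(pred, "volume_mask")) pred$mask else pred
  t_ <- if (inherits(truth, "volume_mask")) truth$mask else truth
  if (!identical(dim(p), dim(t_)))
    stop("`pred` and `truth` must share the same grid", call. = FALSE)
  if (mip_axial) {
    p <- apply(p, c(1, 2), max)
    t_ <- apply(t_, c(1, 2), max)
  }
  p <- p != 0; t_ <- t_ != 0
  tp <- sum(p & t_); tn <- sum(!p & !t_)
  fp <- sum(p & !t_); fn <- sum(!p & t_)
  dsc <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    dsc = dsc,
    counts = c(tp = tp, tn = tn, fp = fp, fn = fn)),
    class = "segmentation_scores")
}

#' AIF curve characteristics: amplitude, centre, crest width
#'
#' Amplitude is the curve maximum, the centre its (earliest) peak time,
#' and the width the full width at half maximum with linearly
#' interpolated half-max crossings. If the curve does not cross half
#' maximum on one side, the width extends to the curve boundary and
#' `truncated` is flagged.
#'
#' @param curve numeric vector with a positive maximum.
#' @param times_s times of the samples, same length.
#' @return A `curve_characteristics` list: `amplitude`, `center_s`,
#'   `width_s`, `truncated`.
#' @export
curve_characteristics <- function(curve, times_s) {
  stopifnot(length(curve) == length(times_s), length(curve) >= 2)
  if (max(curve) <= 0)
    stop("curve must have a positive maximum", call. = FALSE)
  ipk <- which.max(curve)
  amp <- curve[ipk]
  half <- amp / 2
  truncated <- FALSE

  cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between samples
    times_s[i0] + (half - curve[i0]) * (times_s[i1] - times_s[i0]) /
      (curve[i1] - curve[i0])
  }
  below_l <- which(curve[seq_len(ipk)] < half)
  if (length(below_l)) {
    i0 <- max(below_l)
    t_left <- cross(i0, i0 + 1L)
  } else {
    t_left <- times_s[1]
    truncated <- TRUE
  }
  after <- seq(ipk, length(curve))
  below_r <- after[curve[after] < half]
  if (length(below_r)) {
    i1 <- min(below_r)
    t_right <- cross(i1 - 1L, i1)
  } else {
    t_right <- times_s[length(times_s)]
    truncated <- TRUE
  }
  structure(list(amplitude = amp, center_s = times_s[ipk],
                 width_s = t_right - t_left, truncated = truncated),
            class = "curve_characteristics")
}

#' Differences between two sets of AIF curve characteristics
#'
#' Absolute differences of amplitude, centre and width, the per-case
#' comparison reported between an automatic and a manual AIF.
#'
#' @param auto,manual `curve_characteristics` objects.
#' @return Named numeric: `delta_amplitude`, `delta_center_s`,
#'   `delta_width_s`.
#' @export
curve_deltas <- function(auto, manual) {
  stopifnot(inherits(auto, "curve_characteristics"),
            inherits(manual, "curve_characteristics"))
  c(delta_amplitude = abs(auto$amplitude - manual$amplitude),
    delta_center_s = abs(auto$center_s - manual$center_s),
    delta_width_s = abs(auto$width_s - manual$width_s))
}

#' Discrete Fréchet distance between two AIF curves
#'
#' The minimal leash length over monotone couplings of the two polygonal
#' curves, computed by the standard dynamic program over points
#' `(t_i, c_i / normalize_by)`. Both curves are scaled by the peak of the
#' reference (manual) curve so distances are comparable across cases;
#' optionally the time axis is rescaled to `[0, 1]`.
#'
#' @param curve_a,curve_b equal-length numeric vectors (b is the
#'   reference).
#' @param times_s sample times, same length.
#' @param normalize_by amplitude normalizer, default the peak of
#'   `curve_b`.
#' @param rescale_time rescale the time axis to `[0, 1]` (default FALSE).
#' @return Non-negative scalar; 0 iff the curves are identical.
#' @export
frechet_distance <- function(curve_a, curve_b, times_s,
                             normalize_by = max(curve_b),
                             rescale_time = FALSE) {
  n <- length(curve_a)
  if (length(curve_b) != n)
    stop("curves must have equal length", call. = FALSE)
  stopifnot(n >= 2, length(times_s) == n)
  if (!is.finite(normalize_by) || normalize_by <= 0)
    stop("`normalize_by` must be > 0", call. = FALSE)
  tt <- times_s
  if (rescale_time) tt <- (tt - tt[1]) / (tt[n] - tt[1])
  pa <- cbind(tt, curve_a / normalize_by)
  pb <- cbind(tt, curve_b / normalize_by)
  D <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
              outer(pa[, 2], pb[, 2], "-")^2)
  Fm <- matrix(0, n, n)
  Fm[1, 1] <- D[1, 1]
  for (i in 2:n) Fm[i, 1] <- max(Fm[i - 1, 1], D[i, 1])
  for (j in 2:n) Fm[1, j] <- max(Fm[1, j - 1], D[1, j])
  for (i in 2:n) for (j in 2:n)
    Fm[i, j] <- max(D[i, j],
                    min(Fm[i - 1, j], Fm[i, j - 1], Fm[i - 1, j - 1]))
  Fm[n, n]
}
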