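#' Estimate a brain mask from a 4D series
#'
#' Otsu threshold on the temporal-mean volume, then the largest
#' 6-connected component, then a morphological closing of radius 1.
#' A light-weight stand-in for surface-based skull stripping, adequate
#' for data whose background is near zero.
#'
#' @param series a [perfusion_series].
#' @return A [volume_mask].
#' @export
brain_mask <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  vol <- rowMeans(matrix(series$signal, ncol = dim(series$signal)[4]))
  dim(vol) <- dim(series$signal)[1:3]
  thr <- otsu_threshold(vol)
  m <- vol > thr
  if (!any(m))
    stop("degenerate input: empty mask after Otsu thresholding",
         call. = FALSE)
  lab <- .label_components3(m, dim(m))
  keep <- which.max(tabulate(lab[lab > 0L]))
  m <- lab == keep
  m <- morph_close3(m)
  volume_mask(m, series$voxel_mm)
}

# Otsu's between-class-variance maximizing threshold (256 bins).
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1] == r[2])
    stop("degenerate input: constant volume", call. = FALSE)
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  hh <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- hh / sum(hh)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

shift3 <- function(x, dx, dy, dz, fill) {
  d <- dim(x)
  out <- array(fill, d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- if (dx >= 0) (1 + dx):d[1] else 1:(d[1] + dx)
  sy <- if (dy >= 0) (1 + dy):d[2] else 1:(d[2] + dy)
  sz <- if (dz >= 0) (1 + dz):d[3] else 1:(d[3] + dz)
  out[sx, sy, sz] <- x[sx - dx, sy - dy, sz - dz]
  out
}

morph_close3 <- function(m) {
  dil <- m
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (dx || dy || dz) dil <- dil | shift3(m, dx, dy, dz, FALSE)
  ero <- dil
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (dx || dy || dz) ero <- ero & shift3(dil, dx, dy, dz, TRUE)
  ero
}

#' Slice-timing correction by linear interpolation
#'
#' Each slice is acquired `slice_offsets_s[z]` after the nominal frame
#' time; per-voxel time curves are linearly interpolated back onto the
#' common frame grid, clamping at the first and last frames.
#'
#' @param series a [perfusion_series].
#' @param slice_offsets_s per-slice acquisition offsets in `[0, TR)`.
#' @return A corrected [perfusion_series].
#' @export
slice_time_correct <- function(series, slice_offsets_s) {
  stopifnot(inherits(series, "perfusion_series"))
  d <- dim(series$signal)
  if (length(slice_offsets_s) != d[3])
    stop("`slice_offsets_s` must have one entry per slice", call. = FALSE)
  if (any(slice_offsets_s < 0 | slice_offsets_s >= series$tr_s))
    stop("slice offsets must lie in [0, TR)", call. = FALSE)
  tt <- series$frame_times_s
  out <- series$signal
  for (z in seq_len(d[3])) {
    o <- slice_offsets_s[z]
    if (o == 0) next
    st <- tt + o                      # actual sample times of this slice
    i <- pmin(pmax(findInterval(tt, st), 1L), d[4] - 1L)
    wgt <- (tt - st[i]) / (st[i + 1L] - st[i])
    wgt <- pmin(pmax(wgt, 0), 1)      # clamp before first sample
    for (k in seq_len(d[4]))
      out[, , z, k] <- series$signal[, , z, i[k]] * (1 - wgt[k]) +
        series$signal[, , z, i[k] + 1L] * wgt[k]
  }
  series$signal <- out
  series
}

gauss_edge_matrix <- function(n, sigma_vox) {
  K <- diag(n)
  if (sigma_vox <= 0) return(K)
  r <- ceiling(3 * sigma_vox)
  wts <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  wts <- wts / sum(wts)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (o in -r:r) {
    j <- min(max(i + o, 1L), n)       # replicate-edge padding
    K[i, j] <- K[i, j] + wts[o + r + 1]
  }
  K
}

#' In-plane spatial smoothing
#'
#' Per-frame 2D Gaussian blur within each slice; `sigma_mm` is converted
#' to voxels via the in-plane voxel size. Replicate-edge padding keeps
#' constant images constant. `sigma_mm = 0` is the identity.
#'
#' @param series a [perfusion_series].
#' @param sigma_mm Gaussian SD in mm (default 0.86, i.e. two voxels at
#'   the 0.43 mm in-plane resolution this package emulates).
#' @return A smoothed [perfusion_series].
#' @export
smooth_spatial <- function(series, sigma_mm = 0.86) {
  stopifnot(inherits(series, "perfusion_series"))
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(series)
  d <- dim(series$signal)
  K1 <- gauss_edge_matrix(d[1], sigma_mm / series$voxel_mm[1])
  K2 <- gauss_edge_matrix(d[2], sigma_mm / series$voxel_mm[2])
  out <- series$signal
  for (z in seq_len(d[3])) for (k in seq_len(d[4]))
    out[, , z, k] <- K1 %*% series$signal[, , z, k] %*% t(K2)
  series$signal <- pmax(out, 0)
  series
}

#' Motion-correction hook
#'
#' Interface placeholder in the preprocessing chain; the default is the
#' identity (the bundled phantoms are motion-free). Supply your own
#' function `series -> series` to plug in a registration step.
#'
#' @param series a [perfusion_series].
#' @param method `"none"` (identity) or a function.
#' @return A [perfusion_series].
#' @export
motion_correct <- function(series, method = "none") {
  if (is.function(method)) return(method(series))
  series
}

#' Convert signal to tracer concentration
#'
#' Standard DSC relaxivity conversion \eqn{C = -\ln(S/S_0)/TE} per voxel
#' and frame, with \eqn{S_0} the mean of the first `baseline_frames`
#' frames. Voxels where \eqn{S_0 \le 0} are dropped from the mask;
#' samples with \eqn{S \le 0} yield concentration 0. Both counts are
#' recorded in the result's `log`.
#'
#' @param series a [perfusion_series].
#' @param baseline_frames number of pre-bolus frames; `NULL` autodetects
#'   (first frame whose global mean drops 3 SD below the initial mean),
#'   falling back to 5.
#' @param mask optional [volume_mask]; computed by [brain_mask()] if
#'   missing.
#' @return A `concentration_series`: `conc` (4D array, zero outside the
#'   mask), `frame_times_s`, `brain_mask`, `baseline_frames`, `te_s`,
#'   `voxel_mm`, `log`.
#' @export
signal_to_concentration <- function(series, baseline_frames = NULL,
                                    mask = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  if (is.null(mask)) mask <- brain_mask(series)
  d <- dim(series$signal)
  if (is.null(baseline_frames))
    baseline_frames <- detect_baseline_frames(series, mask)
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 2L || baseline_frames >= d[4])
    stop("`baseline_frames` must be in [2, f)", call. = FALSE)
  S <- matrix(series$signal, ncol = d[4])
  inmask <- as.logical(mask$mask)
  s0 <- rowMeans(S[, seq_len(baseline_frames), drop = FALSE])
  bad_s0 <- inmask & s0 <= 0
  inmask[bad_s0] <- FALSE
  C <- matrix(0, nrow(S), d[4])
  rows <- which(inmask)
  ratio <- S[rows, , drop = FALSE] / s0[rows]
  nonpos <- ratio <= 0
  ratio[nonpos] <- 1                      # -> concentration 0
  C[rows, ] <- -log(ratio) / series$te_s
  m <- mask
  m$mask <- array(as.integer(inmask), dim = d[1:3])
  structure(list(
    conc = array(C, dim = d),
    frame_times_s = series$frame_times_s,
    brain_mask = m,
    baseline_frames = baseline_frames,
    te_s = series$te_s,
    voxel_mm = series$voxel_mm,
    log = list(n_s0_excluded = sum(bad_s0), n_nonpos_signal = sum(nonpos))),
    class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf(
    "<concentration_series> %d x %d x %d voxels, %d frames | baseline %d frames, %d in mask\n",
    d[1], d[2], d[3], d[4], x$baseline_frames, sum(x$brain_mask$mask)))
  invisible(x)
}

detect_baseline_frames <- function(series, mask) {
  d <- dim(series$signal)
  S <- matrix(series$signal, ncol = d[4])
  gm <- colMeans(S[as.logical(mask$mask), , drop = FALSE])
  mu0 <- mean(gm[1:min(3, d[4])])
  sd0 <- max(sd(gm[1:min(3, d[4])]), 1e-8 * abs(mu0), 1e-12)
  arr <- which(gm < mu0 - 3 * sd0)[1]
  bl <- if (is.na(arr)) 5L else as.integer(arr - 1L)
  min(max(bl, 2L), d[4] - 1L)
}

#' Remove linear baseline drift from concentration curves
#'
#' Fits a straight line per voxel through the pre-bolus baseline frames
#' and the last `tail_frames` frames, subtracts it over the whole curve,
#' and re-zeroes negative values within the fitted frames.
#'
#' @param conc a `concentration_series`.
#' @param tail_frames number of trailing frames in the fit (default 5).
#' @return The detrended `concentration_series`.
#' @export
remove_drift <- function(conc, tail_frames = 5L) {
  stopifnot(inherits(conc, "concentration_series"), tail_frames >= 1)
  f <- dim(conc$conc)[4]
  idx <- sort(unique(c(seq_len(conc$baseline_frames),
                       (f - tail_frames + 1L):f)))
  tt <- conc$frame_times_s
  Y <- matrix(conc$conc, ncol = f)
  X <- cbind(1, tt[idx])
  beta <- solve(crossprod(X), t(X)) %*% t(Y[, idx, drop = FALSE])  # 2 x V
  fitted <- t(cbind(1, tt) %*% beta)
  out <- Y - fitted
  # tail should sit on the post-bolus plateau, not on the bolus itself
  gm <- colMeans(abs(out))
  if (max(gm) > 1e-9 * max(abs(Y)) &&
      max(gm[(f - tail_frames + 1L):f]) > 0.5 * max(gm))
    warning("tail frames overlap the bolus; drift fit may be biased")
  out[, idx][out[, idx] < 0] <- 0
  inmask <- as.logical(conc$brain_mask$mask)
  out[!inmask, ] <- 0
  conc$conc <- array(out, dim = dim(conc$conc))
  conc
}

#' Full preprocessing chain
#'
#' Motion hook, optional slice-timing correction, in-plane smoothing,
#' brain masking, signal-to-concentration conversion and linear drift
#' removal, in that order.
#'
#' @param series a [perfusion_series].
#' @param slice_offsets_s optional per-slice offsets for
#'   [slice_time_correct()].
#' @param sigma_mm smoothing SD in mm (0 disables).
#' @param baseline_frames passed to [signal_to_concentration()].
#' @param tail_frames passed to [remove_drift()].
#' @param motion passed to [motion_correct()].
#' @return A `concentration_series`.
#' @export
preprocess_series <- function(series, slice_offsets_s = NULL,
                              sigma_mm = 0.86, baseline_frames = NULL,
                              tail_frames = 5L, motion = "none") {
  series <- motion_correct(series, motion)
  if (!is.null(slice_offsets_s))
    series <- slice_time_correct(series, slice_offsets_s)
  if (sigma_mm > 0) series <- smooth_spatial(series, sigma_mm)
  conc <- signal_to_concentration(series, baseline_frames)
  remove_drift(conc, tail_frames)
}
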