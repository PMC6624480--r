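#' Gamma-variate bolus parameters
#'
#' The first-pass bolus of contrast agent in a feeding artery is modelled
#' by a gamma-variate curve
#' \deqn{C(t) = A (t - t_0)^{\alpha} e^{-(t - t_0)/\beta}, \quad t > t_0,}
#' zero before arrival. Its peak sits at \eqn{t_0 + \alpha\beta}.
#'
#' @param amplitude scale factor A (concentration a.u.), > 0.
#' @param t0_s bolus arrival time in seconds, >= 0.
#' @param alpha dimensionless shape, > 0.
#' @param beta_s decay scale in seconds, > 0.
#' @return A `gamma_params` object.
#' @export
gamma_params <- function(amplitude, t0_s, alpha, beta_s) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta_s) || beta_s <= 0)
    stop("`alpha` and `beta_s` must be > 0", call. = FALSE)
  if (amplitude <= 0 || t0_s < 0)
    stop("need amplitude > 0 and t0_s >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, t0_s = t0_s, alpha = alpha,
                 beta_s = beta_s), class = "gamma_params")
}

#' Evaluate a gamma-variate bolus curve
#'
#' @param t numeric vector of times in seconds.
#' @param p a [gamma_params].
#' @return Concentration values, zero for `t <= t0_s`.
#' @export
#' @examples
#' p <- gamma_params(40, 9, 3, 1.5)
#' t <- seq(0, 60, by = 1.5)
#' max_at <- t[which.max(gamma_variate(t, p))]  # near t0 + alpha * beta
gamma_variate <- function(t, p) {
  stopifnot(inherits(p, "gamma_params"), all(is.finite(t)))
  dt <- t - p$t0_s
  out <- numeric(length(t))
  up <- dt > 0
  out[up] <- p$amplitude * dt[up]^p$alpha * exp(-dt[up] / p$beta_s)
  out
}

#' Synthetic phantom configuration
#'
#' Defines the geometry, acquisition metadata, bolus, tissue-parameter
#' ranges and lesion of a synthetic 4D DSC-MRI case. Defaults are the
#' desk-scale study conditions: 64 x 64 x 8 voxels over 40 frames at
#' dt = 1.5 s, TE = 2.6 ms, voxel 0.43 x 0.43 x 5.00 mm.
#'
#' Tissue kinetics use CBF in 1/s (so CBV = CBF x MTT is a volume
#' fraction), per-voxel bolus delays quantized to whole frames, and a
#' mono-exponential residue. The ADC map is in 1e-6 mm^2/s so the
#' conventional infarct-core threshold of 620 applies verbatim.
#'
#' @param dims length-4 integer, w x h x s x f.
#' @param dt_s frame interval (s).
#' @param te_s echo time (s).
#' @param voxel_mm voxel edge lengths (mm).
#' @param s0 baseline signal (a.u.).
#' @param noise_sd Gaussian signal noise SD (a.u.); roughly 10% of the
#'   typical tissue signal drop at the default.
#' @param aif [gamma_params] of the arterial bolus.
#' @param arterial_jitter per-voxel multiplicative amplitude jitter
#'   half-range for arterial voxels.
#' @param vessel_center_xy in-plane vessel-tube centre as fractions of w,h.
#' @param vessel_radius_vox in-plane tube radius in voxels (tube spans all
#'   slices).
#' @param brain_radius_frac in-plane brain-ellipse radii as a fraction of
#'   w and h.
#' @param cbf_range tissue CBF range (1/s), uniform per voxel.
#' @param mtt_range_s tissue MTT range (s), uniform per voxel.
#' @param delay_max_s maximum background bolus delay (s); per-voxel delays
#'   are drawn from frame multiples in `[0, delay_max_s]`.
#' @param lesion NULL, or a list with `center_xy` (fractions), `radius_vox`
#'   (in-plane), `slices` (integer vector), `cbf_factor`, `delay_s`,
#'   `mtt_s`, and `core_radius_vox` (ADC lesion, concentric).
#' @param adc_mean,adc_sd background ADC distribution (1e-6 mm^2/s).
#' @param adc_core_mean infarct-core ADC mean (below 620).
#' @param recirculation add a small second bolus lobe (default FALSE).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dims = c(64, 64, 8, 40), dt_s = 1.5,
                           te_s = 0.0026, voxel_mm = c(0.43, 0.43, 5),
                           s0 = 1000, noise_sd = 7,
                           aif = gamma_params(40, 9, 3, 1.5),
                           arterial_jitter = 0.03,
                           vessel_center_xy = c(0.3, 0.5),
                           vessel_radius_vox = 4,
                           brain_radius_frac = 0.42,
                           cbf_range = c(0.008, 0.012),
                           mtt_range_s = c(3, 5),
                           delay_max_s = 3,
                           lesion = list(center_xy = c(0.65, 0.6),
                                         radius_vox = 11, slices = 2:7,
                                         cbf_factor = 0.4, delay_s = 7.5,
                                         mtt_s = 6, core_radius_vox = 6),
                           adc_mean = 800, adc_sd = 30,
                           adc_core_mean = 450,
                           recirculation = FALSE) {
  stopifnot(length(dims) == 4, all(dims >= 1), dims[4] >= 2,
            dt_s > 0, te_s > 0, s0 > 0, noise_sd >= 0,
            inherits(aif, "gamma_params"))
  structure(as.list(environment()), class = "phantom_config")
}

in_ellipse <- function(w, h, center_xy, rx, ry) {
  cx <- center_xy[1] * (w - 1) + 1
  cy <- center_xy[2] * (h - 1) + 1
  xs <- matrix(seq_len(w), w, h)
  ys <- matrix(seq_len(h), w, h, byrow = TRUE)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

#' Generate one synthetic phantom case
#'
#' Builds a 4D DSC-MRI signal series with full ground truth: an elliptic
#' brain, a through-slice arterial tube carrying the gamma-variate bolus
#' (with small per-voxel amplitude jitter), tissue voxels carrying
#' \eqn{C_{tis} = CBF \cdot (AIF \circledast R)} with
#' \eqn{R(t) = e^{-(t-delay)/MTT}} on the frame grid (left-Riemann
#' discrete convolution), an optional hypoperfused lesion with an ADC
#' infarct core, and signal \eqn{S = S_0 e^{-TE \cdot C}} plus clipped
#' Gaussian noise. Deterministic given `seed`.
#'
#' @param cfg a [phantom_config].
#' @param seed integer RNG seed.
#' @return A `phantom_case` list: `series` ([perfusion_series]),
#'   `vessel_truth`, `brain_mask` ([volume_mask]s), `aif_truth`
#'   (length-f curve), `cbf_map`, `delay_map`, `mtt_map`, `adc_map`
#'   (3D arrays), `seed`, `cfg`.
#' @export
make_phantom <- function(cfg = phantom_config(), seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(as.integer(seed))
  d <- cfg$dims
  w <- d[1]; h <- d[2]; s <- d[3]; f <- d[4]
  t_s <- (seq_len(f) - 1) * cfg$dt_s

  brain2d <- in_ellipse(w, h, c(0.5, 0.5),
                        cfg$brain_radius_frac * w, cfg$brain_radius_frac * h)
  brain <- array(rep(brain2d, s), dim = c(w, h, s))
  vessel2d <- in_ellipse(w, h, cfg$vessel_center_xy,
                         cfg$vessel_radius_vox, cfg$vessel_radius_vox)
  vessel <- array(rep(vessel2d, s), dim = c(w, h, s)) & brain
  if (!any(vessel)) stop("vessel tube lies outside the brain", call. = FALSE)

  lesion <- core <- array(FALSE, dim = c(w, h, s))
  if (!is.null(cfg$lesion)) {
    L <- cfg$lesion
    les2d <- in_ellipse(w, h, L$center_xy, L$radius_vox, L$radius_vox)
    core2d <- in_ellipse(w, h, L$center_xy, L$core_radius_vox,
                         L$core_radius_vox)
    sl <- intersect(L$slices, seq_len(s))
    lesion[, , sl] <- les2d
    core[, , sl] <- core2d
    if (any(lesion & !brain))
      stop("lesion region extends outside the brain mask", call. = FALSE)
    lesion <- lesion & !vessel
    core <- core & !vessel
  }

  aif_truth <- gamma_variate(t_s, cfg$aif)
  if (isTRUE(cfg$recirculation)) {
    p2 <- cfg$aif
    recirc <- gamma_params(p2$amplitude * 0.15, p2$t0_s + 5 * p2$beta_s,
                           p2$alpha, p2$beta_s * 2)
    aif_truth <- aif_truth + gamma_variate(t_s, recirc)
  }

  nvox <- w * h * s
  # per-voxel tissue parameters (drawn everywhere, meaningful inside brain)
  cbf <- runif(nvox, cfg$cbf_range[1], cfg$cbf_range[2])
  mtt <- runif(nvox, cfg$mtt_range_s[1], cfg$mtt_range_s[2])
  max_lag <- floor(cfg$delay_max_s / cfg$dt_s)
  delay <- cfg$dt_s * sample.int(max_lag + 1L, nvox, replace = TRUE) -
    cfg$dt_s
  jitter <- 1 + runif(nvox, -cfg$arterial_jitter, cfg$arterial_jitter)
  if (!is.null(cfg$lesion)) {
    cbf[lesion] <- cbf[lesion] * cfg$lesion$cbf_factor
    delay[lesion] <- round(cfg$lesion$delay_s / cfg$dt_s) * cfg$dt_s
    mtt[lesion] <- cfg$lesion$mtt_s
  }

  # residue matrix (voxel x frame) and discrete convolution with the AIF
  A <- conv_matrix(aif_truth, cfg$dt_s)
  tmat <- matrix(t_s, nvox, f, byrow = TRUE)
  shifted <- tmat - delay
  R <- exp(-pmax(shifted, 0) / mtt) * (shifted >= 0)
  conc <- (cbf * R) %*% t(A)            # voxel x frame tissue curves
  conc[vessel, ] <- jitter[vessel] %o% aif_truth
  conc[!brain, ] <- 0

  sig <- cfg$s0 * exp(-cfg$te_s * conc)
  sig[!brain, ] <- 0
  if (cfg$noise_sd > 0)
    sig <- sig + rnorm(length(sig), sd = cfg$noise_sd)
  sig <- pmax(sig, 0)
  signal <- array(sig, dim = c(w, h, s, f))

  adc <- rnorm(nvox, cfg$adc_mean, cfg$adc_sd)
  adc[core] <- rnorm(sum(core), cfg$adc_core_mean, cfg$adc_sd)
  adc[!brain] <- cfg$adc_mean       # neutral background, never "core"
  adc <- pmax(adc, 1)

  cbf_map <- array(cbf, dim = c(w, h, s)); cbf_map[!brain] <- 0
  delay_map <- array(delay, dim = c(w, h, s)); delay_map[!brain] <- 0
  mtt_map <- array(mtt, dim = c(w, h, s)); mtt_map[!brain] <- 0

  structure(list(
    series = perfusion_series(signal, tr_s = cfg$dt_s, te_s = cfg$te_s,
                              voxel_mm = cfg$voxel_mm),
    vessel_truth = volume_mask(array(vessel * 1L, dim = c(w, h, s)),
                               cfg$voxel_mm),
    brain_mask = volume_mask(array(brain * 1L, dim = c(w, h, s)),
                             cfg$voxel_mm),
    aif_truth = aif_truth,
    cbf_map = cbf_map, delay_map = delay_map, mtt_map = mtt_map,
    adc_map = array(adc, dim = c(w, h, s)),
    lesion_mask = volume_mask(array(lesion * 1L, dim = c(w, h, s)),
                              cfg$voxel_mm),
    seed = as.integer(seed), cfg = cfg), class = "phantom_case")
}

#' Generate a reproducible multi-case phantom dataset
#'
#' Each case gets its own RNG stream derived from `(seed, case index)`.
#'
#' @param cfg a [phantom_config].
#' @param n_cases number of cases.
#' @param seed master seed.
#' @return List of `phantom_case` objects.
#' @export
make_phantom_set <- function(cfg = phantom_config(), n_cases = 1L,
                             seed = 1L) {
  lapply(seq_len(n_cases), function(i)
    make_phantom(cfg, seed = (as.integer(seed) * 1009L + i) %% .Machine$integer.max))
}

#' Write a phantom case to disk
#'
#' Writes the 4D series (NIfTI + YAML sidecar), truth masks and maps
#' (NIfTI), the true AIF (CSV) and a JSON manifest of the simulated
#' parameters.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(dir, x)
  write_series(case$series, p("series.nii.gz"))
  write_volume(case$vessel_truth, p("vessel_truth.nii.gz"))
  write_volume(case$brain_mask, p("brain_mask.nii.gz"))
  for (nm in c("cbf_map", "delay_map", "mtt_map", "adc_map"))
    write_volume(case[[nm]], p(paste0(nm, ".nii.gz")),
                 voxel_mm = case$cfg$voxel_mm)
  write_aif_csv(case$aif_truth, case$series$frame_times_s, p("aif_truth.csv"))
  manifest <- list(seed = case$seed, dims = case$cfg$dims,
                   dt_s = case$cfg$dt_s, te_s = case$cfg$te_s,
                   voxel_mm = case$cfg$voxel_mm,
                   aif = unclass(case$cfg$aif),
                   n_vessel_voxels = sum(case$vessel_truth$mask))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
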