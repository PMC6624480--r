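#' Segment the AIF region with a trained multi-stream model
#'
#' Classifies brain-mask voxels by their patch pair through both
#' streams and the SVM fusion. To bound compute, voxels whose TDC peak
#' lies in the top `1 - amp_quantile` amplitude fraction (the plausible
#' arterial candidates) are scanned exhaustively; the rest of the mask
#' is scanned on a coarse grid (`stride` in-plane, `stride_z` through
#' slice). Of the fused positives the largest 6-connected component is
#' kept as the AIF region; its voxel-mean TDC is the AIF.
#'
#' @param model an `msnet_model` from [train_msnet()].
#' @param conc a `concentration_series`.
#' @param amp_quantile amplitude quantile defining dense-scan
#'   candidates (default 0.95, i.e. top 5%).
#' @param stride,stride_z coarse-scan strides outside the candidate
#'   region.
#' @param combine `"fusion"` (SVM late fusion, default) or a single
#'   stream (`"spatial"` / `"temporal"`, thresholding its softmax score
#'   at 0.5).
#' @param keep_scores also return the per-voxel stream scores.
#' @return An `aif_result` (see [select_aif_fcm()]) with extra fields
#'   `n_evaluated` and `n_positive` (and, with `keep_scores`, `scores`:
#'   voxel indices plus both streams' softmax scores).
#' @export
segment_aif <- function(model, conc, amp_quantile = 0.95, stride = 4L,
                        stride_z = 2L,
                        combine = c("fusion", "spatial", "temporal"),
                        keep_scores = FALSE) {
  combine <- match.arg(combine)
  stopifnot(inherits(model, "msnet_model"),
            inherits(conc, "concentration_series"))
  d <- dim(conc$conc)
  C <- matrix(conc$conc, ncol = d[4])
  inmask <- conc$brain_mask$mask > 0
  amps <- apply(C, 1, max)
  thr <- quantile(amps[inmask], amp_quantile)
  co_all <- arrayInd(seq_len(prod(d[1:3])), d[1:3])
  coarse <- (co_all[, 1] %% stride == 0) & (co_all[, 2] %% stride == 0) &
    (co_all[, 3] %% stride_z == 0)
  vox <- which(inmask & (amps >= thr | coarse))
  cfg <- model$net_cfg
  sp_ <- model$spatial$n_slices
  co <- arrayInd(vox, d[1:3])
  ssc <- matrix(0, length(vox), 2)
  tsc <- matrix(0, length(vox), 2)
  for (k in seq_along(vox)) {
    p <- extract_one_patch(d, conc$conc, co[k, 1], co[k, 2], co[k, 3],
                           cfg$patch_wh, sp_)
    dim(p) <- dim(p)[1:4]
    ssc[k, ] <- forward_stream(model$spatial,
                               stream_input(p, "spatial"))$p
    tsc[k, ] <- forward_stream(model$temporal,
                               stream_input(p, "temporal"))$p
  }
  pred <- switch(combine,
                 fusion = apply_fusion(model$fusion, ssc, tsc),
                 spatial = as.integer(ssc[, 2] > 0.5),
                 temporal = as.integer(tsc[, 2] > 0.5))
  posv <- vox[pred == 1L]
  if (!length(posv))
    stop(paste("empty AIF region after fusion; consider a lower",
               "`amp_quantile` or smaller stride"), call. = FALSE)
  roi <- roi_largest_cc(posv, d[1:3])
  curve <- colMeans(C[roi > 0, , drop = FALSE])
  out <- structure(
    list(roi = volume_mask(roi, conc$voxel_mm), curve = curve,
         characteristics = curve_characteristics(curve,
                                                 conc$frame_times_s),
         n_evaluated = length(vox), n_positive = length(posv)),
    class = "aif_result")
  if (keep_scores)
    out$scores <- list(voxels = vox, spatial = ssc, temporal = tsc)
  out
}

# largest 6-connected component of a set of positive voxel indices
roi_largest_cc <- function(posv, d3) {
  m <- array(FALSE, d3)
  m[posv] <- TRUE
  lab <- .label_components3(m, d3)
  keep <- which.max(tabulate(lab[lab > 0L]))
  roi <- array(0L, d3)
  roi[lab == keep] <- 1L
  roi
}

#' Save / load a trained multi-stream model
#'
#' The model directory holds the weights (`weights.rds`) plus a JSON
#' record of the network and training configuration for provenance.
#'
#' @param model an `msnet_model`.
#' @param dir model directory.
#' @return `save_msnet`: `dir` invisibly; `load_msnet`: the model.
#' @export
save_msnet <- function(model, dir) {
  stopifnot(inherits(model, "msnet_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(net_config = model$net_cfg[c("preset", "conv_filters",
                                      "fc_units", "patch_wh",
                                      "slices_per_patch")],
         train_config = unclass(model$tcfg),
         n_patches = model$n_patches),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_msnet
#' @export
load_msnet <- function(dir) {
  m <- readRDS(file.path(dir, "weights.rds"))
  stopifnot(inherits(m, "msnet_model"))
  m
}
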