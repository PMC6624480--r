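#' Training hyperparameters
#'
#' Mini-batch SGD settings. The `"full"` preset is batch 50, 50
#' epochs, learning rate 0.001, momentum 0.9; the `"desk"` preset keeps
#' the optimizer but shortens training for CPU-scale runs.
#'
#' @param preset `"desk"` or `"full"`.
#' @param batch,epochs,lr,momentum,seed overrides.
#' @return A `train_config` list.
#' @export
train_config <- function(preset = c("desk", "full"), batch = NULL,
                         epochs = NULL, lr = 0.001, momentum = 0.9,
                         seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(batch)) batch <- if (preset == "full") 50L else 32L
  if (is.null(epochs)) epochs <- if (preset == "full") 50L else 8L
  stopifnot(batch >= 1, epochs >= 1, lr >= 0, momentum >= 0, momentum < 1)
  structure(list(preset = preset, batch = as.integer(batch),
                 epochs = as.integer(epochs), lr = lr,
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

#' Grow training labels from a manual AIF annotation
#'
#' The manual AIF is the mean TDC of the annotated voxels. Every voxel
#' within Chebyshev radius `r_voxels` of the annotation whose TDC has
#' Pearson correlation at least `corr_min` with the manual AIF and a
#' peak of at least half the manual AIF peak is labeled arterial;
#' annotated voxels are always labeled arterial.
#'
#' @param conc a `concentration_series`.
#' @param manual_roi a non-empty [volume_mask] of annotated AIF voxels.
#' @param r_voxels Chebyshev dilation radius.
#' @param corr_min correlation threshold in (0, 1].
#' @return A [volume_mask] of arterial labels.
#' @export
make_labels <- function(conc, manual_roi, r_voxels = 1L, corr_min = 0.9) {
  stopifnot(inherits(conc, "concentration_series"),
            corr_min > 0, corr_min <= 1)
  roi <- if (inherits(manual_roi, "volume_mask")) manual_roi$mask else
    manual_roi
  if (!any(roi > 0)) stop("`manual_roi` is empty", call. = FALSE)
  d <- dim(conc$conc)
  C <- matrix(conc$conc, ncol = d[4])
  aif <- colMeans(C[roi > 0, , drop = FALSE])
  cand <- roi > 0
  if (r_voxels > 0) {
    base <- roi > 0
    for (dz in -r_voxels:r_voxels)
      for (dy in -r_voxels:r_voxels)
        for (dx in -r_voxels:r_voxels)
          if (dx || dy || dz)
            cand <- cand | shift3(base, dx, dy, dz, FALSE)
  }
  cand <- cand & conc$brain_mask$mask > 0
  idx <- which(cand & !(roi > 0))
  lab <- array(0L, dim = d[1:3])
  lab[roi > 0] <- 1L
  if (length(idx)) {
    tdc <- C[idx, , drop = FALSE]
    cc <- suppressWarnings(as.vector(cor(t(tdc), aif)))
    cc[is.na(cc)] <- -1
    peaks <- apply(tdc, 1, max)
    lab[idx[cc >= corr_min & peaks >= 0.5 * max(aif)]] <- 1L
  }
  volume_mask(lab, conc$voxel_mm)
}

clamp_seq <- function(center, size, n) {
  half <- size %/% 2
  pmin(pmax(seq(center - half + 1L, center + half), 1L), n)
}

extract_one_patch <- function(conc_mat_dims, conc4d, x, y, z, wh, sp) {
  d <- conc_mat_dims
  conc4d[clamp_seq(x, wh, d[1]), clamp_seq(y, wh, d[2]),
         clamp_seq(z, sp, d[3]), , drop = FALSE]
}

#' Extract labeled training patches
#'
#' One canonical `(wh, wh, s_p, f)` patch is centered on every positive
#' voxel (optionally capped at `max_pos` per case); negatives are drawn
#' inside the brain mask at `neg_ratio` per positive — half of them
#' near-miss voxels within Chebyshev radius 2 of a positive, the rest
#' uniform — deterministically given `seed`. Patch borders are handled
#' by edge-clamped (replicated) indexing. The spatial and temporal
#' stream tensors of a patch are axis permutations of the stored
#' canonical patch (see [patch_stream_tensor()]).
#'
#' @param conc a `concentration_series`.
#' @param labels a [volume_mask] from [make_labels()].
#' @param patch_wh in-plane patch size.
#' @param slices_per_patch slices per patch.
#' @param neg_ratio negatives per positive.
#' @param seed sampling seed.
#' @param max_pos cap on positive patches (default all).
#' @param case_id recorded in the provenance table.
#' @return A `patch_set`: `patches` (`wh x wh x s_p x f x N` array),
#'   `labels` (0/1), `provenance` (case, x, y, z).
#' @export
extract_patches <- function(conc, labels, patch_wh = 16L,
                            slices_per_patch = 8L, neg_ratio = 3,
                            seed = 1L, max_pos = Inf, case_id = 1L) {
  stopifnot(inherits(conc, "concentration_series"))
  d <- dim(conc$conc)
  if (patch_wh > min(d[1], d[2]))
    stop("patch_wh exceeds the in-plane matrix size", call. = FALSE)
  sp <- min(slices_per_patch, d[3])
  lab <- if (inherits(labels, "volume_mask")) labels$mask else labels
  pos <- which(lab > 0)
  if (!length(pos))
    stop("degenerate input: no positive labels", call. = FALSE)
  set.seed(as.integer(seed))
  if (length(pos) > max_pos) pos <- sort(sample(pos, max_pos))
  inmask <- conc$brain_mask$mask > 0
  near <- lab > 0
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2)
    if (dx || dy || dz) near <- near | shift3(lab > 0, dx, dy, dz, FALSE)
  neg_pool_hard <- which(near & inmask & lab == 0)
  neg_pool_any <- which(inmask & lab == 0)
  n_neg <- round(neg_ratio * length(pos))
  n_hard <- min(n_neg %/% 2, length(neg_pool_hard))
  neg <- sample(neg_pool_hard, n_hard)
  rest <- setdiff(neg_pool_any, neg)
  neg <- c(neg, sample(rest, min(n_neg - n_hard, length(rest))))
  vox <- c(pos, neg)
  labs <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  co <- arrayInd(vox, d[1:3])
  N <- length(vox)
  patches <- array(0, dim = c(patch_wh, patch_wh, sp, d[4], N))
  for (i in seq_len(N))
    patches[, , , , i] <- extract_one_patch(d, conc$conc, co[i, 1],
                                            co[i, 2], co[i, 3],
                                            patch_wh, sp)
  structure(list(patches = patches, labels = labs,
                 provenance = data.frame(case = case_id, x = co[, 1],
                                         y = co[, 2], z = co[, 3]),
                 patch_wh = as.integer(patch_wh),
                 slices_per_patch = as.integer(sp),
                 n_frames = d[4]), class = "patch_set")
}

#' Combine patch sets from several cases
#'
#' @param sets list of `patch_set` objects with identical geometry.
#' @return One merged `patch_set`.
#' @export
merge_patch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  d1 <- dim(sets[[1]]$patches)
  N <- sum(vapply(sets, function(s) dim(s$patches)[5], 1L))
  patches <- array(0, dim = c(d1[1:4], N))
  at <- 0L
  for (s in sets) {
    n <- dim(s$patches)[5]
    patches[, , , , at + seq_len(n)] <- s$patches
    at <- at + n
  }
  structure(list(patches = patches,
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 provenance = do.call(rbind,
                                      lapply(sets, `[[`, "provenance")),
                 patch_wh = sets[[1]]$patch_wh,
                 slices_per_patch = sets[[1]]$slices_per_patch,
                 n_frames = sets[[1]]$n_frames), class = "patch_set")
}

#' Stream-ordered tensor of one stored patch
#'
#' Returns patch `i` in a network stream's axis order: `f x s x w x h`
#' (spatial, frame by frame then slice by slice) or `s x f x w x h`
#' (temporal, slice by slice then frame by frame).
#'
#' @param ps a `patch_set`.
#' @param i patch index.
#' @param layout `"spatial"` or `"temporal"`.
#' @return 4D array.
#' @export
patch_stream_tensor <- function(ps, i, layout = c("spatial", "temporal")) {
  layout <- match.arg(layout)
  p <- ps$patches[, , , , i]
  perm <- if (layout == "spatial") c(4, 3, 1, 2) else c(3, 4, 1, 2)
  aperm(p, perm)
}

zero_like <- function(model) {
  list(conv = lapply(model$conv, function(l)
    list(W = l$W * 0, b = l$b * 0)),
    fc1 = list(W = model$fc1$W * 0, b = model$fc1$b * 0),
    fc2 = list(W = model$fc2$W * 0, b = model$fc2$b * 0),
    out = list(W = model$out$W * 0, b = model$out$b * 0))
}

#' Train one CNN stream
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. The batch size is clipped to the dataset size;
#' batch composition is reshuffled each epoch from the training seed,
#' so runs are deterministic given `(model, patches, tcfg)`.
#'
#' @param model a `stream_model` from [build_stream()].
#' @param ps a `patch_set`.
#' @param tcfg a [train_config()].
#' @param subset optional integer indices of patches to train on.
#' @return The trained `stream_model`; per-epoch mean loss in
#'   `$loss_trace`.
#' @export
train_stream <- function(model, ps, tcfg, subset = NULL) {
  stopifnot(inherits(model, "stream_model"), inherits(ps, "patch_set"),
            inherits(tcfg, "train_config"))
  idx <- if (is.null(subset)) seq_along(ps$labels) else subset
  y <- ps$labels[idx]
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("degenerate input: need >= 2 examples per class", call. = FALSE)
  bsz <- min(tcfg$batch, length(idx))
  vel <- zero_like(model)
  loss_trace <- numeric(tcfg$epochs)
  set.seed(tcfg$seed)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(seq_along(idx))
    ep_loss <- 0
    for (b0 in seq(1, length(ord), by = bsz)) {
      bidx <- ord[b0:min(b0 + bsz - 1, length(ord))]
      acc <- zero_like(model)
      bl <- 0
      for (j in bidx) {
        X <- stream_input(ps$patches[, , , , idx[j]], model$stream)
        fw <- forward_stream(model, X, keep_cache = TRUE)
        yj <- y[j] + 1L                 # class index 1/2
        bl <- bl - log(max(fw$p[yj], 1e-12))
        dlog <- fw$p
        dlog[yj] <- dlog[yj] - 1
        g <- backward_stream(model, fw$cache, dlog)
        for (i in 1:8) {
          acc$conv[[i]]$W <- acc$conv[[i]]$W + g$conv[[i]]$W
          acc$conv[[i]]$b <- acc$conv[[i]]$b + g$conv[[i]]$b
        }
        for (nm in c("fc1", "fc2", "out")) {
          acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W
          acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
        }
      }
      nb <- length(bidx)
      upd <- function(w, v, gsum) {
        v <- tcfg$momentum * v - tcfg$lr * gsum / nb
        list(w = w + v, v = v)
      }
      for (i in 1:8) {
        uW <- upd(model$conv[[i]]$W, vel$conv[[i]]$W, acc$conv[[i]]$W)
        ub <- upd(model$conv[[i]]$b, vel$conv[[i]]$b, acc$conv[[i]]$b)
        model$conv[[i]]$W <- uW$w; vel$conv[[i]]$W <- uW$v
        model$conv[[i]]$b <- ub$w; vel$conv[[i]]$b <- ub$v
      }
      for (nm in c("fc1", "fc2", "out")) {
        uW <- upd(model[[nm]]$W, vel[[nm]]$W, acc[[nm]]$W)
        ub <- upd(model[[nm]]$b, vel[[nm]]$b, acc[[nm]]$b)
        model[[nm]]$W <- uW$w; vel[[nm]]$W <- uW$v
        model[[nm]]$b <- ub$w; vel[[nm]]$b <- ub$v
      }
      ep_loss <- ep_loss + bl
    }
    loss_trace[ep] <- ep_loss / length(ord)
  }
  model$loss_trace <- loss_trace
  model
}

#' Softmax scores of a stream on a patch set
#'
#' @param model a trained `stream_model`.
#' @param ps a `patch_set`.
#' @param subset optional indices.
#' @return `N x 2` matrix of class probabilities (rows sum to 1).
#' @export
predict_stream <- function(model, ps, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(ps$labels) else subset
  out <- matrix(0, length(idx), 2)
  for (k in seq_along(idx)) {
    X <- stream_input(ps$patches[, , , , idx[k]], model$stream)
    out[k, ] <- forward_stream(model, X)$p
  }
  out
}

#' Fit the late-fusion linear SVM
#'
#' Trains a linear support vector machine on the concatenated softmax
#' scores of the two streams (4 features per sample). Fit it on a split
#' held out from stream training to avoid overfit scores.
#'
#' @param spatial_scores,temporal_scores `N x 2` softmax score
#'   matrices (rows sum to 1).
#' @param labels length-N 0/1 labels with both classes present.
#' @param cost SVM cost parameter C.
#' @return A `fusion_model`.
#' @export
fuse_svm <- function(spatial_scores, temporal_scores, labels, cost = 1) {
  stopifnot(nrow(spatial_scores) == length(labels),
            nrow(temporal_scores) == length(labels))
  if (max(abs(rowSums(spatial_scores) - 1)) > 1e-6 ||
      max(abs(rowSums(temporal_scores) - 1)) > 1e-6)
    stop("score rows must sum to 1 (softmax outputs)", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("degenerate input: fusion labels contain a single class",
         call. = FALSE)
  feat <- cbind(spatial_scores, temporal_scores)
  colnames(feat) <- c("s0", "s1", "t0", "t1")
  fit <- e1071::svm(feat, factor(labels, levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(svm = fit), class = "fusion_model")
}

#' Apply the late fusion to stream scores
#'
#' @param fm a `fusion_model`.
#' @param spatial_scores,temporal_scores `N x 2` score matrices.
#' @return Integer 0/1 predictions.
#' @export
apply_fusion <- function(fm, spatial_scores, temporal_scores) {
  stopifnot(inherits(fm, "fusion_model"))
  feat <- cbind(spatial_scores, temporal_scores)
  colnames(feat) <- c("s0", "s1", "t0", "t1")
  as.integer(as.character(predict(fm$svm, feat)))
}

#' Train the full multi-stream model on phantom cases
#'
#' End-to-end training driver: converts each case's series to
#' concentration, grows labels from the manual annotation (the phantom's
#' vessel truth by default), extracts patch pairs, trains the spatial
#' and temporal streams on 80% of the patches and fits the linear-SVM
#' fusion on the held-out 20%.
#'
#' @param cases list of `phantom_case` objects (or lists with `series`
#'   and `manual_roi` entries).
#' @param net_cfg a [net_config()].
#' @param tcfg a [train_config()].
#' @param r_voxels,corr_min label-growing parameters
#'   ([make_labels()]).
#' @param neg_ratio,max_pos patch-sampling parameters
#'   ([extract_patches()]).
#' @param fusion_frac fraction of patches held out for the fusion SVM.
#' @return An `msnet_model`: `spatial`, `temporal`, `fusion`,
#'   `net_cfg`, `tcfg`, plus patch bookkeeping.
#' @export
train_msnet <- function(cases, net_cfg = net_config("desk"),
                        tcfg = train_config("desk"), r_voxels = 1L,
                        corr_min = 0.9, neg_ratio = 3, max_pos = 12L,
                        fusion_frac = 0.2) {
  sets <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    conc <- signal_to_concentration(cs$series)
    roi <- if (!is.null(cs$manual_roi)) cs$manual_roi else cs$vessel_truth
    lab <- make_labels(conc, roi, r_voxels = r_voxels,
                       corr_min = corr_min)
    sets[[i]] <- extract_patches(conc, lab, patch_wh = net_cfg$patch_wh,
                                 slices_per_patch =
                                   net_cfg$slices_per_patch,
                                 neg_ratio = neg_ratio,
                                 seed = tcfg$seed + i, max_pos = max_pos,
                                 case_id = i)
  }
  ps <- merge_patch_sets(sets)
  N <- length(ps$labels)
  set.seed(tcfg$seed)
  fus_idx <- sort(sample(N, max(2L, round(fusion_frac * N))))
  # guarantee both classes in both splits
  if (length(unique(ps$labels[fus_idx])) < 2)
    fus_idx <- sort(c(fus_idx[-1], which(ps$labels !=
                                           ps$labels[fus_idx[1]])[1]))
  tr_idx <- setdiff(seq_len(N), fus_idx)
  sp <- build_stream(net_cfg, "spatial", ps$n_frames,
                     ps$slices_per_patch, seed = tcfg$seed)
  tp <- build_stream(net_cfg, "temporal", ps$n_frames,
                     ps$slices_per_patch, seed = tcfg$seed + 1L)
  sp <- train_stream(sp, ps, tcfg, subset = tr_idx)
  tp <- train_stream(tp, ps, tcfg, subset = tr_idx)
  fus <- fuse_svm(predict_stream(sp, ps, fus_idx),
                  predict_stream(tp, ps, fus_idx),
                  ps$labels[fus_idx])
  structure(list(spatial = sp, temporal = tp, fusion = fus,
                 net_cfg = net_cfg, tcfg = tcfg,
                 n_patches = N, n_fusion = length(fus_idx)),
            class = "msnet_model")
}
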