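# Shared fixtures: small phantom configurations and synthetic patch sets
# built in code at test time.

# quick phantom: quarter-scale grid, short series; keeps per-test runtime low
tiny_cfg <- function(...) {
  phantom_config(dims = c(32, 32, 4, 20), vessel_radius_vox = 2,
                 lesion = NULL, delay_max_s = 3, ...)
}

# study-condition phantom (desk scale), as used end to end
desk_cfg <- function(...) phantom_config(...)

# a minimal network config that exercises every layer type in seconds
tiny_net <- function() {
  net_config("desk", conv_filters = c(2, 2, 2, 2, 2, 2, 2, 2),
             fc_units = 8L, patch_wh = 16L, slices_per_patch = 2L)
}

# synthetic separable patch set: class 1 carries a bright temporal bump at
# the patch centre, class 0 is noise. geometry (wh, wh, sp, f).
separable_patches <- function(n_pos, n_neg, wh = 16L, sp = 2L, f = 6L,
                              seed = 1, amplitude = 4) {
  set.seed(seed)
  N <- n_pos + n_neg
  patches <- array(rnorm(wh * wh * sp * f * N, sd = 0.5),
                   dim = c(wh, wh, sp, f, N))
  ctr <- wh %/% 2
  for (i in seq_len(n_pos))
    patches[ctr + (-1:1), ctr + (-1:1), , 2:3, i] <-
      patches[ctr + (-1:1), ctr + (-1:1), , 2:3, i] + amplitude
  structure(list(patches = patches,
                 labels = c(rep(1L, n_pos), rep(0L, n_neg)),
                 provenance = data.frame(case = 1L, x = 1L, y = 1L,
                                         z = 1L)[rep(1, N), ],
                 patch_wh = wh, slices_per_patch = sp, n_frames = f),
            class = "patch_set")
}

# brute-force discrete Frechet distance: explicit enumeration of all
# monotone couplings (no memoization) — independent of the DP implementation
frechet_bruteforce <- function(pa, pb) {
  n <- nrow(pa); m <- nrow(pb)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                 outer(pa[, 2], pb[, 2], "-")^2)
  rec <- function(i, j) {
    if (i == n && j == m) return(dmat[i, j])
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    max(dmat[i, j], best)
  }
  rec(1, 1)
}

# brute-force confusion metrics with an explicit voxel loop
scores_bruteforce <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  list(accuracy = (tp + tn) / length(pred), sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp), precision = tp / (tp + fp),
       dsc = 2 * tp / (2 * tp + fp + fn))
}
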