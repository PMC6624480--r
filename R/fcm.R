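#' Fuzzy c-means clustering of tissue concentration curves
#'
#' Clusters the per-voxel concentration time curves (TDCs) inside the
#' brain mask with standard fuzzy c-means: centroids are the
#' membership^m-weighted means, memberships follow the
#' inverse-distance-ratio rule with power `2/(m-1)`, iterated until the
#' largest membership change drops below `tol` or `max_iter` is
#' reached. TDCs are min-max normalized per voxel first (clustering by
#' curve shape, not amplitude); initial centroids are `c` distinct TDCs
#' drawn with `seed`.
#'
#' @param conc a `concentration_series`.
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @param seed RNG seed for centroid initialization.
#' @param normalize min-max normalize TDCs before clustering.
#' @return An `fcm_state`: `centroids` (c x f, in clustering space),
#'   `membership` (V x c), `objective` (per-iteration trace),
#'   `fuzzifier_m`, `voxel_index` (linear indices of the V in-mask
#'   voxels), `iterations`, `converged`.
#' @export
fcm_cluster <- function(conc, c = 5L, m = 2, tol = 1e-5, max_iter = 200L,
                        seed = 1L, normalize = TRUE) {
  stopifnot(inherits(conc, "concentration_series"), c >= 2L, m > 1)
  d <- dim(conc$conc)
  vox <- which(conc$brain_mask$mask > 0)
  X <- matrix(conc$conc, ncol = d[4])[vox, , drop = FALSE]
  if (normalize) X <- minmax_rows(X)
  ux <- unique(X)
  if (nrow(ux) < c)
    stop(sprintf("degenerate input: only %d distinct TDCs for %d clusters",
                 nrow(ux), c), call. = FALSE)
  # canonical (lexicographic) ordering makes the seeded initialization,
  # and hence the whole run, invariant to voxel enumeration order
  ux <- ux[do.call(order, as.data.frame(ux)), , drop = FALSE]
  set.seed(as.integer(seed))
  cent <- ux[sample.int(nrow(ux), c), , drop = FALSE]
  V <- nrow(X)
  xs2 <- rowSums(X^2)
  U_prev <- matrix(0, V, c)
  obj <- numeric(0)
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    D2 <- pmax(outer(xs2, rowSums(cent^2), "+") - 2 * X %*% t(cent), 0)
    W <- (D2 + 1e-300)^(-expo / 2)       # distance^(-2/(m-1))
    U <- W / rowSums(W)
    zr <- which(rowSums(D2 < 1e-200) > 0)       # coincident with a centroid
    if (length(zr)) {
      ind <- (D2[zr, , drop = FALSE] < 1e-200) * 1
      U[zr, ] <- ind / rowSums(ind)
    }
    Um <- U^m
    cent <- (t(Um) %*% X) / colSums(Um)
    D2 <- pmax(outer(xs2, rowSums(cent^2), "+") - 2 * X %*% t(cent), 0)
    obj <- c(obj, sum(Um * D2))
    if (max(abs(U - U_prev)) < tol) {
      U_prev <- U
      break
    }
    U_prev <- U
  }
  structure(list(centroids = cent, membership = U_prev, objective = obj,
                 fuzzifier_m = m, voxel_index = vox,
                 iterations = length(obj),
                 converged = length(obj) < max_iter),
            class = "fcm_state")
}

minmax_rows <- function(X) {
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  (X - lo) / rng
}

#' Cost of a candidate AIF curve
#'
#' Scores how "arterial" a mean cluster curve looks. The ideal AIF has
#' large amplitude, small width and fast attenuation, so the cost
#' \deqn{cost = t_{peak} \times FWHM / amplitude}
#' is low for early, narrow, tall curves. Curves without a positive
#' maximum get infinite cost and are never selected.
#'
#' @param centroid length-f mean concentration curve.
#' @param frame_times_s frame times in seconds.
#' @return Positive scalar cost (lower = more AIF-like).
#' @export
aif_cost <- function(centroid, frame_times_s) {
  if (max(centroid) <= 0) return(Inf)
  ch <- curve_characteristics(centroid, frame_times_s)
  dt_min <- min(diff(frame_times_s))
  max(ch$center_s, dt_min) * ch$width_s / ch$amplitude
}

#' Select an AIF by fuzzy c-means clustering
#'
#' Restricts the mask to plausible arterial candidates (TDC peak in the
#' top `1 - candidate_quantile` amplitude fraction — arterial voxels
#' carry far more contrast than tissue, and clustering the whole brain
#' would drown the small arterial minority in tissue clusters), runs
#' [fcm_cluster()], hard-assigns each voxel to its maximum-membership
#' cluster (ties to the lower cluster index), scores every cluster's
#' mean raw TDC with [aif_cost()], and returns the minimum-cost cluster
#' as the AIF region with its averaged curve.
#'
#' @inheritParams fcm_cluster
#' @param candidate_quantile amplitude quantile defining the candidate
#'   voxels clustered (default 0.95); 0 clusters the whole mask.
#' @return An `aif_result`: `roi` ([volume_mask]), `curve` (length-f
#'   mean TDC), `characteristics` ([curve_characteristics()]),
#'   `cluster` (selected index), `costs`, `fcm` (the `fcm_state`).
#' @export
select_aif_fcm <- function(conc, c = 5L, m = 2, tol = 1e-5,
                           max_iter = 200L, seed = 1L,
                           candidate_quantile = 0.95) {
  if (candidate_quantile > 0) {
    d3 <- dim(conc$conc)[1:3]
    C <- matrix(conc$conc, ncol = dim(conc$conc)[4])
    inmask <- conc$brain_mask$mask > 0
    amps <- apply(C, 1, max)
    thr <- quantile(amps[inmask], candidate_quantile)
    cand <- array(as.integer(inmask & amps >= thr), dim = d3)
    conc$brain_mask$mask <- cand
  }
  st <- fcm_cluster(conc, c = c, m = m, tol = tol, max_iter = max_iter,
                    seed = seed)
  d <- dim(conc$conc)
  Xraw <- matrix(conc$conc, ncol = d[4])[st$voxel_index, , drop = FALSE]
  assign <- max.col(st$membership, ties.method = "first")
  costs <- rep(Inf, nrow(st$centroids))
  curves <- matrix(0, nrow(st$centroids), d[4])
  for (k in seq_len(nrow(st$centroids))) {
    rows <- which(assign == k)
    if (!length(rows)) next
    curves[k, ] <- colMeans(Xraw[rows, , drop = FALSE])
    costs[k] <- aif_cost(curves[k, ], conc$frame_times_s)
  }
  if (all(!is.finite(costs)))
    stop("no cluster has a positive mean curve", call. = FALSE)
  k_best <- which.min(costs)
  roi <- array(0L, dim = d[1:3])
  roi[st$voxel_index[assign == k_best]] <- 1L
  curve <- curves[k_best, ]
  structure(list(roi = volume_mask(roi, conc$voxel_mm), curve = curve,
                 characteristics = curve_characteristics(
                   curve, conc$frame_times_s),
                 cluster = k_best, costs = costs, fcm = st),
            class = "aif_result")
}

#' @export
print.aif_result <- function(x, ...) {
  ch <- x$characteristics
  cat(sprintf(
    "<aif_result> %d ROI voxels | amplitude %.3g, center %.3g s, width %.3g s\n",
    sum(x$roi$mask), ch$amplitude, ch$center_s, ch$width_s))
  invisible(x)
}
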