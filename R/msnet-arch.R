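#' Multi-stream 3D CNN configuration
#'
#' Both streams share one topology: eight 3x3x3 convolution layers
#' (stride 1, same padding, ReLU), five max-pooling layers placed after
#' convolutions 1, 2, 4, 6 and 8, two fully connected layers, and a
#' 2-class softmax output. The spatial stream treats the patch as an
#' in-plane-by-slice volume with one input channel per frame; the
#' temporal stream treats it as an in-plane-by-frame volume with one
#' channel per slice, and its first pooling uses kernel and stride
#' 2x2x1 so the early layers keep full temporal resolution.
#'
#' Two presets are provided: `"full"` — filters 64, 128, 256, 256,
#' 512, 512, 512, 512, 4096-unit fully connected layers, 32-voxel
#' patches — and `"desk"`, an architecture-isomorphic scale-down
#' (filters 8, 16, 32, 32, 64, 64, 64, 64, 256 fully connected units,
#' 16-voxel patches) that trains in minutes on one CPU.
#'
#' @param preset `"desk"` or `"full"`.
#' @param conv_filters length-8 integer vector of filter counts.
#' @param kernel 3D convolution kernel size (only 3x3x3 is supported).
#' @param fc_units units in each fully connected layer.
#' @param pool_kernels,pool_strides lists of five length-3 vectors
#'   (the temporal stream's first pool is forced to 2x2x1 at build
#'   time).
#' @param patch_wh in-plane patch size in voxels (>= 16).
#' @param slices_per_patch slices per patch (clamped to the data).
#' @param classes number of output classes (2).
#' @return A `net_config` list.
#' @export
net_config <- function(preset = c("desk", "full"), conv_filters = NULL,
                       kernel = c(3, 3, 3), fc_units = NULL,
                       pool_kernels = rep(list(c(2, 2, 2)), 5),
                       pool_strides = rep(list(c(2, 2, 2)), 5),
                       patch_wh = NULL, slices_per_patch = 8L,
                       classes = 2L) {
  preset <- match.arg(preset)
  if (is.null(conv_filters))
    conv_filters <- if (preset == "full")
      c(64, 128, 256, 256, 512, 512, 512, 512) else
        c(8, 16, 32, 32, 64, 64, 64, 64)
  if (is.null(fc_units)) fc_units <- if (preset == "full") 4096L else 256L
  if (is.null(patch_wh)) patch_wh <- if (preset == "full") 32L else 16L
  stopifnot(length(conv_filters) == 8, all(conv_filters >= 1),
            identical(as.numeric(kernel), c(3, 3, 3)),
            length(pool_kernels) == 5, length(pool_strides) == 5,
            classes == 2L)
  if (patch_wh < 16)
    stop(sprintf(
      "patch_wh = %d too small for five pooling stages; minimum is 16",
      patch_wh), call. = FALSE)
  structure(list(preset = preset, conv_filters = as.integer(conv_filters),
                 kernel = c(3L, 3L, 3L), fc_units = as.integer(fc_units),
                 pool_kernels = pool_kernels, pool_strides = pool_strides,
                 patch_wh = as.integer(patch_wh),
                 slices_per_patch = as.integer(slices_per_patch),
                 classes = 2L), class = "net_config")
}

POOL_AFTER <- c(1L, 2L, 4L, 6L, 8L)

#' Architecture summary of one stream
#'
#' Computes, without allocating weights, the layer sequence and
#' per-stage feature-map dimensions for one stream on a given patch
#' geometry, including the flattened size feeding the first fully
#' connected layer.
#'
#' @param cfg a [net_config].
#' @param stream `"spatial"` or `"temporal"`.
#' @param n_frames frames per patch (f).
#' @param n_slices slices per patch (s_p).
#' @return List: `in_channels`, `in_dims`, `layers` (data.frame of
#'   type/filters/output dims), `flat_size`, `pool_kernels`,
#'   `pool_strides`, `n_conv`, `n_pool`, `n_fc`.
#' @export
net_architecture <- function(cfg, stream = c("spatial", "temporal"),
                             n_frames, n_slices) {
  stream <- match.arg(stream)
  stopifnot(inherits(cfg, "net_config"))
  pk <- cfg$pool_kernels
  ps <- cfg$pool_strides
  if (stream == "temporal") {
    pk[[1]] <- c(2, 2, 1)   # keep temporal resolution in the early stage
    ps[[1]] <- c(2, 2, 1)
  }
  if (stream == "spatial") {
    in_ch <- n_frames
    dims <- c(cfg$patch_wh, cfg$patch_wh, n_slices)
  } else {
    in_ch <- n_slices
    dims <- c(cfg$patch_wh, cfg$patch_wh, n_frames)
  }
  rows <- list()
  ip <- 0L
  for (i in 1:8) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "conv", filters = cfg$conv_filters[i],
      d1 = dims[1], d2 = dims[2], d3 = dims[3])
    if (i %in% POOL_AFTER) {
      ip <- ip + 1L
      dims <- ceiling(dims / ps[[ip]])   # ceil-mode pooling
      rows[[length(rows) + 1L]] <- data.frame(
        type = "pool", filters = cfg$conv_filters[i],
        d1 = dims[1], d2 = dims[2], d3 = dims[3])
    }
  }
  flat <- cfg$conv_filters[8] * prod(dims)
  rows[[length(rows) + 1L]] <- data.frame(type = "fc",
                                          filters = cfg$fc_units,
                                          d1 = 1, d2 = 1, d3 = 1)
  rows[[length(rows) + 1L]] <- data.frame(type = "fc",
                                          filters = cfg$fc_units,
                                          d1 = 1, d2 = 1, d3 = 1)
  rows[[length(rows) + 1L]] <- data.frame(type = "softmax", filters = 2,
                                          d1 = 1, d2 = 1, d3 = 1)
  layers <- do.call(rbind, rows)
  list(in_channels = in_ch,
       in_dims = if (stream == "spatial")
         c(cfg$patch_wh, cfg$patch_wh, n_slices) else
           c(cfg$patch_wh, cfg$patch_wh, n_frames),
       layers = layers, flat_size = flat,
       pool_kernels = pk, pool_strides = ps,
       n_conv = sum(layers$type == "conv"),
       n_pool = sum(layers$type == "pool"),
       n_fc = sum(layers$type == "fc"))
}

#' Analytic parameter count of one stream
#'
#' @inheritParams net_architecture
#' @return Total number of trainable weights and biases.
#' @export
net_param_count <- function(cfg, stream = c("spatial", "temporal"),
                            n_frames, n_slices) {
  arch <- net_architecture(cfg, stream, n_frames, n_slices)
  cin <- c(arch$in_channels, cfg$conv_filters[1:7])
  n <- sum(27 * cin * cfg$conv_filters + cfg$conv_filters)
  n <- n + arch$flat_size * cfg$fc_units + cfg$fc_units
  n <- n + cfg$fc_units * cfg$fc_units + cfg$fc_units
  n + cfg$fc_units * 2 + 2
}

#' Build an untrained stream model
#'
#' Allocates He-initialized weights for one stream; deterministic given
#' `seed`.
#'
#' @inheritParams net_architecture
#' @param seed RNG seed for initialization.
#' @return A `stream_model`.
#' @export
build_stream <- function(cfg, stream = c("spatial", "temporal"),
                         n_frames, n_slices, seed = 1L) {
  stream <- match.arg(stream)
  arch <- net_architecture(cfg, stream, n_frames, n_slices)
  set.seed(as.integer(seed))
  cin <- c(arch$in_channels, cfg$conv_filters[1:7])
  conv <- lapply(1:8, function(i) {
    fan_in <- 27 * cin[i]
    list(W = matrix(rnorm(cfg$conv_filters[i] * fan_in,
                          sd = sqrt(2 / fan_in)),
                    cfg$conv_filters[i], fan_in),
         b = numeric(cfg$conv_filters[i]))
  })
  fc <- function(n_out, n_in)
    list(W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
         b = numeric(n_out))
  structure(list(stream = stream, cfg = cfg, arch = arch,
                 n_frames = as.integer(n_frames),
                 n_slices = as.integer(n_slices),
                 conv = conv,
                 fc1 = fc(cfg$fc_units, arch$flat_size),
                 fc2 = fc(cfg$fc_units, cfg$fc_units),
                 out = fc(2L, cfg$fc_units)),
            class = "stream_model")
}

#' @export
print.stream_model <- function(x, ...) {
  cat(sprintf(
    "<stream_model> %s stream, %s preset | %d conv + %d pool + %d fc | %s parameters\n",
    x$stream, x$cfg$preset, x$arch$n_conv, x$arch$n_pool, x$arch$n_fc,
    format(net_param_count(x$cfg, x$stream, x$n_frames, x$n_slices),
           big.mark = ",")))
  invisible(x)
}

# Rearrange a canonical (wh, wh, s_p, f) patch into a stream input matrix
# (channels x voxels): spatial -> f channels over a (w, h, s) volume,
# temporal -> s_p channels over a (w, h, f) volume.
stream_input <- function(patch, stream) {
  d <- dim(patch)
  if (stream == "spatial") {
    t(matrix(patch, d[1] * d[2] * d[3], d[4]))
  } else {
    t(matrix(aperm(patch, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
  }
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Forward pass for one sample. X is the channels x voxels input matrix.
# Returns probabilities and, when `keep_cache`, everything backward needs.
forward_stream <- function(model, X, keep_cache = FALSE) {
  arch <- model$arch
  dims <- arch$in_dims
  cache <- if (keep_cache) list(conv = vector("list", 8)) else NULL
  ip <- 0L
  for (i in 1:8) {
    Z <- .conv3_forward(X, dims[1], dims[2], dims[3],
                        model$conv[[i]]$W, model$conv[[i]]$b)
    mask <- Z > 0
    A <- Z * mask
    if (keep_cache)
      cache$conv[[i]] <- list(X = X, dims = dims, mask = mask)
    if (i %in% POOL_AFTER) {
      ip <- ip + 1L
      k <- arch$pool_kernels[[ip]]
      s <- arch$pool_strides[[ip]]
      pl <- .pool3_forward(A, dims[1], dims[2], dims[3],
                           k[1], k[2], k[3], s[1], s[2], s[3])
      if (keep_cache) cache$conv[[i]]$pool <-
          list(argmax = pl$argmax, vin = ncol(A))
      X <- pl$Y
      dims <- pl$dims
    } else X <- A
  }
  flat <- as.vector(X)
  h1 <- pmax(model$fc1$W %*% flat + model$fc1$b, 0)
  h2 <- pmax(model$fc2$W %*% h1 + model$fc2$b, 0)
  logits <- model$out$W %*% h2 + model$out$b
  p <- softmax2(as.vector(logits))
  if (keep_cache) {
    cache$flat <- flat; cache$h1 <- h1; cache$h2 <- h2
    cache$final_shape <- dim(X)
  }
  list(p = p, cache = cache)
}

# Backward pass for one sample; dlogits = p - onehot(y).
# Returns gradients with the same shapes as the model weights.
backward_stream <- function(model, cache, dlogits) {
  g <- list()
  dlogits <- matrix(dlogits, ncol = 1)
  g$out <- list(W = dlogits %*% t(cache$h2), b = as.vector(dlogits))
  dh2 <- (t(model$out$W) %*% dlogits) * (cache$h2 > 0)
  g$fc2 <- list(W = dh2 %*% t(cache$h1), b = as.vector(dh2))
  dh1 <- (t(model$fc2$W) %*% dh2) * (cache$h1 > 0)
  g$fc1 <- list(W = dh1 %*% t(cache$flat), b = as.vector(dh1))
  dflat <- t(model$fc1$W) %*% dh1
  dX <- matrix(dflat, cache$final_shape[1], cache$final_shape[2])
  g$conv <- vector("list", 8)
  for (i in 8:1) {
    cc <- cache$conv[[i]]
    if (!is.null(cc$pool))
      dX <- .pool3_backward(dX, cc$pool$argmax, cc$pool$vin)
    dZ <- dX * cc$mask
    bw <- .conv3_backward(cc$X, cc$dims[1], cc$dims[2], cc$dims[3],
                          model$conv[[i]]$W, dZ)
    g$conv[[i]] <- list(W = bw$dW, b = as.vector(bw$db))
    dX <- bw$dX
  }
  g
}
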