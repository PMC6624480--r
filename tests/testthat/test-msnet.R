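test_that("network presets match the full-scale architecture", {
  full <- net_config("full")
  expect_equal(full$conv_filters, c(64, 128, 256, 256, 512, 512, 512, 512))
  expect_equal(full$fc_units, 4096L)
  expect_equal(full$kernel, c(3L, 3L, 3L))
  arch_s <- net_architecture(full, "spatial", n_frames = 50, n_slices = 8)
  arch_t <- net_architecture(full, "temporal", n_frames = 50, n_slices = 8)
  # eight convolution, five pooling, two fully connected layers
  expect_equal(arch_s$n_conv, 8)
  expect_equal(arch_s$n_pool, 5)
  expect_equal(arch_s$n_fc, 2)
  # the temporal stream's first pool preserves the frame axis
  expect_equal(arch_t$pool_kernels[[1]], c(2, 2, 1))
  expect_equal(arch_t$pool_strides[[1]], c(2, 2, 1))
  expect_equal(arch_s$pool_kernels[[1]], c(2, 2, 2))
  expect_error(net_config("desk", patch_wh = 8), "minimum")
})

test_that("desk preset stays under 5M parameters and matches its formula", {
  desk <- net_config("desk")
  for (stream in c("spatial", "temporal")) {
    n_analytic <- net_param_count(desk, stream, n_frames = 40,
                                  n_slices = 8)
    expect_lt(n_analytic, 5e6)
    m <- build_stream(desk, stream, n_frames = 40, n_slices = 8, seed = 1)
    n_actual <- sum(vapply(m$conv, function(l) length(l$W) + length(l$b),
                           1)) +
      length(m$fc1$W) + length(m$fc1$b) + length(m$fc2$W) +
      length(m$fc2$b) + length(m$out$W) + length(m$out$b)
    expect_identical(n_actual, as.numeric(n_analytic))
  }
})

test_that("forward pass produces normalized softmax scores", {
  cfg <- tiny_net()
  set.seed(3)
  for (stream in c("spatial", "temporal")) {
    m <- build_stream(cfg, stream, n_frames = 6, n_slices = 2, seed = 5)
    patch <- array(rnorm(16 * 16 * 2 * 6), c(16, 16, 2, 6))
    p <- perfaid:::forward_stream(m, perfaid:::stream_input(patch, stream))$p
    expect_length(p, 2)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- tiny_net()
  m <- build_stream(cfg, "temporal", n_frames = 5, n_slices = 2, seed = 3)
  set.seed(9)
  patch <- array(rnorm(16 * 16 * 2 * 5), c(16, 16, 2, 5))
  X <- perfaid:::stream_input(patch, "temporal")
  lossf <- function(model) -log(perfaid:::forward_stream(model, X)$p[2])
  fw <- perfaid:::forward_stream(m, X, keep_cache = TRUE)
  dlog <- fw$p; dlog[2] <- dlog[2] - 1
  g <- perfaid:::backward_stream(m, fw$cache, dlog)
  eps <- 1e-6
  pick <- function(W, gW, set) {
    for (i in sample(length(W), 4)) {
      mp <- set(m, replace(W, i, W[i] + eps))
      mm <- set(m, replace(W, i, W[i] - eps))
      num <- (lossf(mp) - lossf(mm)) / (2 * eps)
      expect_lt(abs(gW[i] - num), 1e-5)
    }
  }
  pick(m$conv[[1]]$W, g$conv[[1]]$W,
       function(m, W) { m$conv[[1]]$W <- W; m })
  pick(m$conv[[6]]$W, g$conv[[6]]$W,
       function(m, W) { m$conv[[6]]$W <- W; m })
  pick(m$fc1$W, g$fc1$W, function(m, W) { m$fc1$W <- W; m })
  pick(m$out$W, g$out$W, function(m, W) { m$out$W <- W; m })
})

test_that("label growing follows correlation and amplitude rules", {
  f <- 20
  tt <- (0:(f - 1)) * 1.5
  art <- gamma_variate(tt, gamma_params(40, 6, 3, 1.5))
  d <- c(8, 8, 1, f)
  arr <- array(0, dim = d)
  for (x in 1:8) for (y in 1:8) arr[x, y, 1, ] <- 0.05 * art
  arr[4, 4, 1, ] <- art
  arr[4, 5, 1, ] <- 0.9 * art                 # correlated, high peak
  arr[5, 4, 1, ] <- 0.3 * art                 # correlated but peak < 50%
  arr[4, 3, 1, ] <- max(art) - art            # anticorrelated neighbour
  conc <- structure(list(conc = arr, frame_times_s = tt,
                         brain_mask = volume_mask(array(1L, d[1:3])),
                         baseline_frames = 3L, te_s = 0.0026,
                         voxel_mm = c(1, 1, 1), log = list()),
                    class = "concentration_series")
  roi <- array(0L, d[1:3]); roi[4, 4, 1] <- 1L
  # identity limit: zero radius, perfect correlation required
  lab0 <- make_labels(conc, volume_mask(roi), r_voxels = 0, corr_min = 1)
  expect_identical(lab0$mask, roi)
  lab <- make_labels(conc, volume_mask(roi), r_voxels = 1, corr_min = 0.9)
  expect_equal(lab$mask[4, 4, 1], 1L)
  expect_equal(lab$mask[4, 5, 1], 1L)
  expect_equal(lab$mask[5, 4, 1], 0L)         # amplitude rule
  expect_equal(lab$mask[4, 3, 1], 0L)         # anticorrelated
  expect_error(make_labels(conc, volume_mask(array(0L, d[1:3]))), "empty")
})

test_that("phantom labels stay near the vessel with high precision", {
  ph <- make_phantom(desk_cfg(), seed = 17)
  conc <- signal_to_concentration(ph$series)
  lab <- make_labels(conc, ph$vessel_truth, r_voxels = 1, corr_min = 0.9)
  dil <- ph$vessel_truth$mask > 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    dil <- dil | perfaid:::shift3(ph$vessel_truth$mask > 0, dx, dy, dz,
                                  FALSE)
  expect_true(all(dil[lab$mask > 0]))         # labels within the dilation
  sc <- segmentation_scores(lab, ph$vessel_truth)
  expect_gte(sc$precision, 0.9)
})

test_that("patch extraction counts, pairs and determinism hold", {
  ph <- make_phantom(tiny_cfg(), seed = 4)
  conc <- signal_to_concentration(ph$series)
  lab <- array(0L, dim(ph$brain_mask$mask))
  pos <- which(ph$vessel_truth$mask > 0)[1]
  lab[pos] <- 1L
  ps <- extract_patches(conc, volume_mask(lab), patch_wh = 16,
                        slices_per_patch = 4, neg_ratio = 3, seed = 2)
  expect_equal(length(ps$labels), 4)          # 1 positive + 3 negatives
  expect_equal(sum(ps$labels), 1)
  # stream tensors are axis permutations of one another
  sp <- patch_stream_tensor(ps, 1, "spatial")
  tp <- patch_stream_tensor(ps, 1, "temporal")
  expect_equal(dim(sp), c(20, 4, 16, 16))
  expect_equal(dim(tp), c(4, 20, 16, 16))
  expect_equal(aperm(sp, c(2, 1, 3, 4)), tp)
  # determinism of negative sampling
  ps2 <- extract_patches(conc, volume_mask(lab), patch_wh = 16,
                         slices_per_patch = 4, neg_ratio = 3, seed = 2)
  expect_identical(ps$provenance, ps2$provenance)
  expect_identical(ps$patches, ps2$patches)
  expect_error(extract_patches(conc, volume_mask(lab * 0L)), "positive")
})

test_that("stream training learns separable patches deterministically", {
  ps <- separable_patches(30, 30, sp = 2L, f = 6L, seed = 2)
  cfg <- tiny_net()
  tcfg <- train_config("desk", batch = 8, epochs = 10, lr = 0.05,
                       seed = 7)
  m0 <- build_stream(cfg, "temporal", n_frames = 6, n_slices = 2, seed = 1)
  m1 <- train_stream(m0, ps, tcfg)
  acc <- mean((predict_stream(m1, ps)[, 2] > 0.5) == (ps$labels == 1))
  expect_gte(acc, 0.95)
  expect_true(all(diff(range(m1$loss_trace)) > 0))
  # identical seeds give bit-identical training
  m2 <- train_stream(m0, ps, tcfg)
  expect_identical(m1$conv[[1]]$W, m2$conv[[1]]$W)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # zero learning rate leaves the loss trace flat
  mz <- train_stream(m0, ps, train_config("desk", batch = 8, epochs = 3,
                                          lr = 0, seed = 7))
  expect_equal(mz$loss_trace, rep(mz$loss_trace[1], 3), tolerance = 1e-12)
  expect_identical(mz$conv[[3]]$W, m0$conv[[3]]$W)
  # single-class data is rejected
  ps1 <- ps; ps1$labels <- rep(1L, length(ps$labels))
  expect_error(train_stream(m0, ps1, tcfg), "class")
})

test_that("more separable training data never hurts accuracy much", {
  cfg <- tiny_net()
  accs <- sapply(c(20, 40, 60), function(n) {
    ps <- separable_patches(n / 2, n / 2, sp = 2L, f = 6L, seed = 3)
    tcfg <- train_config("desk", batch = 8, epochs = 10, lr = 0.05,
                         seed = 5)
    m <- build_stream(cfg, "temporal", n_frames = 6, n_slices = 2,
                      seed = 2)
    m <- train_stream(m, ps, tcfg)
    mean((predict_stream(m, ps)[, 2] > 0.5) == (ps$labels == 1))
  })
  expect_true(all(diff(accs) >= -0.02))
})

test_that("SVM late fusion respects its contracts", {
  set.seed(6)
  n <- 60
  lab <- rep(c(0L, 1L), n / 2)
  # streams agree and are confident: fusion reproduces them
  s1 <- cbind(1 - lab, lab) * 0.98 + 0.01
  fm <- fuse_svm(s1, s1, lab)
  expect_equal(apply_fusion(fm, s1, s1), lab)
  # linearly separable scores: perfect fused accuracy
  p_a <- runif(n, 0.3, 0.7)
  p_b <- ifelse(lab == 1, runif(n, 0.55, 0.95), runif(n, 0.05, 0.45))
  sA <- cbind(1 - p_a, p_a)
  sB <- cbind(1 - p_b, p_b)
  fm2 <- fuse_svm(sA, sB, lab)
  expect_equal(apply_fusion(fm2, sA, sB), lab)
  # permuting the sample order leaves predictions unchanged
  perm <- sample(n)
  fm3 <- fuse_svm(sA[perm, ], sB[perm, ], lab[perm])
  expect_equal(apply_fusion(fm3, sA, sB), apply_fusion(fm2, sA, sB))
  expect_error(fuse_svm(sA * 2, sB, lab), "sum to 1")
  expect_error(fuse_svm(sA, sB, rep(1, n)), "single class")
})
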