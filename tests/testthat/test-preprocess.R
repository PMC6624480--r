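test_that("brain masking recovers the phantom brain and is idempotent", {
  ph <- make_phantom(tiny_cfg(), seed = 6)
  m <- brain_mask(ph$series)
  agree <- mean(m$mask == ph$brain_mask$mask)
  expect_gte(agree, 0.99)
  # masking an already-masked series returns the same mask
  masked <- ph$series
  masked$signal <- masked$signal *
    array(m$mask, dim = dim(masked$signal))
  expect_identical(brain_mask(masked)$mask, m$mask)
  # degenerate input
  flat <- perfusion_series(array(0, c(8, 8, 2, 4)), 1, 0.001)
  expect_error(brain_mask(flat), "degenerate")
})

test_that("slice-time correction interpolates linearly with clamped ends", {
  tt <- 0:9 * 2
  offs <- c(0, 0.5, 1.2)
  lin <- function(t) 5 + 3 * t                      # true signal s(t)
  x <- array(0, dim = c(4, 4, 3, 10))
  for (z in 1:3) for (k in 1:10)
    x[, , z, k] <- lin(tt[k] + offs[z])             # sampled at t_k + offset
  ser <- perfusion_series(x, tr_s = 2, te_s = 0.001)
  out0 <- slice_time_correct(ser, c(0, 0, 0))
  expect_identical(out0$signal, x)                  # zero offsets: identity
  out <- slice_time_correct(ser, offs)
  # linear signals land exactly on the common grid away from the clamped
  # first frame
  for (z in 1:3) for (k in 2:10)
    expect_equal(unname(out$signal[1, 1, z, k]), lin(tt[k]),
                 tolerance = 1e-12)
  # closed-form check on a sinusoid, offset TR/2
  y <- sin(tt / 3)
  xs <- array(rep(y, each = 16), dim = c(4, 4, 1, 10))
  # sample times are tt + 1; value at target tt[k] interpolates samples k-1, k
  sers <- perfusion_series(xs + 2, tr_s = 2, te_s = 0.001)
  outs <- slice_time_correct(sers, 1)
  ys <- y + 2
  expected <- c(ys[1], (ys[1:9] + ys[2:10]) / 2)[2:10]
  expect_equal(as.vector(outs$signal[1, 1, 1, 2:10]), expected,
               tolerance = 1e-12)
  expect_error(slice_time_correct(ser, c(0, 0)), "per slice")
  expect_error(slice_time_correct(ser, c(0, 0, 2.5)), "TR")
})

test_that("spatial smoothing preserves constants and matches the kernel", {
  ph <- make_phantom(tiny_cfg(), seed = 2)
  expect_identical(smooth_spatial(ph$series, 0)$signal, ph$series$signal)
  expect_error(smooth_spatial(ph$series, -1), ">= 0")
  const <- perfusion_series(array(7, c(16, 16, 2, 3)), 1, 0.001,
                            voxel_mm = c(1, 1, 1))
  sm <- smooth_spatial(const, 1.5)
  expect_equal(as.vector(sm$signal), rep(7, length(sm$signal)),
               tolerance = 1e-12)
  # interior impulse reproduces the separable discrete Gaussian kernel
  imp <- array(0, c(17, 17, 1, 2)); imp[9, 9, 1, ] <- 1
  serimp <- perfusion_series(imp, 1, 0.001, voxel_mm = c(1, 1, 1))
  smi <- smooth_spatial(serimp, 1)
  r <- 3  # ceiling(3 * sigma_vox)
  k1 <- exp(-(-r:r)^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(smi$signal[6:12, 6:12, 1, 1], outer(k1, k1),
               tolerance = 1e-12)
})

test_that("drift removal recovers gamma curves under a linear ramp", {
  f <- 40
  tt <- (0:(f - 1)) * 1.5
  gam <- gamma_variate(tt, gamma_params(40, 9, 3, 1.2))
  mk_conc <- function(curves) {
    arr <- array(0, dim = c(nrow(curves), 1, 1, f))
    arr[, 1, 1, ] <- curves
    structure(list(conc = arr, frame_times_s = tt,
                   brain_mask = volume_mask(array(1L, c(nrow(curves), 1, 1))),
                   baseline_frames = 5L, te_s = 0.0026,
                   voxel_mm = c(1, 1, 1), log = list()),
              class = "concentration_series")
  }
  # drift-free: unchanged (gamma tail is ~0 at 58 s)
  out <- remove_drift(mk_conc(rbind(gam)), tail_frames = 5)
  expect_equal(as.vector(out$conc[1, 1, 1, ]), gam, tolerance = 1e-8)
  # pure ramp: all zero
  ramp <- 0.3 + 0.05 * tt
  out2 <- remove_drift(mk_conc(rbind(ramp)), tail_frames = 5)
  expect_lt(max(abs(out2$conc)), 1e-10)
  # gamma + ramp: gamma recovered
  out3 <- remove_drift(mk_conc(rbind(gam + ramp)), tail_frames = 5)
  expect_lt(max(abs(as.vector(out3$conc[1, 1, 1, ]) - gam)), 1e-6)
})

test_that("signal-concentration conversion is the exact model inverse", {
  f <- 10
  te <- 0.0026
  s0 <- 900
  cval <- matrix(rep(c(0, 0, 0, 40, 120, 80, 30, 10, 2, 0), each = 64),
                 64, f, byrow = FALSE)
  sig <- array(s0 * exp(-te * cval), dim = c(8, 8, 1, f))
  ser <- perfusion_series(sig, 1.5, te)
  mask <- volume_mask(array(1L, c(8, 8, 1)))
  conc <- signal_to_concentration(ser, baseline_frames = 3, mask = mask)
  expect_equal(matrix(conc$conc, ncol = f), cval, tolerance = 1e-10)
  # S = S0 everywhere -> C = 0
  serc <- perfusion_series(array(500, c(4, 4, 2, 5)), 1, te)
  conc0 <- signal_to_concentration(serc, 2, volume_mask(array(1L, c(4, 4, 2))))
  expect_true(all(conc0$conc == 0))
  # decreasing signal => increasing concentration, pointwise
  s_dec <- seq(800, 400, length.out = f)
  ser2 <- perfusion_series(array(rep(s_dec, each = 4), c(2, 2, 1, f)),
                           1, te)
  c2 <- signal_to_concentration(ser2, 2, volume_mask(array(1L, c(2, 2, 1))))
  expect_true(all(diff(c2$conc[1, 1, 1, ]) > 0))
  # voxels with non-positive S0 are excluded from the mask, logged
  sig_bad <- array(500, c(4, 4, 1, 5)); sig_bad[1, 1, 1, ] <- 0
  conc_b <- signal_to_concentration(
    perfusion_series(sig_bad, 1, te), 2,
    volume_mask(array(1L, c(4, 4, 1))))
  expect_equal(conc_b$log$n_s0_excluded, 1)
  expect_equal(conc_b$brain_mask$mask[1, 1, 1], 0L)
})

test_that("full chain preserves the arterial curve shape on a noiseless phantom", {
  ph <- make_phantom(desk_cfg(noise_sd = 0), seed = 21)
  conc <- preprocess_series(ph$series)
  C <- matrix(conc$conc, ncol = dim(conc$conc)[4])
  art <- colMeans(C[ph$vessel_truth$mask > 0, ])
  expect_gte(cor(art, ph$aif_truth), 0.999)
})
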