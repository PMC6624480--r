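aif_40 <- function(f = 40, dt = 1.5)
  gamma_variate((0:(f - 1)) * dt, gamma_params(40, 9, 3, 1.5))

test_that("the convolution matrix implements the left-Riemann sum", {
  f <- 12; dt <- 1.5
  aif <- aif_40(f, dt)
  A <- conv_matrix(aif, dt)
  set.seed(1)
  r <- runif(f)
  direct <- sapply(seq_len(f), function(i)
    dt * sum(aif[seq_len(i)] * r[i - seq_len(i) + 1]))
  expect_equal(as.vector(A %*% r), direct, tolerance = 1e-12)
  expect_true(all(A[upper.tri(A)] == 0))
})

test_that("truncated-SVD deconvolution recovers known residues", {
  f <- 40; dt <- 1.5
  tt <- (0:(f - 1)) * dt
  aif <- aif_40()
  A <- conv_matrix(aif, dt)
  set.seed(11)
  for (i in 1:50) {
    cbf <- runif(1, 0.008, 0.012)
    mtt <- runif(1, 3, 8)
    delay <- dt * sample(0:4, 1)
    R <- cbf * exp(-pmax(tt - delay, 0) / mtt) * (tt >= delay)
    Ctis <- as.vector(A %*% R)
    Rh <- as.vector(deconvolve_curves(matrix(Ctis, 1), aif, dt, 1e-6))
    expect_lt(sqrt(sum((Rh - R)^2) / sum(R^2)), 0.01)
    expect_lt(abs(max(Rh) - cbf) / cbf, 0.05)
    expect_lte(abs(dt * (which.max(Rh) - 1) - delay), dt)
  }
  # zero tissue curve -> zero residue; joint scaling leaves residue fixed
  expect_true(all(deconvolve_curves(matrix(0, 1, f), aif, dt, 1e-6) == 0))
  r1 <- deconvolve_curves(matrix(A %*% (0.01 * exp(-tt / 4)), 1), aif,
                          dt, 1e-4)
  r2 <- deconvolve_curves(matrix(3 * A %*% (0.01 * exp(-tt / 4)), 1),
                          3 * aif, dt, 1e-4)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(deconvolve_curves(matrix(0, 1, f), rep(0, f), dt, 1e-6),
               "zero")
  expect_error(deconvolve_curves(matrix(0, 1, f), aif, dt, 2), "lambda")
})

test_that("Tmax is the residue peak time with shift equivariance", {
  d <- c(2, 2, 1, 8)
  res <- structure(list(residue = array(0, d), dt_s = 1.5,
                        brain_mask = volume_mask(array(1L, d[1:3])),
                        voxel_mm = c(1, 1, 1)), class = "residue_map")
  res$residue[1, 1, 1, ] <- c(5, 1, 0, 0, 0, 0, 0, 0)  # peak frame 1
  res$residue[2, 1, 1, ] <- c(0, 0, 5, 1, 0, 0, 0, 0)  # shifted by 2
  res$residue[1, 2, 1, ] <- c(1, 1, 1, 1, 1, 1, 1, 1)  # tie: earliest
  tm <- tmax_map(res)
  expect_equal(tm[1, 1, 1], 0)
  expect_equal(tm[2, 1, 1], 2 * 1.5)
  expect_equal(tm[1, 2, 1], 0)
})

test_that("rCBF normalization and lesion contrast behave on phantoms", {
  # homogeneous phantom: no lesion, constant tissue parameters
  cfg <- desk_cfg(noise_sd = 0, lesion = NULL,
                  cbf_range = c(0.01, 0.01), mtt_range_s = c(4, 4),
                  delay_max_s = 0)
  ph <- make_phantom(cfg, seed = 3)
  conc <- signal_to_concentration(ph$series, 5, ph$brain_mask)
  res <- deconvolve(conc, ph$aif_truth, lambda_rel = 1e-6)
  rc <- rcbf_map(res)
  tis <- ph$brain_mask$mask > 0 & ph$vessel_truth$mask == 0
  expect_lt(max(abs(rc[tis] - 1)), 0.05)
  # doubling concentrations leaves rCBF unchanged
  conc2 <- conc; conc2$conc <- conc$conc * 2
  rc2 <- rcbf_map(deconvolve(conc2, ph$aif_truth, lambda_rel = 1e-6))
  expect_equal(rc2, rc, tolerance = 1e-9)
  # 40% lesion shows as a 0.40 rCBF ratio
  phL <- make_phantom(desk_cfg(noise_sd = 0), seed = 3)
  concL <- signal_to_concentration(phL$series, 5, phL$brain_mask)
  resL <- deconvolve(concL, phL$aif_truth, lambda_rel = 1e-6)
  rcL <- rcbf_map(resL)
  les <- phL$lesion_mask$mask > 0
  bg <- phL$brain_mask$mask > 0 & !les & phL$vessel_truth$mask == 0
  expect_equal(median(rcL[les]) / median(rcL[bg]), 0.40,
               tolerance = 0.05 / 0.40)
  # contralateral mode runs and normalizes each hemisphere
  rcc <- rcbf_map(resL, "contralateral")
  expect_true(all(is.finite(rcc)))
})

test_that("CBV and MTT follow the central volume theorem", {
  # finer frame grid: the left-Riemann convolution kernel biases the
  # embedded residue area by ~dt/2, so MTT recovery needs dt << MTT
  cfg <- desk_cfg(dims = c(64, 64, 8, 80), dt_s = 0.75, noise_sd = 0,
                  lesion = NULL, mtt_range_s = c(6, 6), delay_max_s = 0)
  ph <- make_phantom(cfg, seed = 9)
  conc <- signal_to_concentration(ph$series, 5, ph$brain_mask)
  res <- deconvolve(conc, ph$aif_truth, lambda_rel = 1e-6)
  cm <- cbv_mtt_maps(conc, ph$aif_truth, res)
  tis <- ph$brain_mask$mask > 0 & ph$vessel_truth$mask == 0
  expect_lt(max(abs(cm$mtt_s[tis] - 6) / 6), 0.10)
  # tissue curve identical to the AIF -> CBV = 1
  f <- 80
  v <- which(ph$vessel_truth$mask > 0)[1]
  conc_id <- conc
  arr <- matrix(conc_id$conc, ncol = f)
  arr[v, ] <- ph$aif_truth
  conc_id$conc <- array(arr, dim = dim(conc$conc))
  cm2 <- cbv_mtt_maps(conc_id, ph$aif_truth, res)
  expect_equal(cm2$cbv[v], 1, tolerance = 1e-9)
  # zero curve -> cbv = 0, mtt = 0
  outside <- which(ph$brain_mask$mask == 0)[1]
  expect_equal(cm$cbv[outside], 0)
  expect_equal(cm$mtt_s[outside], 0)
  expect_error(cbv_mtt_maps(conc, rep(0, f), res), "> 0")
})

test_that("mismatch arithmetic matches the worked example", {
  tm <- array(0, c(10, 10, 2))
  tm[seq_len(100)] <- 10                  # 100 ischemic voxels
  adc <- array(800, c(10, 10, 2))
  adc[seq_len(20)] <- 500                 # 20 core voxels
  rep_ <- mismatch(tm, adc, voxel_mm = c(1, 1, 1))
  expect_equal(rep_$ischemic_volume_ml, 0.1)
  expect_equal(rep_$core_volume_ml, 0.02)
  expect_equal(rep_$mismatch_volume_ml, 0.08)
  expect_equal(rep_$mismatch_ratio, 4.0)
  expect_false(rep_$infinite_ratio)
  # empty core: infinite flag, mismatch = ischemic volume
  rep_inf <- mismatch(tm, array(800, c(10, 10, 2)), c(1, 1, 1))
  expect_true(rep_inf$infinite_ratio)
  expect_equal(rep_inf$mismatch_ratio, Inf)
  expect_equal(rep_inf$mismatch_volume_ml, rep_inf$ischemic_volume_ml)
  # nothing ischemic, nothing infarcted: everything 0, ratio undefined
  rep_0 <- mismatch(array(0, c(10, 10, 2)), array(800, c(10, 10, 2)),
                    c(1, 1, 1))
  expect_equal(rep_0$ischemic_volume_ml, 0)
  expect_true(rep_0$undefined_ratio)
  expect_true(is.na(rep_0$mismatch_ratio))
  expect_error(mismatch(tm, array(800, c(9, 10, 2)), c(1, 1, 1)), "grid")
})

test_that("mismatch volumes are permutation-invariant and additive", {
  set.seed(7)
  tm <- array(sample(c(0, 10), 200, replace = TRUE), c(10, 10, 2))
  adc <- array(sample(c(500, 800), 200, replace = TRUE), c(10, 10, 2))
  r1 <- mismatch(tm, adc, c(1, 1, 2))
  perm <- sample(200)
  r2 <- mismatch(array(tm[perm], dim(tm)), array(adc[perm], dim(adc)),
                 c(1, 1, 2))
  expect_equal(r1$ischemic_volume_ml, r2$ischemic_volume_ml)
  expect_equal(r1$core_volume_ml, r2$core_volume_ml)
  # volumes add over disjoint region unions (via masks)
  m1 <- array(0L, dim(tm)); m1[1:100] <- 1L
  m2 <- array(0L, dim(tm)); m2[101:200] <- 1L
  ra <- mismatch(tm, adc, c(1, 1, 2), mask = m1)
  rb <- mismatch(tm, adc, c(1, 1, 2), mask = m2)
  expect_equal(ra$ischemic_volume_ml + rb$ischemic_volume_ml,
               r1$ischemic_volume_ml)
  expect_equal(ra$core_volume_ml + rb$core_volume_ml, r1$core_volume_ml)
})

test_that("phantom delays are recovered as Tmax within one frame", {
  ph <- make_phantom(desk_cfg(noise_sd = 0), seed = 13)
  conc <- signal_to_concentration(ph$series, 5, ph$brain_mask)
  res <- deconvolve(conc, ph$aif_truth, lambda_rel = 1e-6)
  tm <- tmax_map(res)
  tis <- ph$brain_mask$mask > 0 & ph$vessel_truth$mask == 0
  expect_lte(max(abs(tm[tis] - ph$delay_map[tis])), ph$series$tr_s)
  # the hypoperfused lesion is the Tmax > 6 s region
  les <- ph$lesion_mask$mask > 0
  expect_true(all(tm[les] > 6))
  expect_true(all(tm[tis & !les] <= 6))
})
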