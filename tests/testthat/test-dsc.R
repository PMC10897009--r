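test_that("signal_to_concentration applies the delta-R2* transform", {
  d3 <- c(2, 2, 1)
  n <- 10
  a <- array(1000, c(d3, n))
  vs <- volume_series(a, c(1, 1, 1),
                      acquisition = list(modality = "dsc",
                                         frame_interval_s = 1,
                                         te_s = 0.02, baseline_frames = 4))
  conc <- signal_to_concentration(vs)
  expect_equal(max(abs(conc$curves)), 0)

  a[, , , 7] <- 1000 * exp(-1)
  vs2 <- volume_series(a, c(1, 1, 1),
                       acquisition = list(modality = "dsc",
                                          frame_interval_s = 1,
                                          te_s = 0.02, baseline_frames = 4))
  conc2 <- signal_to_concentration(vs2)
  expect_equal(conc2$curves[1, 1, 1, 7], 50, tolerance = 1e-12)
  expect_error(signal_to_concentration(vs2, te_s = 0), "TE")
  expect_error(signal_to_concentration(vs2, baseline_frames = 2), "baseline")
})

test_that("noise-free forward DSC signal round-trips to the generated delta-R2*", {
  cbf <- array(60, c(3, 3, 2)); mtt <- array(4, c(3, 3, 2))
  vs <- forward_dsc(cbf, mtt, n_frames = 100, dt = 0.5, noise_sigma = 0)
  conc <- signal_to_concentration(vs)
  expect_lt(max(abs(conc$curves - attr(vs, "delta_r2star"))), 1e-10)
})

test_that("extract_aif selects bolus-carrying voxels and baseline-zeroes", {
  d3 <- c(5, 5, 1)
  n <- 30
  times <- (0:(n - 1)) * 0.5
  bolus <- evaluate_aif(aif_model(delay = 3), times)
  tissue <- 0.3 * c(rep(0, 6), bolus[seq_len(n - 6)])
  M <- matrix(rep(tissue, each = prod(d3)), prod(d3), n)
  vessel_rows <- c(7, 13)
  M[vessel_rows, ] <- rep(4 * bolus, each = length(vessel_rows))
  conc <- make_conc(M, d3, dt = 0.5, baseline_frames = 5)
  mask <- roi_mask(array(TRUE, d3), 1)
  aif <- extract_aif(conc, mask)
  expect_equal(aif$n_voxels, 2)
  expect_lt(abs(max(aif$values) - max(4 * bolus)) / max(4 * bolus), 0.02)

  # homogeneous region: percentile filter finds nothing, falls back with warning
  Mh <- matrix(rep(tissue, each = prod(d3)), prod(d3), n)
  conch <- make_conc(Mh, d3, dt = 0.5, baseline_frames = 5)
  expect_warning(aifh <- extract_aif(conch, mask), "whole-mask")
  expect_equal(aifh$values, tissue - mean(tissue[1:5]), tolerance = 1e-12)
})

test_that("a bolus-free reference region invalidates the CBF map", {
  d3 <- c(3, 3, 1)
  n <- 20
  M <- matrix(0, prod(d3), n)
  conc <- make_conc(M, d3, dt = 1, baseline_frames = 4)
  aif <- extract_aif(conc, roi_mask(array(TRUE, d3), 1))
  suppressWarnings(dec <- deconvolve_cbf(conc, aif))
  expect_true(all(!dec$cbf$mask))
})

test_that("deconvolution satisfies the delta-AIF convolution identity", {
  d3 <- c(2, 2, 1)
  n <- 40; dt <- 0.5
  times <- (0:(n - 1)) * dt
  k_true <- 2.5 * exp(-times / 4)
  M <- matrix(rep(k_true, each = prod(d3)), prod(d3), n)
  conc <- make_conc(M, d3, dt = dt)
  aifv <- rep(0, n); aifv[1] <- 1 / dt   # unit-mass impulse
  dec <- deconvolve_cbf(conc, aifv, svd_threshold_frac = 1e-10,
                        keep_residue = TRUE)
  expect_equal(dec$cbf$data[1, 1, 1], 2.5, tolerance = 1e-8)
  expect_equal(dec$residue[1, 1, 1, ], k_true, tolerance = 1e-8)

  zero <- make_conc(matrix(0, prod(d3), n), d3, dt = dt)
  dec0 <- deconvolve_cbf(zero, aifv, svd_threshold_frac = 1e-10)
  expect_equal(max(abs(dec0$cbf$data)), 0)
})

test_that("noise-free phantom CBF is recovered within 5% when MTT >= 3 dt", {
  d3 <- c(4, 4, 2)
  cbf <- array(rep(c(20, 60), each = 16), d3)
  mtt <- array(rep(c(8, 4), each = 16), d3)
  dt <- 0.5
  vs <- forward_dsc(cbf, mtt, n_frames = 160, dt = dt, noise_sigma = 0,
                    k_dsc = 2)
  conc <- signal_to_concentration(vs)
  dec <- deconvolve_cbf(conc, attr(vs, "aif_curve"),
                        svd_threshold_frac = 1e-6)
  rel <- abs(dec$cbf$data - 2 * cbf) / (2 * cbf)   # k_dsc scales CBF
  expect_lt(max(rel), 0.05)
})

test_that("circulant SVD deconvolution matches a brute-force regularized solve", {
  # independent oracle: explicit pseudoinverse from the eigendecomposition of
  # t(A) A with the same truncation rule, applied voxel by voxel
  d3 <- c(8, 8, 1)
  n <- 50; dt <- 1
  times <- (0:(n - 1)) * dt
  aifv <- evaluate_aif(aif_model(delay = 5), times, normalize = TRUE)
  set.seed(7)
  cbf <- array(runif(prod(d3), 10, 90), d3)
  mtt <- array(sample(c(3, 4, 6), prod(d3), replace = TRUE), d3)
  vs <- forward_dsc(cbf, mtt, aif = aif_model(delay = 5), n_frames = n,
                    dt = dt, noise_sigma = 0, k_dsc = 1)
  conc <- signal_to_concentration(vs)
  thr <- 0.15
  dec <- deconvolve_cbf(conc, aifv, svd_threshold_frac = thr)

  A <- strokemri:::circulant_aif_matrix(aifv, dt)
  ev <- eigen(crossprod(A), symmetric = TRUE)
  s <- sqrt(pmax(ev$values, 0))
  keep <- s >= thr * max(s)
  U <- A %*% ev$vectors[, keep] %*% diag(1 / s[keep])
  Ainv <- ev$vectors[, keep] %*% diag(1 / s[keep]) %*% t(U)
  L <- nrow(A)
  cbf_oracle <- array(NA_real_, d3)
  for (i in seq_len(prod(d3))) {
    cpad <- c(matrix(conc$curves, prod(d3), n)[i, ], rep(0, L - n))
    k <- Ainv %*% cpad
    cbf_oracle[i] <- max(k[seq_len(n)])
  }
  expect_lt(max(abs(dec$cbf$data - cbf_oracle)), 1e-6)
})

test_that("CBV integration is trapezoidal and truncates at the fixed frame", {
  d3 <- c(2, 2, 1)
  M <- matrix(2, prod(d3), 10)
  conc <- make_conc(M, d3, dt = 1)
  cbv <- integrate_cbv(conc)
  expect_equal(cbv$data[1, 1, 1], 18)

  # all signal after the truncation index contributes nothing
  M2 <- matrix(0, prod(d3), 500)
  M2[, 420:500] <- 5
  conc2 <- make_conc(M2, d3, dt = 1)
  expect_equal(max(abs(integrate_cbv(conc2, truncate_at_frame = 400)$data)), 0)

  zero <- make_conc(matrix(0, prod(d3), 10), d3, dt = 1)
  expect_equal(max(abs(integrate_cbv(zero)$data)), 0)
})

test_that("MTT is the CBV/CBF quotient with flagged zero-flow voxels", {
  d3 <- c(2, 2, 1)
  cbv <- parametric_map(array(2, d3), "CBV")
  cbf_d <- array(0.5, d3); cbf_d[1, 1, 1] <- 0
  cbf <- parametric_map(cbf_d, "CBF")
  mtt <- compute_mtt(cbv, cbf)
  expect_equal(mtt$data[2, 2, 1], 4)
  expect_true(is.na(mtt$data[1, 1, 1]))
  expect_false(mtt$mask[1, 1, 1])
  expect_error(compute_mtt(cbv, parametric_map(array(1, c(3, 3, 1)), "CBF")),
               "grids")
})

test_that("perfusion outputs obey tissue- and AIF-scale equivariances", {
  d3 <- c(3, 3, 1)
  n <- 60; dt <- 0.5
  times <- (0:(n - 1)) * dt
  aifv <- evaluate_aif(aif_model(delay = 4), times, normalize = TRUE)
  vs <- forward_dsc(array(50, d3), array(4, d3), aif = aif_model(delay = 4),
                    n_frames = n, dt = dt, noise_sigma = 0, k_dsc = 1)
  conc <- signal_to_concentration(vs)
  base_cbf <- deconvolve_cbf(conc, aifv, svd_threshold_frac = 1e-8)$cbf
  base_cbv <- integrate_cbv(conc)
  base_mtt <- compute_mtt(base_cbv, base_cbf)

  # tissue curves scaled by c: CBF and CBV scale by c, MTT unchanged
  cc <- 3
  conc_s <- conc; conc_s$curves <- conc$curves * cc
  cbf_s <- deconvolve_cbf(conc_s, aifv, svd_threshold_frac = 1e-8)$cbf
  cbv_s <- integrate_cbv(conc_s)
  mtt_s <- compute_mtt(cbv_s, cbf_s)
  expect_equal(cbf_s$data, cc * base_cbf$data, tolerance = 1e-8)
  expect_equal(cbv_s$data, cc * base_cbv$data, tolerance = 1e-12)
  expect_equal(mtt_s$data, base_mtt$data, tolerance = 1e-8)

  # AIF scaled by c: CBF divides by c, CBV unchanged, MTT multiplies by c
  cbf_a <- deconvolve_cbf(conc, cc * aifv, svd_threshold_frac = 1e-8)$cbf
  mtt_a <- compute_mtt(base_cbv, cbf_a)
  expect_equal(cbf_a$data, base_cbf$data / cc, tolerance = 1e-8)
  expect_equal(mtt_a$data, cc * base_mtt$data, tolerance = 1e-8)
})
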