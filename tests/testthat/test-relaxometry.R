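series_from <- function(frames, acq) {
  d3 <- dim(frames[[1]])
  a <- array(unlist(frames), c(d3, length(frames)))
  volume_series(a, c(0.25, 0.25, 0.5), acquisition = acq)
}

test_that("two-point ADC matches the closed-form log ratio", {
  d3 <- c(3, 3, 1)
  s0 <- array(1000, d3)
  sb <- array(367.879, d3)
  vs <- series_from(list(s0, sb), list(modality = "dwi",
                                       b_values = c(0, 1000)))
  adc <- fit_adc_direction(vs)
  expect_equal(adc$data[2, 2, 1], (log(1000) - log(367.879)) / 1000,
               tolerance = 1e-12)
  expect_equal(adc$data[2, 2, 1], 1.0e-3, tolerance = 1e-5)
})

test_that("ADC is zero for constant signal and exact on 3-point exponentials", {
  d3 <- c(2, 2, 2)
  flat <- series_from(list(array(500, d3), array(500, d3)),
                      list(modality = "dwi", b_values = c(0, 800)))
  expect_equal(max(abs(fit_adc_direction(flat)$data)), 0)

  truth <- 0.7e-3
  b <- c(0, 500, 1000)
  frames <- lapply(b, function(bb) array(1200 * exp(-bb * truth), d3))
  vs <- series_from(frames, list(modality = "dwi", b_values = b))
  expect_lt(max(abs(fit_adc_direction(vs)$data - truth)), 1e-15)
})

test_that("non-positive signal flags voxels invalid instead of erroring", {
  d3 <- c(2, 2, 1)
  s0 <- array(1000, d3); sb <- array(400, d3)
  sb[1, 1, 1] <- -5
  vs <- series_from(list(s0, sb), list(modality = "dwi",
                                       b_values = c(0, 1000)))
  adc <- fit_adc_direction(vs)
  expect_false(adc$mask[1, 1, 1])
  expect_true(is.na(adc$data[1, 1, 1]))
  expect_true(all(adc$mask[-1]))
})

test_that("ADC fitting rejects invalid b-value sets", {
  d3 <- c(2, 2, 1)
  vs <- series_from(list(array(1, d3), array(1, d3)),
                    list(modality = "dwi", b_values = c(0, -100)))
  expect_error(fit_adc_direction(vs), "negative")
  vs2 <- series_from(list(array(1, d3), array(1, d3)),
                     list(modality = "dwi", b_values = c(100, 200)))
  expect_error(fit_adc_direction(vs2), "b = 0")
})

test_that("mean_adc averages voxelwise and is permutation invariant", {
  d3 <- c(3, 3, 1)
  maps <- lapply(c(0.8e-3, 1.0e-3, 1.2e-3),
                 function(v) parametric_map(array(v, d3), "ADC"))
  avg <- mean_adc(maps)
  expect_equal(avg$data[1, 1, 1], 1.0e-3, tolerance = 1e-15)
  perm <- mean_adc(maps[c(3, 1, 2)])
  expect_equal(avg$data, perm$data)
  expect_equal(mean_adc(maps[c(2, 2, 2)])$data, maps[[2]]$data)
  bad <- parametric_map(array(1e-3, c(4, 4, 1)), "ADC")
  expect_error(mean_adc(list(maps[[1]], maps[[2]], bad)), "grid")
})

test_that("two-point T2 matches the closed form and degenerate voxels clamp", {
  d3 <- c(2, 2, 1)
  f1 <- array(800, d3); f2 <- array(800 * exp(-1), d3)
  vs <- series_from(list(f1, f2), list(modality = "t2",
                                       echo_times_ms = c(10, 60)))
  t2 <- fit_t2(vs)
  expect_equal(t2$data[1, 1, 1], 50, tolerance = 1e-9)

  flat <- series_from(list(array(900, d3), array(900, d3)),
                      list(modality = "t2", echo_times_ms = c(10, 60)))
  ft <- fit_t2(flat, cap_ms = 2000)
  expect_equal(ft$data[1, 1, 1], 2000)
  expect_true(ft$flags[1, 1, 1])
})

test_that("8-echo noise-free T2 recovers the generating value to 1e-6", {
  d3 <- c(4, 4, 2)
  truth <- array(70, d3)
  vs <- forward_t2(truth, echo_times_ms = seq(10, 80, by = 10), s0 = 1000,
                   noise_sigma = 0)
  t2 <- fit_t2(vs)
  expect_lt(max(abs(t2$data - 70) / 70), 1e-6)
})

test_that("saturation- and inversion-recovery R1 fits recover truth", {
  d3 <- c(3, 3, 1)
  r1_true <- 1 / 1.5   # T1 = 1500 ms -> R1 in 1/s
  ti <- c(50, 150, 400, 900, 2000, 4500)
  # saturation recovery via the forward model
  sr <- forward_t1(array(r1_true, d3), recovery_times_ms = ti, s0 = 1000,
                   noise_sigma = 0)
  r1 <- fit_r1(sr)
  expect_lt(max(abs(r1$data - r1_true) / r1_true), 1e-6)

  # inversion recovery magnitude data built directly from the signed model
  rate_ms <- r1_true / 1000
  frames <- lapply(ti, function(t) array(abs(1000 * (1 - 2 * exp(-t * rate_ms))), d3))
  ir <- series_from(frames, list(modality = "t1", recovery_times_ms = ti,
                                 t1_mode = "inversion"))
  r1_ir <- fit_r1(ir)
  expect_lt(max(abs(r1_ir$data - r1_true) / r1_true), 1e-6)
})

test_that("doubling R1 halves the fitted T1 and short series error", {
  d3 <- c(2, 2, 1)
  ti <- c(100, 300, 800, 1800, 3500)
  fit_for <- function(r1) {
    vs <- forward_t1(array(r1, d3), recovery_times_ms = ti, noise_sigma = 0)
    fit_r1(vs)$data[1, 1, 1]
  }
  expect_equal(1 / fit_for(1.2), (1 / fit_for(0.6)) / 2, tolerance = 1e-6)

  single <- volume_series(array(1000, c(2, 2, 1, 1)), c(1, 1, 1),
                          acquisition = list(modality = "t1",
                                             recovery_times_ms = 5000,
                                             t1_mode = "saturation"))
  expect_error(fit_r1(single), "insufficient samples")
})

test_that("fit_r1_series returns time-ordered maps on a shared grid", {
  d3 <- c(3, 3, 1)
  ti <- c(100, 400, 1200, 3000)
  sl <- lapply(c(0.5, 0.7, 0.9), function(r1) {
    forward_t1(array(r1, d3), recovery_times_ms = ti, noise_sigma = 0)
  })
  maps <- fit_r1_series(sl)
  got <- vapply(maps, function(m) m$data[1, 1, 1], numeric(1))
  expect_equal(got, c(0.5, 0.7, 0.9), tolerance = 1e-6)
})

test_that("ADC and T2 recovery stays within 2% median error at SNR 40", {
  # study protocol: two-point DWI with 4 averages, 12-echo CPMG with 2 averages
  d3 <- c(12, 12, 4)
  adc_truth <- array(0.75e-3, d3)
  t2_truth <- array(45, d3)
  vs_d <- forward_dwi(adc_truth, bvalues = c(0, 1000), s0 = 1000,
                      noise_sigma = 25, n_averages = 4, seed = 11)
  adc <- mean_adc(lapply(split_dwi_directions(vs_d), fit_adc_direction))
  err_adc <- abs(adc$data - adc_truth) / adc_truth
  expect_lt(median(err_adc, na.rm = TRUE), 0.02)

  vs_t <- forward_t2(t2_truth, s0 = 1000, noise_sigma = 25, n_averages = 2,
                     seed = 12)
  t2 <- fit_t2(vs_t)
  err_t2 <- abs(t2$data - t2_truth) / t2_truth
  expect_lt(median(err_t2, na.rm = TRUE), 0.02)
})

test_that("recovery error grows monotonically with noise level", {
  d3 <- c(10, 10, 2)
  truth <- array(0.75e-3, d3)
  rmse <- vapply(c(5, 25, 80), function(sig) {
    vs <- forward_dwi(truth, bvalues = c(0, 1000), s0 = 1000,
                      noise_sigma = sig, seed = 42)
    adc <- mean_adc(lapply(split_dwi_directions(vs), fit_adc_direction))
    sqrt(mean((adc$data - truth)^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
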