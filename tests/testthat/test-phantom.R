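test_that("identical config and seed give bit-identical subjects", {
  s1 <- generate_subject(tiny_config(seed = 5, noise = 0.02))
  s2 <- generate_subject(tiny_config(seed = 5, noise = 0.02))
  expect_identical(s1$sessions, s2$sessions)
  expect_identical(s1$truth$synthetic_sds, s2$truth$synthetic_sds)
  s3 <- generate_subject(tiny_config(seed = 6, noise = 0.02))
  expect_false(identical(s1$sessions$occlusion$dwi$data,
                         s3$sessions$occlusion$dwi$data))
})

test_that("lesion-free noise-free phantoms are mirror-symmetric in every truth map", {
  subj <- generate_subject(tiny_config(lesion_radii_frac = c(0, 0, 0)))
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  for (sess in names(subj$truth$maps)) {
    for (q in names(subj$truth$maps[[sess]])) {
      a <- subj$truth$maps[[sess]][[q]]$data
      b <- flip(a)
      same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
      expect_true(all(same), label = sprintf("%s/%s symmetric", sess, q))
    }
  }
  expect_equal(sum(subj$truth$acute_mask$data), 0)
})

test_that("group presets encode the configured lesion-evolution directions", {
  iso <- generate_subject(tiny_config(preset = "isoflurane", seed = 2))
  expect_gt(roi_volume_ul(iso$truth$final_mask),
            roi_volume_ul(iso$truth$acute_mask))
  prop <- generate_subject(tiny_config(preset = "propofol", seed = 2))
  expect_lte(roi_volume_ul(prop$truth$final_mask),
             roi_volume_ul(prop$truth$acute_mask))
  # the configured ratio directions are read back from the presets themselves
  expect_gt(group_preset("isoflurane")$final_scale, 1)
  expect_lt(group_preset("propofol")$final_scale, 1)
  expect_gt(group_preset("isoflurane")$ki_lesion,
            group_preset("propofol")$ki_lesion)
  expect_lt(group_preset("isoflurane")$cvr_lesion,
            group_preset("propofol")$cvr_lesion)
})

test_that("synthetic deficit scores stay within the 0-22 scale", {
  sds <- vapply(1:25, function(s) {
    generate_subject(tiny_config(seed = s))$truth$synthetic_sds
  }, integer(1))
  expect_true(all(sds >= 0 & sds <= 22))
  expect_gt(length(unique(sds)), 1)   # actually random across subjects
})

test_that("lesion specifications outside the right hemisphere are rejected", {
  expect_error(phantom_config(grid_shape = c(16, 16, 8),
                              lesion_radii_frac = c(0.4, 0.2, 0.2)),
               "outside")
  expect_error(phantom_config(grid_shape = c(16, 16, 8),
                              lesion_center_frac = c(0.45, 0.5, 0.5),
                              lesion_radii_frac = c(0.1, 0.1, 0.1)),
               "outside")
  expect_error(phantom_config(grid_shape = c(15, 16, 8)), "even")
})

test_that("forward_dwi follows the Stejskal-Tanner decay", {
  d3 <- c(2, 2, 1)
  vs <- forward_dwi(array(1.0e-3, d3), bvalues = c(0, 1000), s0 = 1000,
                    noise_sigma = 0)
  b0 <- vs$data[, , , vs$acquisition$b_values == 0]
  expect_equal(as.vector(b0), rep(1000, 3 * prod(d3)))
  b1 <- vs$data[1, 1, 1, vs$acquisition$b_values == 1000]
  expect_equal(unique(round(b1, 9)), round(1000 * exp(-1), 9))
  expect_equal(b1[1], 367.88, tolerance = 1e-4)
  expect_error(forward_dwi(array(1e-3, d3), bvalues = c(0, -10)), "negative")

  # anisotropy multipliers act per direction
  va <- forward_dwi(array(1.0e-3, d3), bvalues = c(0, 1000),
                    dir_mult = c(1, 2, 1), noise_sigma = 0)
  dirs <- split_dwi_directions(va)
  adc_y <- fit_adc_direction(dirs[[2]])
  expect_equal(adc_y$data[1, 1, 1], 2e-3, tolerance = 1e-9)
})

test_that("noise-free DWI round-trips through the ADC fit to machine precision", {
  d3 <- c(6, 6, 2)
  truth <- array(seq(0.4e-3, 1.2e-3, length.out = prod(d3)), d3)
  vs <- forward_dwi(truth, bvalues = c(0, 600, 1200), noise_sigma = 0)
  adc <- mean_adc(lapply(split_dwi_directions(vs), fit_adc_direction))
  expect_lt(max(abs(adc$data - truth) / truth), 1e-10)
})

test_that("forward_dsc degenerates correctly", {
  d3 <- c(2, 2, 1)
  # zero flow everywhere: flat series at S0
  vs <- forward_dsc(array(0, d3), array(1, d3), n_frames = 30, dt = 0.5,
                    noise_sigma = 0)
  expect_equal(max(abs(vs$data - 1000)), 0)
  expect_error(forward_dsc(array(1, d3), array(1, d3), dt = 0), "positive")
  expect_error(forward_dsc(array(1, d3), array(0, d3), n_frames = 10,
                           dt = 0.5), "MTT")
  # delta-like AIF: tissue curve proportional to CBF * R(t) on the grid
  n <- 40; dt <- 0.5
  delta_aif <- aif_model(amplitude = 1, delay = 0.01, shape = 0.001,
                         scale = 0.05)
  vs2 <- forward_dsc(array(10, d3), array(4, d3), aif = delta_aif,
                     n_frames = n, dt = dt, noise_sigma = 0, k_dsc = 1)
  curve <- attr(vs2, "delta_r2star")[1, 1, 1, ]
  times <- (0:(n - 1)) * dt
  ref <- exp(-times / 4)
  # compare shape after peak normalization (delta has finite width on the grid)
  expect_gt(cor(curve[3:n], ref[3:n]), 0.999)
})

test_that("forward_patlak is linear in Ki and honours the muscle reference", {
  times <- c(0, 1, 2, 4, 6, 9, 12, 15)
  ref <- (1 - exp(-times / 0.8)) * exp(-times / 40)
  d3 <- c(2, 2, 1)
  # Ki = 0: tissue curve is exactly V0 * reference
  dr0 <- forward_patlak(array(0, d3), 0.05, ref, times)
  for (k in seq_along(times)) {
    expect_equal(dr0[1, 1, 1, k], 0.05 * ref[k], tolerance = 1e-14)
  }
  # doubling Ki doubles the late-time slope of dR1 vs integrated reference
  cum <- pracma::cumtrapz(times, ref)[, 1]
  d1 <- forward_patlak(array(0.01, d3), 0.05, ref, times)
  d2 <- forward_patlak(array(0.02, d3), 0.05, ref, times)
  late <- 6:8
  slope <- function(d) coef(lm(d[1, 1, 1, late] - 0.05 * ref[late] ~ cum[late]))[2]
  expect_equal(unname(slope(d2) / slope(d1)), 2, tolerance = 1e-8)
  # muscle voxels carry the reference curve itself
  mm <- array(FALSE, d3); mm[1, 1, 1] <- TRUE
  dm <- forward_patlak(array(0.01, d3), 0.05, ref, times,
                       muscle_mask = roi_mask(mm, 1))
  expect_equal(dm[1, 1, 1, ], ref, tolerance = 1e-14)
  expect_error(forward_patlak(array(0.01, d3), 0.05, ref, rev(times)),
               "increasing")
})

test_that("forward_bold produces the exact plateau and guards its length", {
  d3 <- c(2, 2, 1)
  vs <- forward_bold(array(5, d3), n_baseline_frames = 20,
                     n_stim_frames = 110, ramp = 0, s0 = 1000,
                     noise_sigma = 0)
  expect_equal(max(vs$data) / vs$data[1, 1, 1, 1], 1.05, tolerance = 1e-12)
  flat <- forward_bold(array(0, d3), n_baseline_frames = 20,
                       n_stim_frames = 110, ramp = 0, noise_sigma = 0)
  expect_equal(max(abs(flat$data - 1000)), 0)
  expect_error(forward_bold(array(5, d3), n_baseline_frames = 20,
                            n_stim_frames = 100, ramp = 10), "plateau")
})

test_that("day-4 bundles carry the permeability and reactivity series", {
  subj <- generate_subject(tiny_config())
  expect_named(subj$sessions, c("occlusion", "post_recan_30min", "day4"))
  for (sess in c("occlusion", "post_recan_30min")) {
    expect_null(subj$sessions[[sess]]$r1_series)
    expect_null(subj$sessions[[sess]]$bold)
  }
  expect_length(subj$sessions$day4$r1_series, 8)
  expect_s3_class(subj$sessions$day4$bold, "volume_series")
  # masks are coherent: lesion inside right-hemisphere brain, muscle outside
  expect_true(all(subj$truth$acute_mask$data <= subj$truth$hemi_right$data))
  expect_equal(sum(subj$truth$muscle_mask$data & subj$truth$brain_mask$data), 0)
})
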