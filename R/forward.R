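# Forward signal models of the digital phantom. Each takes ground-truth
# parameter maps and emits a volume_series the corresponding quantification
# module can be run on, so forward + inverse form a closed round trip.

truth_array <- function(x) {
  a <- if (inherits(x, "parametric_map")) x$data else x
  a[!is.finite(a)] <- 0
  a
}

s0_array <- function(s0, d3) {
  if (length(s0) == 1L) array(s0, d3) else {
    a <- if (inherits(s0, "parametric_map")) s0$data else s0
    stopifnot(identical(dim(a), d3))
    a
  }
}

add_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  x + stats::rnorm(length(x), sd = sigma)
}

#' Simulate a diffusion-weighted series
#'
#' Stejskal-Tanner mono-exponential decay `S(b) = S0 * exp(-b * ADC)` per
#' gradient direction, with optional per-direction anisotropy multipliers and
#' additive Gaussian noise on the magnitude signal.
#'
#' @param truth_adc [parametric_map()] (or 3D array) of ADC in mm^2/s.
#' @param bvalues b-values in s/mm^2; must be non-negative with the first 0.
#' @param s0 Baseline signal, scalar or 3D array/map.
#' @param noise_sigma Gaussian noise SD in signal units.
#' @param seed Integer seed (`NULL` leaves the RNG stream untouched).
#' @param n_averages Number of signal averages (NEX); the effective noise SD
#'   is `noise_sigma / sqrt(n_averages)`.
#' @param dir_mult Length-3 multiplier applied to ADC along directions x,y,z.
#' @param voxel_size Voxel edge lengths in mm.
#'
#' @return A [volume_series()] with frames ordered direction-major
#'   (all b-values of direction 1, then direction 2, then 3) and acquisition
#'   fields `b_values` and `directions`.
#' @export
forward_dwi <- function(truth_adc, bvalues = c(0, 1000), s0 = 1000,
                        noise_sigma = 0, seed = NULL, n_averages = 1L,
                        dir_mult = c(1, 1, 1),
                        voxel_size = c(0.25, 0.25, 0.5)) {
  if (any(bvalues < 0)) stop("negative b-value", call. = FALSE)
  if (bvalues[1] != 0) stop("first b-value must be 0", call. = FALSE)
  adc <- truth_array(truth_adc)
  d3 <- dim(adc)
  S0 <- s0_array(s0, d3)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(bvalues)
  out <- array(0, c(d3, 3L * nb))
  bv <- numeric(3L * nb); dd <- integer(3L * nb)
  k <- 0L
  for (dir in 1:3) {
    for (b in bvalues) {
      k <- k + 1L
      out[, , , k] <- S0 * exp(-b * adc * dir_mult[dir])
      bv[k] <- b; dd[k] <- dir
    }
  }
  out <- add_noise(out, noise_sigma / sqrt(n_averages))
  volume_series(out, voxel_size,
                acquisition = list(modality = "dwi", b_values = bv,
                                   directions = dd))
}

#' Split a multi-direction diffusion series by gradient direction
#'
#' @param series A [volume_series()] produced by [forward_dwi()] or read from
#'   disk with a `directions` acquisition field.
#' @return List of single-direction [volume_series()], one per direction, each
#'   including the b = 0 frames.
#' @export
split_dwi_directions <- function(series) {
  dirs <- series$acquisition$directions
  b <- series$acquisition$b_values
  if (is.null(dirs) || is.null(b)) {
    stop("series lacks directions/b_values metadata", call. = FALSE)
  }
  lapply(sort(unique(dirs)), function(dir) {
    keep <- dirs == dir
    volume_series(series$data[, , , keep, drop = FALSE], series$voxel_size,
                  acquisition = list(modality = "dwi",
                                     b_values = b[keep],
                                     directions = dirs[keep]))
  })
}

#' Simulate a multi-echo T2-weighted series
#'
#' `S(TE) = S0 * exp(-TE / T2)` with Gaussian noise.
#'
#' @param truth_t2 [parametric_map()] or 3D array of T2 in ms.
#' @param echo_times_ms Echo times in ms.
#' @inheritParams forward_dwi
#' @return A [volume_series()] with `echo_times_ms` acquisition metadata.
#' @export
forward_t2 <- function(truth_t2, echo_times_ms = seq(10, 120, by = 10),
                       s0 = 1000, noise_sigma = 0, seed = NULL,
                       n_averages = 1L, voxel_size = c(0.25, 0.25, 0.5)) {
  t2 <- truth_array(truth_t2)
  d3 <- dim(t2)
  S0 <- s0_array(s0, d3)
  if (!is.null(seed)) set.seed(seed)
  ne <- length(echo_times_ms)
  out <- array(0, c(d3, ne))
  decay <- array(0, d3)
  for (k in seq_len(ne)) {
    decay[] <- 0
    pos <- t2 > 0
    decay[pos] <- exp(-echo_times_ms[k] / t2[pos])
    out[, , , k] <- S0 * decay
  }
  out <- add_noise(out, noise_sigma / sqrt(n_averages))
  volume_series(out, voxel_size,
                acquisition = list(modality = "t2",
                                   echo_times_ms = echo_times_ms))
}

#' Simulate a saturation-recovery T1-weighted series
#'
#' `S(t) = S0 * (1 - exp(-t * R1))` at the given recovery times, used for the
#' serial post-contrast R1 mapping of the permeability stage.
#'
#' @param truth_r1 [parametric_map()] or 3D array of R1 in 1/s.
#' @param recovery_times_ms Saturation-recovery times in ms.
#' @inheritParams forward_dwi
#' @return A [volume_series()] with `recovery_times_ms` and `t1_mode`.
#' @export
forward_t1 <- function(truth_r1,
                       recovery_times_ms = c(50, 100, 200, 400, 800, 1600,
                                             3200, 6000),
                       s0 = 1000, noise_sigma = 0, seed = NULL,
                       n_averages = 1L, voxel_size = c(0.25, 0.25, 0.5)) {
  r1 <- truth_array(truth_r1) / 1000   # 1/s -> 1/ms
  d3 <- dim(r1)
  S0 <- s0_array(s0, d3)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(recovery_times_ms)
  out <- array(0, c(d3, nt))
  for (k in seq_len(nt)) {
    out[, , , k] <- S0 * (1 - exp(-recovery_times_ms[k] * r1))
  }
  out <- add_noise(out, noise_sigma / sqrt(n_averages))
  volume_series(out, voxel_size,
                acquisition = list(modality = "t1",
                                   recovery_times_ms = recovery_times_ms,
                                   t1_mode = "saturation"))
}

#' Simulate a dynamic susceptibility contrast series
#'
#' Tissue concentration follows the indicator-dilution convolution model
#' `C(t) = CBF * (C_a (*) R)(t)` with exponential residue
#' `R(t) = exp(-t / MTT)`, converted to signal by
#' `S(t) = S0 * exp(-k_dsc * TE * C(t))`. Baseline frames precede the bolus
#' delay of the AIF model.
#'
#' @param truth_cbf,truth_mtt [parametric_map()]s or 3D arrays of relative
#'   CBF and MTT (s). Voxels with CBF > 0 must have MTT > 0.
#' @param aif An [aif_model()]; its curve is sampled on the frame grid.
#' @param n_frames Number of frames.
#' @param dt Frame interval in seconds (> 0).
#' @param te_s Echo time in seconds.
#' @param k_dsc Susceptibility calibration constant mapping concentration to
#'   delta-R2* (see the package vignette; the peak tissue delta-R2* scales
#'   with it).
#' @param normalize_aif Sample the AIF with unit trapezoidal integral
#'   (default `TRUE`), so the simulated MTT scale is preserved.
#' @inheritParams forward_dwi
#'
#' @return A [volume_series()] with `frame_interval_s` and `baseline_frames`
#'   acquisition fields, plus attribute `delta_r2star` (the generated 4D
#'   delta-R2* field, 1/s) for round-trip testing.
#' @export
forward_dsc <- function(truth_cbf, truth_mtt, aif = aif_model(),
                        n_frames = 450, dt = 0.5, s0 = 1000,
                        te_s = 0.025, k_dsc = 2, noise_sigma = 0,
                        seed = NULL, normalize_aif = TRUE,
                        voxel_size = c(0.25, 0.25, 0.5)) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  cbf <- truth_array(truth_cbf)
  mtt <- truth_array(truth_mtt)
  d3 <- dim(cbf)
  if (any(cbf > 0 & mtt <= 0)) {
    stop("MTT must be positive wherever CBF > 0", call. = FALSE)
  }
  times <- (seq_len(n_frames) - 1) * dt
  c_a <- evaluate_aif(aif, times, normalize = normalize_aif)
  # group voxels by unique MTT: the phantom uses piecewise-constant truth, so
  # one convolution per distinct residue function serves many voxels
  nv <- prod(d3)
  conc <- matrix(0, nv, n_frames)
  cbf_v <- as.vector(cbf)
  mtt_v <- as.vector(mtt)
  act <- which(cbf_v > 0)
  if (length(act)) {
    for (m in unique(mtt_v[act])) {
      resid <- exp(-times / m)
      unit <- dt * stats::convolve(c_a, rev(resid), type = "open")[seq_len(n_frames)]
      sel <- act[mtt_v[act] == m]
      conc[sel, ] <- outer(cbf_v[sel], unit)
    }
  }
  dr2s <- k_dsc * conc
  S0 <- as.vector(s0_array(s0, d3))
  sig <- S0 * exp(-te_s * dr2s)
  if (!is.null(seed)) set.seed(seed)
  sig <- add_noise(sig, noise_sigma)
  out <- array(sig, c(d3, n_frames))
  vs <- volume_series(out, voxel_size,
                      acquisition = list(modality = "dsc",
                                         frame_interval_s = dt,
                                         te_s = te_s,
                                         baseline_frames = sum(times < aif$delay)))
  attr(vs, "delta_r2star") <- array(dr2s, c(d3, n_frames))
  attr(vs, "aif_curve") <- c_a
  vs
}

#' Simulate serial delta-R1 uptake under the Patlak model
#'
#' Tissue response to an intravascular + unidirectional-uptake tracer:
#' `dR1(t) = Ki * integral_0^t C_RT dtau + V0 * C_RT(t)`, where `C_RT` is the
#' reference-tissue (muscle) concentration curve expressed as delta-R1. Muscle
#' voxels carry `C_RT` itself.
#'
#' @param truth_ki [parametric_map()] or 3D array of Ki in 1/min.
#' @param v0 Distribution-volume fraction, scalar or 3D array.
#' @param c_ref_curve Reference-tissue delta-R1 per frame (1/s), non-negative.
#' @param frame_times Times in minutes, strictly increasing.
#' @param muscle_mask Optional [roi_mask()]; these voxels are set to the
#'   reference curve.
#' @inheritParams forward_dwi
#'
#' @return 4D array of delta-R1 (1/s) with attribute `frame_times_min`.
#' @export
forward_patlak <- function(truth_ki, v0, c_ref_curve, frame_times,
                           muscle_mask = NULL, noise_sigma = 0, seed = NULL) {
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing", call. = FALSE)
  }
  if (any(c_ref_curve < 0)) stop("reference curve must be non-negative",
                                 call. = FALSE)
  ki <- truth_array(truth_ki)
  d3 <- dim(ki)
  v0a <- if (length(v0) == 1L) array(v0, d3) else truth_array(v0)
  cum <- pracma::cumtrapz(frame_times, c_ref_curve)[, 1]  # 1/s * min
  nt <- length(frame_times)
  out <- array(0, c(d3, nt))
  for (k in seq_len(nt)) {
    out[, , , k] <- ki * cum[k] + v0a * c_ref_curve[k]
  }
  if (!is.null(muscle_mask)) {
    mm <- muscle_mask$data
    for (k in seq_len(nt)) {
      sl <- out[, , , k]
      sl[mm] <- c_ref_curve[k]
      out[, , , k] <- sl
    }
  }
  if (!is.null(seed)) set.seed(seed)
  out <- add_noise(out, noise_sigma)
  attr(out, "frame_times_min") <- frame_times
  out
}

#' Simulate a hypercapnic-challenge BOLD series
#'
#' `S(t) = S0 * (1 + CVR/100 * h(t))` where the stimulus response `h` is 0
#' during baseline, ramps linearly to 1 over `ramp` frames at stimulus onset
#' and then stays at 1 for the stimulated plateau.
#'
#' @param truth_cvr [parametric_map()] or 3D array of CVR in percent.
#' @param n_baseline_frames Frames before stimulus onset.
#' @param n_stim_frames Frames from onset to the end of the series.
#' @param ramp Frames over which the response rises 0 to 1.
#' @param frame_interval_s Frame interval in seconds.
#' @inheritParams forward_dwi
#'
#' @return A [volume_series()] with `baseline_frames` acquisition metadata.
#'   The stimulated plateau must hold at least 100 frames (the window length
#'   of the reactivity estimator), otherwise a configuration error is raised.
#' @export
forward_bold <- function(truth_cvr, n_baseline_frames = 90,
                         n_stim_frames = 130, ramp = 10, s0 = 1000,
                         noise_sigma = 0, seed = NULL,
                         frame_interval_s = 2,
                         voxel_size = c(0.25, 0.25, 0.5)) {
  if (n_stim_frames - ramp < 100) {
    stop("stimulated plateau shorter than 100 frames", call. = FALSE)
  }
  cvr <- truth_array(truth_cvr)
  d3 <- dim(cvr)
  S0 <- s0_array(s0, d3)
  n <- n_baseline_frames + n_stim_frames
  h <- c(rep(0, n_baseline_frames),
         if (ramp > 0) pmin(seq_len(n_stim_frames) / ramp, 1)
         else rep(1, n_stim_frames))
  out <- array(0, c(d3, n))
  for (k in seq_len(n)) {
    out[, , , k] <- S0 * (1 + cvr / 100 * h[k])
  }
  if (!is.null(seed)) set.seed(seed)
  out <- add_noise(out, noise_sigma)
  volume_series(out, voxel_size,
                acquisition = list(modality = "bold",
                                   frame_interval_s = frame_interval_s,
                                   baseline_frames = n_baseline_frames))
}
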