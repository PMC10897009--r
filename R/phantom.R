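#' Anesthesia-group presets for the digital phantom
#'
#' Coherent sets of ground-truth tissue values emulating the two anesthesia
#' arms of a transient-MCAO study design. Presets encode the *direction* of
#' the group contrasts only: the isoflurane-like preset has a final lesion
#' larger than the acute ischemic area, elevated day-4 relative CBF, shortened
#' relative MTT, a higher lesion-core transfer constant Ki and lower
#' ipsilesional CVR; the propofol-like preset the converse. Magnitudes are
#' editable defaults, not claims about any real cohort.
#'
#' Lesion geometry and tissue values are expressed per session
#' (`occlusion`, `post_recan_30min`, `day4`) as multipliers on normal tissue.
#'
#' @param name `"isoflurane"` or `"propofol"`.
#' @return Named list of truth values and lesion geometry fractions.
#' @export
group_preset <- function(name = c("isoflurane", "propofol")) {
  name <- match.arg(name)
  base <- list(
    # normal-tissue values (rat brain, high field)
    adc = list(brain = 0.75e-3, muscle = 1.3e-3),     # mm^2/s
    t2 = list(brain = 45, muscle = 25),               # ms
    t1 = list(brain = 1800, muscle = 1400),           # ms
    cbf = list(brain = 60, muscle = 5, vessel = 400), # relative units
    mtt = list(brain = 4, muscle = 2, vessel = 1),    # s
    ki_brain = 0.001,                                 # 1/min
    v0 = 0.05,
    cvr_brain = 5,                                    # percent
    # lesion center and acute radii as fractions of the grid
    lesion_center_frac = c(0.75, 0.5, 0.5),
    s0 = 1000
  )
  spec <- switch(
    name,
    isoflurane = list(
      acute_radii_frac = c(0.1875, 0.15625, 0.25),
      final_scale = 1.15,
      adc_lesion_mult = c(occlusion = 0.60, post_recan_30min = 0.75, day4 = 1.00),
      t2_lesion_mult = c(occlusion = 1.05, post_recan_30min = 1.10, day4 = 1.40),
      t1_lesion_mult = c(occlusion = 1.05, post_recan_30min = 1.10, day4 = 1.20),
      cbf_lesion_mult = c(occlusion = 0.20, post_recan_30min = 0.80, day4 = 1.30),
      mtt_lesion_mult = c(occlusion = 2.00, post_recan_30min = 1.20, day4 = 0.70),
      ki_lesion = 0.020,
      cvr_lesion = 1.0,
      sds_rate = 6.0
    ),
    propofol = list(
      acute_radii_frac = c(0.15625, 0.125, 0.21875),
      final_scale = 0.85,
      adc_lesion_mult = c(occlusion = 0.60, post_recan_30min = 0.88, day4 = 1.00),
      t2_lesion_mult = c(occlusion = 1.05, post_recan_30min = 1.06, day4 = 1.30),
      t1_lesion_mult = c(occlusion = 1.05, post_recan_30min = 1.08, day4 = 1.15),
      cbf_lesion_mult = c(occlusion = 0.20, post_recan_30min = 0.90, day4 = 0.90),
      mtt_lesion_mult = c(occlusion = 2.00, post_recan_30min = 1.10, day4 = 1.15),
      ki_lesion = 0.008,
      cvr_lesion = 3.0,
      sds_rate = 3.8
    )
  )
  c(base, spec, list(preset = name))
}

#' Configuration of one phantom subject
#'
#' @param grid_shape Integer length-3 voxel grid; the first (x) axis must be
#'   even so the central sagittal plane is an exact voxel boundary.
#' @param fov_mm Field of view in mm per axis; voxel size is `fov_mm /
#'   grid_shape`.
#' @param group_preset `"isoflurane"` or `"propofol"` (see [group_preset()]).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   subjects.
#' @param noise Named list of Gaussian noise SDs as a fraction of baseline
#'   signal per modality (`dwi`, `t2`, `t1`, `dsc`, `bold`).
#' @param lesion_radii_frac Optional acute lesion semi-axes as fractions of
#'   the grid (overrides the preset); use `c(0, 0, 0)` for a lesion-free
#'   subject.
#' @param lesion_center_frac Lesion center as fractions of the grid; must keep
#'   the lesion inside the right hemisphere.
#' @param n_dsc_frames,dsc_dt DSC series length and frame interval (s). The
#'   default keeps at least 400 frames so the fixed integration truncation
#'   index exists.
#' @param n_bold_baseline,n_bold_stim,bold_ramp BOLD challenge layout in
#'   frames (baseline, stimulus, onset ramp). The stimulated plateau must hold
#'   at least 100 frames.
#' @param patlak_times_min Serial R1-mapping times in minutes from injection.
#' @param protocol Acquisition protocol: named list with `dwi_bvalues`,
#'   `dwi_averages`, `t2_echo_times_ms`, `t2_averages`,
#'   `t1_recovery_times_ms`, `t1_averages`. Defaults emulate a standard
#'   preclinical session (two-point DWI with 4 averages, 12-echo CPMG with 2
#'   averages, 8-point saturation-recovery T1 mapping).
#' @param truth Optional named list overriding individual preset truth values.
#'
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 32L),
                           fov_mm = c(16, 16, 16),
                           group_preset = "isoflurane",
                           seed = 1L,
                           noise = list(dwi = 0.025, t2 = 0.025, t1 = 0.025,
                                        dsc = 0.025, bold = 0.005),
                           lesion_radii_frac = NULL,
                           lesion_center_frac = NULL,
                           n_dsc_frames = 420L, dsc_dt = 0.5,
                           n_bold_baseline = 90L, n_bold_stim = 130L,
                           bold_ramp = 10L,
                           patlak_times_min = c(0, 1, 2, 4, 6, 9, 12, 15),
                           protocol = list(),
                           truth = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("grid_shape must be three integers >= 8", call. = FALSE)
  }
  if (grid_shape[1] %% 2L != 0L) {
    stop("the x extent must be even (exact voxel-level midline)", call. = FALSE)
  }
  preset <- group_preset(group_preset)
  preset[names(truth)] <- truth
  if (!is.null(lesion_radii_frac)) preset$acute_radii_frac <- lesion_radii_frac
  if (!is.null(lesion_center_frac)) preset$lesion_center_frac <- lesion_center_frac
  default_noise <- list(dwi = 0.025, t2 = 0.025, t1 = 0.025, dsc = 0.025,
                        bold = 0.005)
  default_noise[names(noise)] <- noise
  default_protocol <- list(
    dwi_bvalues = c(0, 1000), dwi_averages = 4L,
    t2_echo_times_ms = seq(10, 120, by = 10), t2_averages = 2L,
    t1_recovery_times_ms = c(50, 100, 200, 400, 800, 1600, 3200, 6000),
    t1_averages = 1L
  )
  default_protocol[names(protocol)] <- protocol
  cfg <- structure(
    list(grid_shape = grid_shape, fov_mm = as.numeric(fov_mm),
         voxel_size = as.numeric(fov_mm) / grid_shape,
         preset = preset, seed = as.integer(seed), noise = default_noise,
         n_dsc_frames = as.integer(n_dsc_frames), dsc_dt = dsc_dt,
         n_bold_baseline = as.integer(n_bold_baseline),
         n_bold_stim = as.integer(n_bold_stim),
         bold_ramp = as.integer(bold_ramp),
         patlak_times_min = patlak_times_min,
         protocol = default_protocol),
    class = "phantom_config"
  )
  # the lesion must stay strictly inside the right hemisphere; its outer edge
  # may be cropped by the brain surface (as cortical lesions are)
  g <- grid_shape
  radii <- preset$acute_radii_frac * g * max(1, preset$final_scale)
  center <- preset$lesion_center_frac * (g + 1)
  if (any(preset$acute_radii_frac > 0)) {
    if (center[1] - radii[1] <= g[1] / 2 ||
        any(center < 1) || any(center > g)) {
      stop("lesion specification extends outside the right hemisphere/grid",
           call. = FALSE)
    }
  }
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %s grid, %s preset, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$preset$preset, x$seed))
  invisible(x)
}

ellipsoid_mask <- function(grid, center, radii) {
  if (any(radii <= 0)) return(array(FALSE, grid))
  x <- (seq_len(grid[1]) - center[1]) / radii[1]
  y <- (seq_len(grid[2]) - center[2]) / radii[2]
  z <- (seq_len(grid[3]) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

# Static geometry shared by all sessions of a subject.
phantom_geometry <- function(cfg) {
  g <- cfg$grid_shape
  vox_ul <- prod(cfg$voxel_size)   # mm^3 == uL
  centre <- (g + 1) / 2
  brain <- ellipsoid_mask(g, centre, c(0.44, 0.41, 0.41) * g)
  hemi_left <- array(FALSE, g); hemi_left[seq_len(g[1] / 2), , ] <- TRUE
  hemi_right <- !hemi_left
  # muscle slab adjacent to the skull (posterior y edge), symmetric in x
  muscle <- array(FALSE, g)
  ys <- seq.int(max(1L, g[2] - max(2L, round(0.06 * g[2]))), g[2])
  xs <- seq.int(round(0.25 * g[1]), g[1] - round(0.25 * g[1]) + 1L)
  zs <- seq.int(round(0.3 * g[3]), round(0.7 * g[3]))
  muscle[xs, ys, zs] <- TRUE
  muscle <- muscle & !brain
  # symmetric pair of intracerebral vessels (AIF carriers)
  vessel <- array(FALSE, g)
  r_v <- max(1.2, 0.025 * g[1])
  cx_l <- 0.3 * (g[1] + 1)
  cy <- (g[2] + 1) / 2
  zs_v <- seq.int(round(0.35 * g[3]), round(0.65 * g[3]))
  xv <- seq_len(g[1]); yv <- seq_len(g[2])
  disc_l <- outer((xv - cx_l)^2, (yv - cy)^2, `+`) <= r_v^2
  disc_r <- disc_l[rev(seq_len(g[1])), ]
  for (z in zs_v) {
    vessel[, , z] <- vessel[, , z] | disc_l | disc_r
  }
  vessel <- vessel & brain
  lesion_center <- cfg$preset$lesion_center_frac * (g + 1)
  acute_radii <- cfg$preset$acute_radii_frac * g
  acute <- ellipsoid_mask(g, lesion_center, acute_radii) & brain
  final <- ellipsoid_mask(g, lesion_center,
                          acute_radii * cfg$preset$final_scale) & brain
  list(grid = g, voxel_volume_ul = vox_ul, brain = brain,
       hemi_left = hemi_left, hemi_right = hemi_right, muscle = muscle,
       vessel = vessel, acute = acute, final = final)
}

# Ground-truth parametric maps for one session.
phantom_truth_maps <- function(cfg, geo, session) {
  p <- cfg$preset
  g <- geo$grid
  lesion <- if (session == "day4") geo$final else geo$acute
  assemble <- function(brain_val, muscle_val, lesion_mult, quantity,
                       vessel_val = NULL) {
    a <- array(NA_real_, g)
    a[geo$brain] <- brain_val
    a[geo$muscle] <- muscle_val
    if (!is.null(vessel_val)) a[geo$vessel] <- vessel_val
    if (!is.null(lesion_mult)) {
      lm <- lesion & !geo$vessel
      a[lm] <- brain_val * lesion_mult
    }
    parametric_map(a, quantity, mask = geo$brain | geo$muscle)
  }
  maps <- list(
    adc = assemble(p$adc$brain, p$adc$muscle,
                   p$adc_lesion_mult[[session]], "ADC"),
    t2 = assemble(p$t2$brain, p$t2$muscle,
                  p$t2_lesion_mult[[session]], "T2"),
    t1 = assemble(p$t1$brain, p$t1$muscle,
                  p$t1_lesion_mult[[session]], "T1"),
    cbf = assemble(p$cbf$brain, p$cbf$muscle,
                   p$cbf_lesion_mult[[session]], "CBF",
                   vessel_val = p$cbf$vessel),
    mtt = assemble(p$mtt$brain, p$mtt$muscle,
                   p$mtt_lesion_mult[[session]], "MTT",
                   vessel_val = p$mtt$vessel)
  )
  maps$cbv <- parametric_map(maps$cbf$data * maps$mtt$data, "CBV",
                             mask = geo$brain | geo$muscle)
  if (session == "day4") {
    ki <- array(NA_real_, g)
    ki[geo$brain] <- p$ki_brain
    ki[lesion] <- p$ki_lesion
    maps$ki <- parametric_map(ki, "KI", mask = geo$brain)
    v0 <- array(NA_real_, g)
    v0[geo$brain] <- p$v0
    maps$v0 <- parametric_map(v0, "V0", mask = geo$brain)
    cvr <- array(NA_real_, g)
    cvr[geo$brain] <- p$cvr_brain
    cvr[lesion] <- p$cvr_lesion
    maps$cvr <- parametric_map(cvr, "CVR", mask = geo$brain)
  }
  maps
}

subseed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9349) %% 2147483629)
}

# Reference-tissue (muscle) concentration curve as delta-R1, 1/s: fast uptake
# with slow washout, evaluated at minutes from injection.
muscle_reference_curve <- function(times_min, peak = 1.0, tau_up = 0.8,
                                   tau_down = 40) {
  raw <- (1 - exp(-times_min / tau_up)) * exp(-times_min / tau_down)
  if (max(raw) > 0) raw <- raw / max(raw) * peak
  raw
}

#' Ground-truth maps and geometry of a phantom without signal simulation
#'
#' Builds the static geometry (brain, hemispheres, muscle, vessels, lesion
#' masks) and the per-session ground-truth parametric maps a
#' [generate_subject()] call would embed, without simulating any signal.
#' Useful for forward-model round-trip tests against known truth.
#'
#' @param config A [phantom_config()].
#' @return List with `maps` (per-session lists of [parametric_map()]s),
#'   the geometry [roi_mask()]s, and `voxel_volume_ul`.
#' @export
phantom_ground_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  geo <- phantom_geometry(config)
  vox_ul <- geo$voxel_volume_ul
  maps <- lapply(c(occlusion = "occlusion",
                   post_recan_30min = "post_recan_30min", day4 = "day4"),
                 function(s) phantom_truth_maps(config, geo, s))
  list(maps = maps,
       brain_mask = roi_mask(geo$brain, vox_ul),
       hemi_left = roi_mask(geo$hemi_left, vox_ul),
       hemi_right = roi_mask(geo$hemi_right, vox_ul),
       muscle_mask = roi_mask(geo$muscle, vox_ul),
       vessel_mask = roi_mask(geo$vessel, vox_ul),
       acute_mask = roi_mask(geo$acute, vox_ul),
       final_mask = roi_mask(geo$final, vox_ul),
       voxel_volume_ul = vox_ul)
}

#' Generate one synthetic subject with known ground truth
#'
#' Builds a two-hemisphere rat-brain phantom with an ipsilateral (right
#' hemisphere) lesion, a muscle reference region and a symmetric pair of
#' intracerebral vessels, then simulates every modality for the three imaging
#' sessions of the longitudinal design: diffusion (b0 + three directions),
#' multi-echo T2 and a DSC bolus passage at every session, plus serial
#' post-contrast T1-mapping and a hypercapnic BOLD challenge at day 4.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_subject`: list with `sessions` (named list of
#'   [volume_series()] bundles), `truth` (per-session ground-truth
#'   [parametric_map()]s, lesion masks, geometry masks, the AIF model, the
#'   reference curve and a synthetic sensorimotor deficit score), and the
#'   originating `config`.
#' @export
generate_subject <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  geo <- phantom_geometry(config)
  p <- config$preset
  vox <- config$voxel_size
  vox_ul <- geo$voxel_volume_ul
  s0 <- array(0, geo$grid)
  s0[geo$brain | geo$muscle] <- p$s0
  aif <- aif_model(amplitude = 1, delay = 10, shape = 2.5, scale = 1.5)
  sessions <- list()
  truth_maps <- list()
  sess_names <- c("occlusion", "post_recan_30min", "day4")
  for (si in seq_along(sess_names)) {
    sess <- sess_names[si]
    tm <- phantom_truth_maps(config, geo, sess)
    truth_maps[[sess]] <- tm
    sb <- subseed(config$seed, si * 100)
    proto <- config$protocol
    bundle <- list(
      dwi = forward_dwi(tm$adc, bvalues = proto$dwi_bvalues, s0 = s0,
                        noise_sigma = config$noise$dwi * p$s0,
                        n_averages = proto$dwi_averages,
                        seed = subseed(sb, 1), voxel_size = vox),
      t2 = forward_t2(tm$t2, echo_times_ms = proto$t2_echo_times_ms, s0 = s0,
                      noise_sigma = config$noise$t2 * p$s0,
                      n_averages = proto$t2_averages,
                      seed = subseed(sb, 2), voxel_size = vox),
      dsc = forward_dsc(tm$cbf, tm$mtt, aif = aif,
                        n_frames = config$n_dsc_frames, dt = config$dsc_dt,
                        s0 = s0, noise_sigma = config$noise$dsc * p$s0,
                        seed = subseed(sb, 3), voxel_size = vox)
    )
    attr(bundle$dsc, "delta_r2star") <- NULL   # bulk truth not carried per subject
    if (sess == "day4") {
      times <- config$patlak_times_min
      c_rt <- muscle_reference_curve(times)
      dr1 <- forward_patlak(tm$ki, truth_array(tm$v0), c_rt, times,
                            muscle_mask = roi_mask(geo$muscle, vox_ul))
      r1_0 <- array(NA_real_, geo$grid)
      r1_0[geo$brain | geo$muscle] <- 1000 / tm$t1$data[geo$brain | geo$muscle]
      r1_0[!is.finite(r1_0)] <- 0
      r1_series <- lapply(seq_along(times), function(k) {
        forward_t1(r1_0 + dr1[, , , k],
                   recovery_times_ms = proto$t1_recovery_times_ms, s0 = s0,
                   noise_sigma = config$noise$t1 * p$s0,
                   n_averages = proto$t1_averages,
                   seed = subseed(sb, 10 + k), voxel_size = vox)
      })
      for (k in seq_along(r1_series)) {
        r1_series[[k]]$acquisition$frame_time_min <- times[k]
      }
      bundle$r1_series <- r1_series
      bundle$bold <- forward_bold(tm$cvr,
                                  n_baseline_frames = config$n_bold_baseline,
                                  n_stim_frames = config$n_bold_stim,
                                  ramp = config$bold_ramp, s0 = s0,
                                  noise_sigma = config$noise$bold * p$s0,
                                  seed = subseed(sb, 30), voxel_size = vox)
    }
    sessions[[sess]] <- bundle
  }
  set.seed(subseed(config$seed, 777))
  sds <- min(stats::rpois(1, p$sds_rate), 22L)
  truth <- list(
    maps = truth_maps,
    acute_mask = roi_mask(geo$acute, vox_ul),
    final_mask = roi_mask(geo$final, vox_ul),
    brain_mask = roi_mask(geo$brain, vox_ul),
    hemi_left = roi_mask(geo$hemi_left, vox_ul),
    hemi_right = roi_mask(geo$hemi_right, vox_ul),
    muscle_mask = roi_mask(geo$muscle, vox_ul),
    vessel_mask = roi_mask(geo$vessel, vox_ul),
    synthetic_sds = sds,
    aif = aif,
    reference_curve = muscle_reference_curve(config$patlak_times_min),
    frame_times_min = config$patlak_times_min
  )
  structure(list(sessions = sessions, truth = truth, config = config,
                 group = p$preset),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> %s preset, grid %s, sessions: %s, SDS %d\n",
              x$group, paste(x$config$grid_shape, collapse = "x"),
              paste(names(x$sessions), collapse = ", "),
              x$truth$synthetic_sds))
  invisible(x)
}
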