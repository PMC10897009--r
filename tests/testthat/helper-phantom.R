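# Small-grid phantom configs and fixture builders used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_config <- function(seed = 1L, noise = 0, preset = "isoflurane",
                        lesion_radii_frac = c(0.12, 0.12, 0.15),
                        lesion_center_frac = c(0.72, 0.5, 0.5), ...) {
  phantom_config(
    grid_shape = c(16L, 16L, 8L),
    group_preset = preset,
    seed = seed,
    noise = list(dwi = noise, t2 = noise, t1 = noise, dsc = noise,
                 bold = noise),
    lesion_radii_frac = lesion_radii_frac,
    lesion_center_frac = lesion_center_frac,
    n_dsc_frames = 80L, dsc_dt = 0.5,
    n_bold_baseline = 15L, n_bold_stim = 115L, bold_ramp = 5L,
    ...
  )
}

# Bare concentration_curves object from a voxels-by-frames matrix.
make_conc <- function(curves_matrix, d3, dt = 0.5, baseline_frames = 3L,
                      valid = NULL) {
  n <- ncol(curves_matrix)
  stopifnot(nrow(curves_matrix) == prod(d3))
  structure(
    list(curves = array(curves_matrix, c(d3, n)),
         frame_interval_s = dt, baseline_frames = baseline_frames,
         valid = valid %||% array(TRUE, d3)),
    class = "concentration_curves")
}

# Dice similarity of two logical arrays.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
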