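#' Convert a DSC signal series to concentration curves
#'
#' Applies the standard delta-R2* transform
#' `C(t) = -ln(S(t)/S0) / TE`, with `S0` the mean over the pre-bolus baseline
#' frames. Concentrations where the signal sits at or above baseline (within
#' `tol`) are set to zero.
#'
#' @param series A [volume_series()] with `frame_interval_s` and
#'   `baseline_frames` acquisition fields.
#' @param te_s Echo time in seconds (> 0). Defaults to the acquisition's
#'   `te_s` field.
#' @param baseline_frames Number of pre-bolus frames; defaults to the
#'   acquisition field. Must be at least 3.
#' @param tol Relative tolerance above baseline below which concentration is
#'   zeroed.
#' @param mask Optional [roi_mask()] or logical array; voxels outside get
#'   zero curves.
#'
#' @return A `concentration_curves` object: list with `curves` (4D array,
#'   1/s), `frame_interval_s`, `baseline_frames` and `valid` (logical 3D
#'   array of voxels with positive baseline signal).
#' @export
signal_to_concentration <- function(series, te_s = NULL,
                                    baseline_frames = NULL, tol = 0,
                                    mask = NULL) {
  te_s <- te_s %||% series$acquisition$te_s
  if (is.null(te_s) || te_s <= 0) stop("TE must be positive", call. = FALSE)
  baseline_frames <- baseline_frames %||% series$acquisition$baseline_frames
  if (is.null(baseline_frames) || baseline_frames < 3L) {
    stop("need at least 3 baseline frames", call. = FALSE)
  }
  d <- dim(series$data)
  S <- as_signal_matrix(series)
  keep <- mask_vector(mask, d[1:3])
  s0 <- rowMeans(S[, seq_len(baseline_frames), drop = FALSE])
  valid <- keep & is.finite(s0) & s0 > 0
  conc <- matrix(0, nrow(S), d[4])
  if (any(valid)) {
    ratio <- S[valid, , drop = FALSE] / s0[valid]
    cc <- -log(pmax(ratio, 1e-12)) / te_s
    cc[ratio >= 1 + tol] <- 0
    conc[valid, ] <- cc
  }
  structure(
    list(curves = array(conc, d), frame_interval_s = series$acquisition$frame_interval_s,
         baseline_frames = baseline_frames, valid = array(valid, d[1:3])),
    class = "concentration_curves"
  )
}

#' @export
print.concentration_curves <- function(x, ...) {
  d <- dim(x$curves)
  cat(sprintf("<concentration_curves> %dx%dx%d voxels, %d frames, dt %gs, %d baseline\n",
              d[1], d[2], d[3], d[4], x$frame_interval_s, x$baseline_frames))
  invisible(x)
}

#' Extract an arterial reference curve from the contralateral hemisphere
#'
#' Selects the bolus-carrying voxels of the contralateral mask — those whose
#' peak concentration strictly exceeds the mask's 90th-percentile peak — and
#' returns their frame-wise mean concentration, zeroed to its own baseline
#' average. If the percentile filter selects nothing (e.g. a perfectly
#' homogeneous region), the whole-mask mean is used with a warning.
#'
#' @param conc A `concentration_curves` object from
#'   [signal_to_concentration()].
#' @param contralateral_mask A [roi_mask()] in the contralateral hemisphere.
#' @param peak_quantile Peak-percentile cut for bolus-carrying voxels.
#'
#' @return An `arterial_input_curve`: list with `values` (concentration per
#'   frame, 1/s), `n_voxels` used, and `baseline_frames`.
#' @export
extract_aif <- function(conc, contralateral_mask, peak_quantile = 0.9) {
  m <- contralateral_mask$data & conc$valid
  if (!any(m)) stop("contralateral mask selects no valid voxels", call. = FALSE)
  d <- dim(conc$curves)
  C <- matrix(conc$curves, prod(d[1:3]), d[4])[as.vector(m), , drop = FALSE]
  peaks <- apply(C, 1, max)
  cut <- stats::quantile(peaks, peak_quantile, names = FALSE)
  sel <- peaks > cut
  if (!any(sel)) {
    warning("no voxel exceeds the peak percentile; using whole-mask mean")
    sel <- rep(TRUE, nrow(C))
  }
  curve <- colMeans(C[sel, , drop = FALSE])
  curve <- curve - mean(curve[seq_len(conc$baseline_frames)])
  structure(list(values = curve, n_voxels = sum(sel),
                 baseline_frames = conc$baseline_frames,
                 frame_interval_s = conc$frame_interval_s),
            class = "arterial_input_curve")
}

#' @export
print.arterial_input_curve <- function(x, ...) {
  cat(sprintf("<arterial_input_curve> %d frames, peak %.3g 1/s from %d voxels\n",
              length(x$values), max(x$values), x$n_voxels))
  invisible(x)
}

# Block-circulant matrix of the zero-padded AIF, scaled by dt.
circulant_aif_matrix <- function(aif_values, dt, pad_factor = 2L) {
  n <- length(aif_values)
  L <- pad_factor * n
  a <- c(aif_values, rep(0, L - n))
  idx <- outer(seq_len(L), seq_len(L), function(i, j) ((i - j) %% L) + 1L)
  matrix(a[idx], L, L) * dt
}

#' Deconvolve tissue curves against an arterial reference to map CBF
#'
#' Builds the block-circulant matrix of the time-padded AIF (zero-padded to
#' twice the series length so the deconvolution cannot wrap around), inverts
#' it by truncated singular value decomposition — singular values below
#' `svd_threshold_frac` of the largest are zeroed — and solves for the scaled
#' residue function `k(t) = CBF * R(t)` in every voxel. CBF is the maximum of
#' `k(t)`.
#'
#' @param conc A `concentration_curves` object.
#' @param aif An `arterial_input_curve` (or bare numeric vector on the same
#'   frame grid).
#' @param svd_threshold_frac Truncation threshold as a fraction of the largest
#'   singular value.
#' @param mask Optional [roi_mask()]/logical array restricting the solve.
#' @param keep_residue Return the full scaled-residue 4D array (first N
#'   frames) alongside the map.
#'
#' @return List with `cbf` (a [parametric_map()], relative 1/s units) and, if
#'   requested, `residue`. An all-zero AIF invalidates the whole map.
#' @export
deconvolve_cbf <- function(conc, aif, svd_threshold_frac = 0.15, mask = NULL,
                           keep_residue = FALSE) {
  values <- if (inherits(aif, "arterial_input_curve")) aif$values else aif
  d <- dim(conc$curves)
  n <- d[4]
  if (length(values) != n) stop("AIF frame grid mismatch", call. = FALSE)
  dt <- conc$frame_interval_s
  valid <- as.vector(conc$valid) & mask_vector(mask, d[1:3])
  if (max(values) <= 0) {
    empty <- array(NA_real_, d[1:3])
    return(list(cbf = parametric_map(empty, "CBF", mask = array(FALSE, d[1:3])),
                residue = NULL))
  }
  A <- circulant_aif_matrix(values, dt)
  sv <- svd(A)
  w <- ifelse(sv$d >= svd_threshold_frac * max(sv$d), 1 / sv$d, 0)
  Ainv <- sv$v %*% (w * t(sv$u))
  L <- nrow(A)
  C <- matrix(conc$curves, prod(d[1:3]), n)
  Cpad <- cbind(C[valid, , drop = FALSE],
                matrix(0, sum(valid), L - n))
  K <- Cpad %*% t(Ainv)          # voxels x L, rows are k(t)
  cbf_v <- rep(NA_real_, prod(d[1:3]))
  cbf_v[valid] <- apply(K[, seq_len(n), drop = FALSE], 1, max)
  out <- list(cbf = parametric_map(array(cbf_v, d[1:3]), "CBF",
                                   mask = array(valid, d[1:3])))
  if (keep_residue) {
    R4 <- array(0, c(d[1:3], n))
    Rm <- matrix(R4, prod(d[1:3]), n)
    Rm[valid, ] <- K[, seq_len(n)]
    out$residue <- array(Rm, c(d[1:3], n))
  }
  out
}

#' Integrate tissue concentration curves to map CBV
#'
#' Trapezoidal integral of each voxel's concentration curve over time,
#' truncated at a fixed frame index to suppress contrast-agent recirculation.
#'
#' @param conc A `concentration_curves` object.
#' @param truncate_at_frame Integration uses frames `1..min(truncate, N)`.
#' @param mask Optional [roi_mask()] or logical array.
#'
#' @return A [parametric_map()] of CBV (arbitrary relative units).
#' @export
integrate_cbv <- function(conc, truncate_at_frame = 400L, mask = NULL) {
  d <- dim(conc$curves)
  dt <- conc$frame_interval_s
  if (is.null(dt) || dt <= 0) stop("frame interval unknown", call. = FALSE)
  m <- min(truncate_at_frame, d[4])
  C <- matrix(conc$curves, prod(d[1:3]), d[4])[, seq_len(m), drop = FALSE]
  # trapezoid over m frames: interior frames weighted 1, ends 1/2
  wts <- c(0.5, rep(1, m - 2L), 0.5) * dt
  cbv <- as.vector(C %*% wts)
  valid <- as.vector(conc$valid) & mask_vector(mask, d[1:3])
  cbv[!valid] <- NA_real_
  parametric_map(array(cbv, d[1:3]), "CBV", mask = array(valid, d[1:3]))
}

#' Mean transit time as the quotient of CBV and CBF
#'
#' @param cbv,cbf [parametric_map()]s on the same grid.
#' @return A [parametric_map()] of MTT (seconds, on the relative scale of its
#'   inputs). Voxels with CBF = 0 are flagged invalid rather than infinite.
#' @export
compute_mtt <- function(cbv, cbf) {
  if (!identical(dim(cbv$data), dim(cbf$data))) {
    stop("CBV and CBF grids differ", call. = FALSE)
  }
  d <- dim(cbv$data)
  joint <- (cbv$mask %||% array(TRUE, d)) & (cbf$mask %||% array(TRUE, d))
  ok <- joint & is.finite(cbf$data) & cbf$data > 0
  mtt <- array(NA_real_, d)
  mtt[ok] <- cbv$data[ok] / cbf$data[ok]
  parametric_map(mtt, "MTT", mask = ok)
}
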