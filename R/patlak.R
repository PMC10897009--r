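#' Build the reference-region concentration curve from serial R1 maps
#'
#' Concentration is operationalized as delta-R1: per time point, the mean R1
#' over the muscle reference region minus the pre-contrast (first frame)
#' value. The proportionality between delta-R1 and gadolinium concentration
#' cancels out of the Patlak estimate, so no relaxivity value is needed.
#'
#' @param r1_maps Time-ordered list of R1 [parametric_map()]s (1/s).
#' @param muscle_mask [roi_mask()] of the reference tissue (a region with
#'   reversible blood-tissue exchange, e.g. temporal muscle).
#' @return Numeric delta-R1 curve (1/s), one value per time point; the first
#'   is 0 by construction.
#' @export
build_reference_curve <- function(r1_maps, muscle_mask) {
  if (!sum(muscle_mask$data)) stop("empty reference mask", call. = FALSE)
  means <- vapply(r1_maps, function(m) mean(map_values(m, muscle_mask)),
                  numeric(1))
  means - means[1]
}

#' Patlak plot coordinates for one tissue curve
#'
#' The generalized Patlak linearization with a reference-region input:
#' abscissa `X(t) = integral_0^t C_RT dtau / C_RT(t)` (units of time),
#' ordinate `Y(t) = C(t) / C_RT(t)` (unitless). Under unidirectional uptake
#' the points fall on the line `Y = Ki * X + V0`.
#'
#' @param tissue_curve Tissue concentration (delta-R1) per frame.
#' @param ref_curve Reference-tissue concentration per frame.
#' @param frame_times Times in minutes, strictly increasing.
#' @return List with `x` (minutes), `y` (unitless) and `frames` (the retained
#'   frame indices; frames where the reference is zero are dropped).
#' @export
patlak_axes <- function(tissue_curve, ref_curve, frame_times) {
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing", call. = FALSE)
  }
  cum <- pracma::cumtrapz(frame_times, ref_curve)[, 1]
  keep <- which(ref_curve > 0)
  list(x = cum[keep] / ref_curve[keep],
       y = tissue_curve[keep] / ref_curve[keep],
       frames = keep)
}

#' Voxelwise Patlak fit of the blood-to-brain transfer constant
#'
#' Regresses the Patlak ordinate on the abscissa by ordinary least squares in
#' every voxel; the slope is the transfer constant Ki (1/min) and the
#' intercept the apparent distribution volume V0. Negative slopes are
#' retained, not clipped.
#'
#' @param tissue_conc 4D array of tissue delta-R1 over frames (1/s).
#' @param ref_curve Reference-tissue delta-R1 per frame (1/s).
#' @param frame_times Times in minutes, strictly increasing.
#' @param fit_window Integer frame indices used for the regression. Default:
#'   every frame after the first post-injection map. Frames where the
#'   reference curve is non-positive are dropped; at least 3 usable frames are
#'   required.
#' @param mask Optional [roi_mask()] or logical array.
#'
#' @return A `patlak_result`: list of [parametric_map()]s `ki` (1/min),
#'   `v0` (unitless) and `r_squared`.
#' @export
fit_ki <- function(tissue_conc, ref_curve, frame_times,
                   fit_window = NULL, mask = NULL) {
  d <- dim(tissue_conc)
  stopifnot(length(d) == 4L, length(ref_curve) == d[4],
            length(frame_times) == d[4])
  fit_window <- fit_window %||% seq.int(2L, d[4])
  keep <- intersect(fit_window, which(ref_curve > 0))
  if (length(keep) < 3L) {
    stop("fewer than 3 usable frames in the fit window", call. = FALSE)
  }
  cum <- pracma::cumtrapz(frame_times, ref_curve)[, 1]
  x <- cum[keep] / ref_curve[keep]
  nv <- prod(d[1:3])
  C <- matrix(tissue_conc, nv, d[4])[, keep, drop = FALSE]
  Y <- C / rep(ref_curve[keep], each = nv)
  valid <- mask_vector(mask, d[1:3]) & rowSums(!is.finite(Y)) == 0L
  xc <- x - mean(x)
  sxx <- sum(xc * xc)
  ki <- v0 <- rsq <- rep(NA_real_, nv)
  if (any(valid) && sxx > 0) {
    Yv <- Y[valid, , drop = FALSE]
    ybar <- rowMeans(Yv)
    slope <- as.vector(Yv %*% xc) / sxx
    intercept <- ybar - slope * mean(x)
    fitted_dev <- outer(slope, xc)
    ss_tot <- rowSums((Yv - ybar)^2)
    ss_res <- rowSums((Yv - ybar - fitted_dev)^2)
    r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1)
    ki[valid] <- slope
    v0[valid] <- intercept
    rsq[valid] <- pmin(pmax(r2, 0), 1)
  }
  vmask <- array(valid & is.finite(ki), d[1:3])
  structure(
    list(ki = parametric_map(array(ki, d[1:3]), "KI", mask = vmask),
         v0 = parametric_map(array(v0, d[1:3]), "V0", mask = vmask),
         r_squared = parametric_map(array(rsq, d[1:3]), "RSQ", mask = vmask),
         frames_used = keep),
    class = "patlak_result"
  )
}

#' @export
print.patlak_result <- function(x, ...) {
  v <- map_values(x$ki, x$ki$mask %||% array(TRUE, dim(x$ki$data)))
  cat(sprintf("<patlak_result> median Ki %.4g 1/min over %d voxels (%d frames)\n",
              stats::median(v), length(v), length(x$frames_used)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Patlak fit into a per-voxel tibble
#'
#' @param x A `patlak_result`.
#' @param mask Optional [roi_mask()] restricting the rows.
#' @param ... Unused.
#' @return A tibble with voxel indices, `ki`, `v0` and `r_squared`.
#' @export
tidy.patlak_result <- function(x, mask = NULL, ...) {
  d <- dim(x$ki$data)
  m <- x$ki$mask %||% array(TRUE, d)
  if (!is.null(mask)) m <- m & (if (inherits(mask, "roi_mask")) mask$data else mask)
  idx <- which(m, arr.ind = TRUE)
  ki <- x$ki$data[m]; v0 <- x$v0$data[m]; r2 <- x$r_squared$data[m]
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    ki = ki, v0 = v0, r_squared = r2
  )
}

#' One-line summary of a Patlak fit
#'
#' @param x A `patlak_result`.
#' @param ... Unused.
#' @return A one-row tibble with voxel count, median Ki/V0 and median r^2.
#' @export
glance.patlak_result <- function(x, ...) {
  tb <- tidy(x)
  tibble::tibble(
    n_voxels = nrow(tb),
    ki_median = stats::median(tb$ki),
    v0_median = stats::median(tb$v0),
    r_squared_median = stats::median(tb$r_squared),
    n_frames = length(x$frames_used)
  )
}
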