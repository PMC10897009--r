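#' Fit an ADC map from a single-direction diffusion series
#'
#' Voxelwise least-squares slope of `-ln(S/S0)` against the b-value. With two
#' b-values this reduces to the closed form `(ln S0 - ln S_b) / b`; with three
#' or more it is the ordinary least-squares slope on log-signal, which is
#' exact on noise-free mono-exponential decays.
#'
#' @param series A [volume_series()] whose acquisition carries `b_values`
#'   (s/mm^2) for one gradient direction, the first of which must be 0.
#' @param mask Optional [roi_mask()] (or logical array) restricting the fit.
#' @param floor Lower physical bound for ADC; fitted values below it are
#'   clamped and flagged. Default 0.
#'
#' @return A [parametric_map()] of ADC in mm^2/s. Voxels with non-positive
#'   signal inside the mask are flagged invalid (excluded from the map mask),
#'   not raised as errors.
#' @export
fit_adc_direction <- function(series, mask = NULL, floor = 0) {
  b <- series$acquisition$b_values
  if (is.null(b)) stop("series carries no b-values", call. = FALSE)
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  if (length(unique(b)) < 2L || !any(b == 0)) {
    stop("need at least two distinct b-values including b = 0", call. = FALSE)
  }
  dirs <- series$acquisition$directions
  if (!is.null(dirs) && length(unique(dirs[b > 0])) > 1L) {
    stop("series mixes gradient directions; split it first", call. = FALSE)
  }
  d3 <- dim(series$data)[1:3]
  S <- as_signal_matrix(series)
  valid <- mask_vector(mask, d3)
  positive <- rowSums(S <= 0) == 0L
  fit_ok <- valid & positive
  adc <- rep(NA_real_, nrow(S))
  if (any(fit_ok)) {
    Y <- log(S[fit_ok, , drop = FALSE])
    bc <- b - mean(b)
    adc[fit_ok] <- -as.vector(Y %*% bc) / sum(bc * bc)
  }
  flags <- fit_ok & is.finite(adc) & adc < floor
  adc[flags] <- floor
  parametric_map(array(adc, d3), "ADC",
                 mask = array(fit_ok, d3), flags = array(flags, d3))
}

#' Average three directional ADC maps
#'
#' Mean ADC is the voxelwise arithmetic mean of the ADC maps fitted along the
#' three cardinal gradient directions.
#'
#' @param maps List of three ADC [parametric_map()]s on identical grids.
#' @return A [parametric_map()] of mean ADC. A voxel is valid only where all
#'   three inputs are valid.
#' @export
mean_adc <- function(maps) {
  if (length(maps) != 3L) stop("expected exactly three directional maps",
                               call. = FALSE)
  d <- dim(maps[[1]]$data)
  for (m in maps) {
    if (!identical(dim(m$data), d)) stop("grid mismatch between ADC maps",
                                         call. = FALSE)
    if (m$quantity != "ADC") stop("inputs must be ADC maps", call. = FALSE)
  }
  masks <- lapply(maps, function(m) m$mask %||% array(TRUE, d))
  joint <- masks[[1]] & masks[[2]] & masks[[3]]
  avg <- (maps[[1]]$data + maps[[2]]$data + maps[[3]]$data) / 3
  avg[!joint] <- NA_real_
  parametric_map(avg, "ADC", mask = joint)
}

#' Fit a T2 map from a multi-echo series
#'
#' Voxelwise mono-exponential fit `S(TE) = S0 * exp(-TE/T2)`, initialized by
#' the log-linear least-squares solution and refined by Gauss-Newton nonlinear
#' least squares on the signal scale.
#'
#' @param series A [volume_series()] with `echo_times_ms` in its acquisition.
#' @param mask Optional [roi_mask()] or logical array.
#' @param cap_ms Upper physical bound for T2 (ms). Non-decaying voxels
#'   (fitted T2 <= 0 or above the cap) are clamped to the cap and flagged.
#' @param refine Run the nonlinear refinement (default `TRUE`); `FALSE` gives
#'   the pure log-linear estimate.
#'
#' @return A [parametric_map()] of T2 in ms.
#' @export
fit_t2 <- function(series, mask = NULL, cap_ms = 2000, refine = TRUE) {
  te <- series$acquisition$echo_times_ms
  if (is.null(te)) stop("series carries no echo times", call. = FALSE)
  if (length(unique(te)) < 2L) stop("need at least two distinct echo times",
                                    call. = FALSE)
  d3 <- dim(series$data)[1:3]
  S <- as_signal_matrix(series)
  valid <- mask_vector(mask, d3) & rowSums(S <= 0) == 0L
  t2 <- rep(NA_real_, nrow(S))
  flags <- rep(FALSE, nrow(S))
  if (any(valid)) {
    fit <- fit_monoexp(S[valid, , drop = FALSE], te, refine = refine)
    t2v <- 1 / fit$rate
    bad <- !is.finite(t2v) | t2v <= 0 | t2v > cap_ms
    t2v[bad] <- cap_ms
    t2[valid] <- t2v
    flags[valid] <- bad
  }
  parametric_map(array(t2, d3), "T2", mask = array(valid, d3),
                 flags = array(flags, d3))
}

#' Fit an R1 map from a saturation- or inversion-recovery series
#'
#' Saturation recovery fits `S(t) = S0 * (1 - exp(-t * R1))`; inversion
#' recovery fits the magnitude model `S(t) = |S0 * (1 - 2 exp(-t * R1))|`,
#' restoring signal polarity around the null point before the nonlinear fit.
#' Initialization is a separable grid search over R1 (S0 solved in closed
#' form), refined by Gauss-Newton.
#'
#' @param series A [volume_series()] with `recovery_times_ms` and `t1_mode`
#'   (`"saturation"` or `"inversion"`) in its acquisition.
#' @param mask Optional [roi_mask()] or logical array.
#'
#' @return A [parametric_map()] of R1 in 1/s. Voxels whose fit fails are
#'   invalid (outside the map mask).
#' @export
fit_r1 <- function(series, mask = NULL) {
  ti <- series$acquisition$recovery_times_ms
  if (is.null(ti)) stop("series carries no recovery times", call. = FALSE)
  if (length(ti) < 2L) {
    stop("insufficient samples: R1 fitting needs at least two recovery times",
         call. = FALSE)
  }
  mode <- series$acquisition$t1_mode %||% "saturation"
  mode <- match.arg(mode, c("saturation", "inversion"))
  d3 <- dim(series$data)[1:3]
  S <- as_signal_matrix(series)
  valid <- mask_vector(mask, d3) & rowSums(!is.finite(S)) == 0L &
    rowSums(abs(S)) > 0
  r1 <- rep(NA_real_, nrow(S))
  if (any(valid)) {
    Sv <- S[valid, , drop = FALSE]
    # rate grid spans T1 from 20 ms to 20 s
    grid <- exp(seq(log(1 / 20000), log(1 / 20), length.out = 60))
    if (mode == "saturation") {
      rate_ms <- .fit_recovery(Sv, ti, grid,
                               ffun = function(a) 1 - exp(-a),
                               fprime = function(a) exp(-a))$rate
    } else {
      rate_ms <- .fit_ir_magnitude(Sv, ti, grid)
    }
    r1[valid] <- rate_ms * 1000   # 1/ms -> 1/s
  }
  ok <- valid & is.finite(r1) & r1 > 0
  r1[!ok] <- NA_real_
  parametric_map(array(r1, d3), "R1", mask = array(ok, d3))
}

.fit_recovery <- function(S, x, grid, ffun, fprime) {
  init <- grid_init(S, x, grid, ffun)
  gn_separable(S, x, init$s0, init$rate, ffun, fprime,
               rate_bounds = c(1e-7, 1))
}

# Inversion-recovery magnitude data: restore polarity under the two
# hypotheses consistent with the signal minimum, fit both signed models and
# keep the better one per voxel.
.fit_ir_magnitude <- function(S, x, grid) {
  ord <- order(x)
  xo <- x[ord]
  So <- S[, ord, drop = FALSE]
  imin <- max.col(-abs(So), ties.method = "first")
  ffun <- function(a) 1 - 2 * exp(-a)
  fprime <- function(a) 2 * exp(-a)
  fit_hypothesis <- function(n_neg) {
    # n_neg: per-voxel count of early frames whose true signal was negative
    sign_m <- matrix(1, nrow(So), ncol(So))
    cols <- col(sign_m)
    sign_m[cols <= n_neg] <- -1
    Ss <- So * sign_m
    fit <- .fit_recovery(Ss, xo, grid, ffun, fprime)
    A <- outer(fit$rate, xo)
    rss <- rowSums((Ss - fit$s0 * ffun(A))^2)
    list(rate = fit$rate, rss = rss)
  }
  h1 <- fit_hypothesis(imin)        # frames up to and including the minimum
  h2 <- fit_hypothesis(imin - 1L)   # frames strictly before the minimum
  ifelse(h1$rss <= h2$rss, h1$rate, h2$rate)
}

#' Fit serial R1 maps over time
#'
#' Applies [fit_r1()] to a time-ordered list of T1-mapping series (for
#' example, serial post-contrast acquisitions used for permeability mapping)
#' and returns the R1 maps in the same order.
#'
#' @param series_list List of [volume_series()], all on the same grid, in
#'   temporal order.
#' @param mask Optional [roi_mask()] or logical array shared by all fits.
#' @return List of R1 [parametric_map()]s.
#' @export
fit_r1_series <- function(series_list, mask = NULL) {
  if (length(series_list) == 0L) stop("empty series list", call. = FALSE)
  d3 <- dim(series_list[[1]]$data)[1:3]
  for (s in series_list) {
    if (!identical(dim(s$data)[1:3], d3)) {
      stop("series grids differ across time points", call. = FALSE)
    }
  }
  lapply(series_list, fit_r1, mask = mask)
}
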