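#' Image series with acquisition metadata
#'
#' A `volume_series` is the universal carrier between processing stages: a 3D
#' or 4D array of signal magnitude together with voxel geometry and an
#' acquisition descriptor that says how the frames were encoded (b-values and
#' directions for diffusion, echo times for T2 mapping, recovery times for T1
#' mapping, or a frame interval plus baseline count for dynamic series).
#'
#' @param data Numeric 3D or 4D array `(x, y, z[, frame])`. 3D input is
#'   promoted to a single-frame 4D array.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param acquisition Named list describing the frame dimension. Recognised
#'   fields: `modality`, `b_values` (s/mm^2), `directions` (integer index per
#'   frame), `echo_times_ms`, `recovery_times_ms` and `t1_mode`
#'   (`"saturation"` or `"inversion"`), `frame_interval_s`, `baseline_frames`,
#'   `frame_times_min`.
#'
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, voxel_size, acquisition = list()) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 3D or 4D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive lengths in mm", call. = FALSE)
  }
  n_frames <- dim(data)[4L]
  for (f in c("b_values", "echo_times_ms", "recovery_times_ms",
              "frame_times_min")) {
    if (!is.null(acquisition[[f]]) && length(acquisition[[f]]) != n_frames) {
      stop(sprintf("acquisition$%s has %d entries but the series has %d frames",
                   f, length(acquisition[[f]]), n_frames), call. = FALSE)
    }
  }
  structure(
    list(data = data, voxel_size = voxel_size, acquisition = acquisition),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d, %d frame(s), voxels %s mm, modality: %s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x"),
              x$acquisition$modality %||% "unspecified"))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[4L]

#' Voxelwise map of one physical quantity
#'
#' @param data Numeric 3D array.
#' @param quantity One of `"ADC"`, `"T2"`, `"T1"`, `"R1"`, `"CBF"`, `"CBV"`,
#'   `"MTT"`, `"KI"`, `"V0"`, `"CVR"`, `"RSQ"`.
#' @param units Units string; defaults to the conventional units of
#'   `quantity` (ADC mm^2/s, T2/T1 ms, R1 1/s, KI 1/min, CVR percent).
#' @param mask Optional logical array of valid voxels. Non-finite values are
#'   only permitted outside the mask.
#' @param flags Optional logical array marking voxels whose fit was clamped or
#'   otherwise degraded (still inside the mask).
#'
#' @return A `parametric_map` object.
#' @export
parametric_map <- function(data, quantity, units = NULL, mask = NULL,
                           flags = NULL) {
  quantity <- match.arg(quantity, names(.quantity_units))
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (is.null(units)) units <- .quantity_units[[quantity]]
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data))) {
      stop("`mask` dimensions do not match `data`", call. = FALSE)
    }
    mask <- array(as.logical(mask), dim(data))
    if (any(!is.finite(data[mask]))) {
      stop("non-finite values inside the validity mask", call. = FALSE)
    }
  }
  structure(
    list(data = data, quantity = quantity, units = units, mask = mask,
         flags = flags),
    class = "parametric_map"
  )
}

.quantity_units <- c(
  ADC = "mm^2/s", T2 = "ms", T1 = "ms", R1 = "1/s",
  CBF = "1/s (relative)", CBV = "a.u.", MTT = "s (relative)",
  KI = "1/min", V0 = "unitless", CVR = "%", RSQ = "unitless"
)

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$data)
  v <- if (is.null(x$mask)) x$data else x$data[x$mask]
  v <- v[is.finite(v)]
  cat(sprintf("<parametric_map> %s [%s] %dx%dx%d, median %s over %d valid voxels\n",
              x$quantity, x$units, d[1], d[2], d[3],
              signif(stats::median(v), 4), length(v)))
  invisible(x)
}

#' @export
dim.parametric_map <- function(x) dim(x$data)

#' Values of a parametric map inside a region
#'
#' @param map A [parametric_map()].
#' @param roi A [roi_mask()] (or logical array) selecting voxels.
#' @return Numeric vector of finite map values in the region.
#' @export
map_values <- function(map, roi) {
  m <- if (inherits(roi, "roi_mask")) roi$data else roi
  if (!identical(dim(m), dim(map$data))) {
    stop("region grid does not match the map grid", call. = FALSE)
  }
  if (!is.null(map$mask)) m <- m & map$mask
  v <- map$data[m]
  v[is.finite(v)]
}

#' Binary region-of-interest mask
#'
#' A 3D boolean mask on a named reference grid. Set algebra and mirroring are
#' only defined between masks sharing the same `space_tag`.
#'
#' @param data Logical (or coercible) 3D array.
#' @param voxel_volume_ul Volume of one voxel in microliters.
#' @param space_tag Identifier of the reference grid the mask lives on.
#'
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(data, voxel_volume_ul, space_tag = "native") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  data <- array(as.logical(data), dim(data))
  data[is.na(data)] <- FALSE
  voxel_volume_ul <- as.numeric(voxel_volume_ul)
  if (length(voxel_volume_ul) != 1L || !is.finite(voxel_volume_ul) ||
      voxel_volume_ul <= 0) {
    stop("`voxel_volume_ul` must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, voxel_volume_ul = voxel_volume_ul,
         space_tag = space_tag),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels (%.2f uL) on grid %s [%s]\n",
              sum(x$data), roi_volume_ul(x),
              paste(dim(x$data), collapse = "x"), x$space_tag))
  invisible(x)
}

#' @export
dim.roi_mask <- function(x) dim(x$data)

#' Mask volume in microliters
#' @param mask A [roi_mask()].
#' @return Volume in uL (voxel count times voxel volume).
#' @export
roi_volume_ul <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$data) * mask$voxel_volume_ul
}

check_same_space <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("masks live on different grids", call. = FALSE)
  }
  if (!identical(a$space_tag, b$space_tag)) {
    stop(sprintf("space_tag mismatch: '%s' vs '%s'", a$space_tag, b$space_tag),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Intersection, union and difference of ROI masks
#'
#' @param a,b [roi_mask()] objects on the same grid and `space_tag`.
#' @return A [roi_mask()].
#' @export
roi_intersect <- function(a, b) {
  check_same_space(a, b)
  roi_mask(a$data & b$data, a$voxel_volume_ul, a$space_tag)
}

#' @rdname roi_intersect
#' @export
roi_union <- function(a, b) {
  check_same_space(a, b)
  roi_mask(a$data | b$data, a$voxel_volume_ul, a$space_tag)
}

#' @rdname roi_intersect
#' @export
roi_setdiff <- function(a, b) {
  check_same_space(a, b)
  roi_mask(a$data & !b$data, a$voxel_volume_ul, a$space_tag)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
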