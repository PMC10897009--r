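# Lesion segmentation, mirrored homologues and relative regional indices.

# 3D binary dilation/erosion with a 6-connected (face-neighbor) structuring
# element, implemented by axis shifts; radius r applies the element r times.
shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

dilate3 <- function(a, radius = 1L) {
  for (r in seq_len(radius)) {
    a <- a | shift3(a, 1, 0, 0) | shift3(a, -1, 0, 0) |
      shift3(a, 0, 1, 0) | shift3(a, 0, -1, 0) |
      shift3(a, 0, 0, 1) | shift3(a, 0, 0, -1)
  }
  a
}

erode3 <- function(a, radius = 1L) !dilate3(!a, radius)

close3 <- function(a, radius = 1L) erode3(dilate3(a, radius), radius)

# Largest 6-connected component, by iterative vectorized flood fill.
largest_component <- function(a) {
  remaining <- a
  best <- array(FALSE, dim(a))
  best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(a))
    seed[which(remaining)[1]] <- TRUE
    comp <- seed
    repeat {
      grown <- dilate3(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  best
}

#' Segment a lesion by contralateral-referenced thresholding
#'
#' Semi-automatic lesion delineation: the threshold is the contralateral
#' reference mean minus (`polarity = "hypo"`, e.g. cytotoxic edema on ADC) or
#' plus (`polarity = "hyper"`, e.g. vasogenic edema on T2) `k_sd` standard
#' deviations. Supra-/sub-threshold voxels in the ipsilateral hemisphere are
#' cleaned by a 1-voxel morphological closing and reduced to the largest
#' 6-connected component.
#'
#' @param map A [parametric_map()] to segment.
#' @param contralateral_mask [roi_mask()] of normal reference tissue
#'   (contralateral hemisphere, within brain).
#' @param polarity `"hypo"` or `"hyper"`.
#' @param k_sd Threshold distance in contralateral standard deviations.
#' @param ipsilateral_mask [roi_mask()] of candidate tissue; defaults to the
#'   mirror image of `contralateral_mask`.
#' @param closing_radius Radius of the morphological closing (voxels).
#'
#' @return A [roi_mask()]; empty (with attribute `empty = TRUE`) if nothing
#'   survives thresholding.
#' @export
segment_lesion <- function(map, contralateral_mask,
                           polarity = c("hypo", "hyper"), k_sd = 2,
                           ipsilateral_mask = NULL, closing_radius = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(ipsilateral_mask)) {
    ipsilateral_mask <- mirror_mask(contralateral_mask)
  }
  check_same_space(contralateral_mask, ipsilateral_mask)
  ref <- map_values(map, contralateral_mask)
  if (length(ref) < 2L) stop("contralateral statistics not computable",
                             call. = FALSE)
  thr <- mean(ref) + (if (polarity == "hyper") 1 else -1) * k_sd * stats::sd(ref)
  vals <- map$data
  hit <- if (polarity == "hyper") vals > thr else vals < thr
  hit[!is.finite(vals)] <- FALSE
  hit <- hit & ipsilateral_mask$data
  if (!is.null(map$mask)) hit <- hit & map$mask
  if (any(hit)) {
    hit <- close3(hit, closing_radius) & ipsilateral_mask$data
    hit <- largest_component(hit)
  }
  out <- roi_mask(hit, contralateral_mask$voxel_volume_ul,
                  contralateral_mask$space_tag)
  attr(out, "empty") <- !any(hit)
  attr(out, "threshold") <- thr
  out
}

#' Lesion core: intersection of acute and final lesion masks
#'
#' The irreversibly injured acute tissue that proceeded to infarction:
#' `core = final lesion AND acute ischemic area`, voxelwise.
#'
#' @param acute Acute ischemic-area [roi_mask()] (ADC-derived, occlusion).
#' @param final Final lesion [roi_mask()] (T2-derived, day 4).
#' @return A [roi_mask()].
#' @export
derive_core <- function(acute, final) {
  roi_intersect(acute, final)
}

#' Mirror a mask about the midline sagittal plane
#'
#' Pure left-right grid reflection: with the default midline (the central
#' plane of the grid) voxel `x` maps to `nx + 1 - x`, which preserves volume
#' exactly. An explicit `midline` gives the reflection plane `x -> 2*midline -
#' x` in voxel coordinates; reflections that leave the grid are an error.
#'
#' @param mask A [roi_mask()].
#' @param midline Optional reflection plane in voxel coordinates (use `k +
#'   0.5` for the boundary after column `k`). Default: the grid center.
#' @return The mirrored [roi_mask()].
#' @export
mirror_mask <- function(mask, midline = NULL) {
  d <- dim(mask$data)
  if (is.null(midline)) {
    out <- mask$data[rev(seq_len(d[1])), , , drop = FALSE]
  } else {
    src <- round(2 * midline - seq_len(d[1]))
    if (any(mask$data) ) {
      occupied <- which(apply(mask$data, 1, any))
      tgt <- round(2 * midline - occupied)
      if (any(tgt < 1 | tgt > d[1])) {
        stop("reflected mask exits the grid", call. = FALSE)
      }
    }
    out <- array(FALSE, d)
    ok <- src >= 1 & src <= d[1]
    out[which(ok), , ] <- mask$data[src[ok], , , drop = FALSE]
  }
  dim(out) <- d
  roi_mask(out, mask$voxel_volume_ul, mask$space_tag)
}

#' Relative regional index of a parametric map
#'
#' The ipsilesional region mean expressed as a percentage of the mean over
#' the contralateral homologous region: `100 * mean(map | ipsi) / mean(map |
#' contra)`. Because absolute perfusion units are arbitrary (they depend on
#' bolus injection and AIF scaling), only these relative indices are
#' interpretable across subjects.
#'
#' @param map A [parametric_map()].
#' @param ipsi,contra Non-empty [roi_mask()]s.
#' @return Percentage (scalar). `NA` with a warning if the contralateral mean
#'   is zero.
#' @export
relative_regional_index <- function(map, ipsi, contra) {
  vi <- map_values(map, ipsi)
  vc <- map_values(map, contra)
  if (!length(vi) || !length(vc)) {
    stop("both regions must contain valid voxels", call. = FALSE)
  }
  mc <- mean(vc)
  if (mc == 0) {
    warning("contralateral mean is zero; index undefined")
    return(NA_real_)
  }
  100 * mean(vi) / mc
}

#' Lesion volume as a fraction of the hemisphere
#'
#' @param mask Lesion [roi_mask()].
#' @param hemisphere Hemisphere [roi_mask()] on the same grid.
#' @return Unitless fraction in `[0, 1]`.
#' @export
hemispheric_lesion_volume <- function(mask, hemisphere) {
  check_same_space(mask, hemisphere)
  hv <- roi_volume_ul(hemisphere)
  if (hv <= 0) stop("empty hemisphere", call. = FALSE)
  roi_volume_ul(mask) / hv
}

#' Minimum-lesion-volume inclusion rule
#'
#' A subject is included only if the acute ischemic volume is strictly larger
#' than the cutoff (default 30 uL); a lesion of exactly the cutoff volume is
#' excluded.
#'
#' @param acute Acute lesion [roi_mask()].
#' @param min_volume_ul Strict lower bound in microliters.
#' @return Logical.
#' @export
inclusion_filter <- function(acute, min_volume_ul = 30) {
  roi_volume_ul(acute) > min_volume_ul
}
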