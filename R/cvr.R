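#' Normalize a BOLD series to its voxelwise baseline
#'
#' Divides each voxel's time course by its own mean over the pre-stimulus
#' baseline frames, so the baseline mean of the output is exactly 1 in every
#' valid voxel and global multiplicative scaling of the raw signal cancels.
#'
#' @param series A [volume_series()] with `baseline_frames` in its
#'   acquisition (all frames before stimulus onset).
#' @param baseline_frames Override of the acquisition field.
#' @param mask Optional [roi_mask()] or logical array.
#'
#' @return A `bold_normalized` object: list with `data` (4D normalized
#'   signal), `baseline_frames`, and `valid` (voxels with positive baseline).
#' @export
normalize_to_baseline <- function(series, baseline_frames = NULL,
                                  mask = NULL) {
  baseline_frames <- baseline_frames %||% series$acquisition$baseline_frames
  if (is.null(baseline_frames) || baseline_frames < 10L) {
    stop("need at least 10 baseline frames", call. = FALSE)
  }
  d <- dim(series$data)
  if (d[4] < baseline_frames + 100L) {
    stop("series must extend at least 100 frames past baseline", call. = FALSE)
  }
  S <- as_signal_matrix(series)
  base <- rowMeans(S[, seq_len(baseline_frames), drop = FALSE])
  valid <- mask_vector(mask, d[1:3]) & is.finite(base) & base > 0
  out <- matrix(NA_real_, nrow(S), d[4])
  out[valid, ] <- S[valid, , drop = FALSE] / base[valid]
  structure(list(data = array(out, d), baseline_frames = baseline_frames,
                 valid = array(valid, d[1:3])),
            class = "bold_normalized")
}

#' Locate the frame of maximal BOLD response
#'
#' Averages the normalized signal over the contralateral mask into one
#' reference time course and returns the post-baseline frame where the
#' absolute deviation from baseline (|signal - 1|) is largest. Ties go to the
#' earliest frame.
#'
#' @param normalized A `bold_normalized` object.
#' @param contralateral_mask [roi_mask()] (or logical array) of the
#'   contralateral hemisphere.
#' @return Integer frame index (into the full series).
#' @export
find_peak_index <- function(normalized, contralateral_mask) {
  m <- if (inherits(contralateral_mask, "roi_mask")) contralateral_mask$data
       else contralateral_mask
  m <- m & normalized$valid
  if (!any(m)) stop("contralateral mask selects no valid voxels", call. = FALSE)
  d <- dim(normalized$data)
  M <- matrix(normalized$data, prod(d[1:3]), d[4])
  curve <- colMeans(M[as.vector(m), , drop = FALSE])
  post <- seq.int(normalized$baseline_frames + 1L, d[4])
  dev <- abs(curve[post] - 1)
  post[which.max(dev)]   # which.max returns the first maximum
}

#' Map cerebrovascular reactivity from a normalized BOLD series
#'
#' Voxelwise mean percent signal change over a fixed-length window of frames
#' centered on the peak response: `100 * (mean(S_norm[peak-w/2, peak+w/2)) -
#' 1)`. A window extending past the series end or before the response epoch
#' (the first post-baseline frame) is shifted inside those bounds (with a
#' warning) rather than truncated, preserving the fixed averaging length.
#'
#' @param normalized A `bold_normalized` object.
#' @param peak_index Frame of maximal response, from [find_peak_index()].
#' @param window Window length in frames.
#'
#' @return A [parametric_map()] of CVR in percent.
#' @export
cvr_map <- function(normalized, peak_index, window = 100L) {
  d <- dim(normalized$data)
  lo <- normalized$baseline_frames + 1L
  if (window > d[4] - lo + 1L) {
    stop("window longer than the post-baseline series", call. = FALSE)
  }
  start <- peak_index - window %/% 2L
  end <- start + window - 1L
  if (start < lo || end > d[4]) {
    warning("peak window extends past the response-epoch bounds; shifting it inside")
    start <- min(max(start, lo), d[4] - window + 1L)
    end <- start + window - 1L
  }
  M <- matrix(normalized$data, prod(d[1:3]), d[4])
  cvr <- 100 * (rowMeans(M[, start:end, drop = FALSE]) - 1)
  cvr[!normalized$valid] <- NA_real_
  parametric_map(array(cvr, d[1:3]), "CVR", mask = normalized$valid)
}
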