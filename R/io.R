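# NIfTI + JSON-sidecar I/O. One .nii.gz per series/map, with acquisition or
# quantity metadata in an accompanying .json of the same stem.

sidecar_path <- function(nii_path) {
  sub("\\.nii(\\.gz)?$", ".json", nii_path)
}

#' Write and read a volume series as NIfTI + JSON sidecar
#'
#' @param series A [volume_series()].
#' @param nii_path Output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @return `nii_path`, invisibly.
#' @export
write_volume_series <- function(series, nii_path) {
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$voxel_size,
                                    series$acquisition$frame_interval_s %||% 1))
  RNifti::writeNifti(img, nii_path)
  jsonlite::write_json(
    c(series$acquisition, list(voxel_size = series$voxel_size)),
    sidecar_path(nii_path), auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(nii_path) {
  jp <- sidecar_path(nii_path)
  if (!file.exists(jp)) {
    rlang::abort(sprintf("sidecar %s not found", jp),
                 class = "strokemri_sidecar_error")
  }
  side <- tryCatch(jsonlite::read_json(jp, simplifyVector = TRUE),
                   error = function(e) {
                     rlang::abort(sprintf("sidecar %s is not valid JSON: %s",
                                          jp, conditionMessage(e)),
                                  class = "strokemri_sidecar_error")
                   })
  if (is.null(side$modality)) {
    rlang::abort(sprintf("sidecar %s lacks the 'modality' field", jp),
                 class = "strokemri_sidecar_error")
  }
  img <- RNifti::readNifti(nii_path)
  data <- array(as.numeric(img), dim(img))
  vx <- side$voxel_size %||% attr(RNifti::niftiHeader(nii_path), "pixdim")[2:4]
  side$voxel_size <- NULL
  volume_series(data, vx, acquisition = side)
}

#' Write and read a parametric map as NIfTI + JSON sidecar
#'
#' Invalid voxels are stored as NaN; the mask is reconstructed as the finite
#' voxels on read.
#'
#' @param map A [parametric_map()].
#' @param nii_path Output path.
#' @return `nii_path`, invisibly.
#' @export
write_parametric_map <- function(map, nii_path) {
  data <- map$data
  if (!is.null(map$mask)) data[!map$mask] <- NaN
  img <- RNifti::asNifti(data, pixdim = c(1, 1, 1))
  RNifti::writeNifti(img, nii_path)
  jsonlite::write_json(list(quantity = map$quantity, units = map$units),
                       sidecar_path(nii_path), auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' @rdname write_parametric_map
#' @export
read_parametric_map <- function(nii_path) {
  jp <- sidecar_path(nii_path)
  side <- jsonlite::read_json(jp, simplifyVector = TRUE)
  img <- RNifti::readNifti(nii_path)
  data <- array(as.numeric(img), dim(img))
  parametric_map(data, side$quantity, units = side$units,
                 mask = is.finite(data))
}

#' Write and read an ROI mask as uint8 NIfTI
#'
#' @param mask A [roi_mask()].
#' @param nii_path Output path.
#' @return `nii_path`, invisibly.
#' @export
write_roi_mask <- function(mask, nii_path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                         datatype = "uint8")
  RNifti::writeNifti(img, nii_path)
  jsonlite::write_json(list(voxel_volume_ul = mask$voxel_volume_ul,
                            space_tag = mask$space_tag),
                       sidecar_path(nii_path), auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(nii_path) {
  side <- jsonlite::read_json(sidecar_path(nii_path), simplifyVector = TRUE)
  img <- RNifti::readNifti(nii_path)
  data <- array(as.numeric(img), dim(img)) > 0
  roi_mask(data, side$voxel_volume_ul, side$space_tag %||% "native")
}

#' Write a phantom subject to disk with a manifest
#'
#' Writes every simulated series and geometry mask under `dir` and a
#' `manifest.json` listing the file layout, so the subject can be re-read and
#' analysed without regenerating it.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(group = subject$group, sessions = list())
  for (sess in names(subject$sessions)) {
    sdir <- file.path(dir, sess)
    dir.create(sdir, showWarnings = FALSE)
    bundle <- subject$sessions[[sess]]
    entry <- list()
    for (mod in c("dwi", "t2", "dsc", "bold")) {
      if (is.null(bundle[[mod]])) next
      fp <- file.path(sdir, paste0(mod, ".nii.gz"))
      write_volume_series(bundle[[mod]], fp)
      entry[[mod]] <- fp
    }
    if (!is.null(bundle$r1_series)) {
      entry$r1_series <- vapply(seq_along(bundle$r1_series), function(k) {
        fp <- file.path(sdir, sprintf("t1map_%02d.nii.gz", k))
        write_volume_series(bundle$r1_series[[k]], fp)
        fp
      }, character(1))
    }
    manifest$sessions[[sess]] <- entry
  }
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  manifest$masks <- list()
  for (mk in c("brain_mask", "hemi_left", "hemi_right", "muscle_mask",
               "acute_mask", "final_mask")) {
    if (is.null(subject$truth[[mk]])) next
    fp <- file.path(mdir, paste0(mk, ".nii.gz"))
    write_roi_mask(subject$truth[[mk]], fp)
    manifest$masks[[mk]] <- fp
  }
  manifest$synthetic_sds <- subject$truth$synthetic_sds
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a subject written by [write_subject()]
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return A subject list consumable by [run_subject()].
#' @export
read_subject <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sessions <- lapply(man$sessions, function(entry) {
    bundle <- list()
    for (mod in c("dwi", "t2", "dsc", "bold")) {
      if (!is.null(entry[[mod]])) bundle[[mod]] <- read_volume_series(entry[[mod]])
    }
    if (!is.null(entry$r1_series)) {
      bundle$r1_series <- lapply(entry$r1_series, read_volume_series)
    }
    bundle
  })
  masks <- lapply(man$masks, read_roi_mask)
  masks$synthetic_sds <- man$synthetic_sds
  list(sessions = sessions, masks = masks, group = man$group)
}

#' Read a phantom configuration from YAML
#'
#' The YAML keys mirror the arguments of [phantom_config()].
#'
#' @param path YAML file.
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(phantom_config, y)
}

#' Export cohort tables to CSV
#'
#' Writes the long records, the group summary, the per-subject volumes and
#' the exclusion log as four CSV files.
#'
#' @param summary A `cohort_summary`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
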