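#' Quantify every modality of one subject and derive lesion-core analytics
#'
#' Runs the full per-subject analysis: per session, mean ADC (three-direction
#' average), T2 mapping and DSC perfusion (CBF by block-circulant SVD
#' deconvolution against a contralateral arterial reference, CBV by truncated
#' integration, MTT = CBV/CBF); at day 4 additionally serial R1 mapping with a
#' reference-region Patlak fit of Ki and CVR mapping from the hypercapnic
#' BOLD challenge. Lesion masks are segmented from the occlusion ADC map
#' (hypointense) and the day-4 T2 map (hyperintense), intersected into the
#' lesion core and mirrored into the contralateral homologue, and a tidy ROI
#' report is assembled.
#'
#' A missing modality skips its stage with a warning rather than failing the
#' subject, mirroring how technically failed acquisitions are excluded in
#' practice.
#'
#' @param subject A `phantom_subject` from [generate_subject()], or a manifest
#'   list read by [read_subject()], carrying `sessions` plus the geometry
#'   masks (`brain_mask`, `hemi_left`, `hemi_right`, `muscle_mask`) under
#'   `truth` or `masks`.
#' @param params Analysis parameters: `svd_threshold_frac`,
#'   `cbv_truncate_frame`, `k_sd`, `cvr_window`, `patlak_fit_window`.
#' @param subject_id Identifier used in the report.
#'
#' @return A `subject_result`: list with `maps` (per session), `lesions`
#'   (acute, final, core, core_contra [roi_mask()]s), `included` (inclusion
#'   filter outcome), `volumes`, `report` (tidy tibble: subject, group,
#'   session, region, quantity, value) and `provenance`.
#' @export
run_subject <- function(subject,
                        params = list(),
                        subject_id = "subject01") {
  p <- list(svd_threshold_frac = 0.15, cbv_truncate_frame = 400L,
            k_sd = 2, cvr_window = 100L, patlak_fit_window = NULL)
  p[names(params)] <- params
  masks <- subject$truth %||% subject$masks
  brain <- masks$brain_mask
  hemi_left <- masks$hemi_left
  hemi_right <- masks$hemi_right
  muscle <- masks$muscle_mask
  contra_brain <- roi_intersect(hemi_left, brain)
  group <- subject$group %||% NA_character_
  maps <- list()
  for (sess in names(subject$sessions)) {
    bundle <- subject$sessions[[sess]]
    out <- list()
    if (!is.null(bundle$dwi)) {
      dirs <- split_dwi_directions(bundle$dwi)
      out$adc <- mean_adc(lapply(dirs, fit_adc_direction, mask = brain$data | muscle$data))
    } else warning(sprintf("%s/%s: no diffusion series; ADC skipped", subject_id, sess))
    if (!is.null(bundle$t2)) {
      out$t2 <- fit_t2(bundle$t2, mask = brain$data | muscle$data)
    } else warning(sprintf("%s/%s: no T2 series; T2 skipped", subject_id, sess))
    if (!is.null(bundle$dsc)) {
      conc <- signal_to_concentration(bundle$dsc, mask = brain$data | muscle$data)
      aif <- extract_aif(conc, contra_brain)
      out$cbf <- deconvolve_cbf(conc, aif,
                                svd_threshold_frac = p$svd_threshold_frac,
                                mask = brain$data)$cbf
      out$cbv <- integrate_cbv(conc, truncate_at_frame = p$cbv_truncate_frame,
                               mask = brain$data)
      out$mtt <- compute_mtt(out$cbv, out$cbf)
    } else warning(sprintf("%s/%s: no DSC series; perfusion skipped", subject_id, sess))
    if (!is.null(bundle$r1_series)) {
      r1_maps <- fit_r1_series(bundle$r1_series, mask = brain$data | muscle$data)
      ref <- build_reference_curve(r1_maps, muscle)
      times <- vapply(bundle$r1_series,
                      function(s) s$acquisition$frame_time_min %||% NA_real_,
                      numeric(1))
      if (anyNA(times)) times <- seq_along(r1_maps) - 1
      nt <- length(r1_maps)
      d3 <- dim(r1_maps[[1]]$data)
      dr1 <- array(0, c(d3, nt))
      base <- r1_maps[[1]]$data
      for (k in seq_len(nt)) dr1[, , , k] <- r1_maps[[k]]$data - base
      dr1[!is.finite(dr1)] <- 0
      pk <- fit_ki(dr1, ref, times, fit_window = p$patlak_fit_window,
                   mask = brain$data)
      out$ki <- pk$ki
      out$v0 <- pk$v0
      out$r1 <- r1_maps
    }
    if (!is.null(bundle$bold)) {
      norm <- normalize_to_baseline(bundle$bold, mask = brain$data)
      peak <- find_peak_index(norm, contra_brain)
      out$cvr <- cvr_map(norm, peak, window = p$cvr_window)
      out$cvr_peak_frame <- peak
    }
    maps[[sess]] <- out
  }
  # lesion masks and core
  if (is.null(maps$occlusion$adc) || is.null(maps$day4$t2)) {
    stop("lesion segmentation requires the occlusion ADC and day-4 T2 maps",
         call. = FALSE)
  }
  acute <- segment_lesion(maps$occlusion$adc, contra_brain, "hypo",
                          k_sd = p$k_sd,
                          ipsilateral_mask = roi_intersect(hemi_right, brain))
  final <- segment_lesion(maps$day4$t2, contra_brain, "hyper", k_sd = p$k_sd,
                          ipsilateral_mask = roi_intersect(hemi_right, brain))
  core <- derive_core(acute, final)
  core_contra <- mirror_mask(core)
  included <- inclusion_filter(acute)
  volumes <- tibble::tibble(
    subject = subject_id, group = group,
    acute_ul = roi_volume_ul(acute), final_ul = roi_volume_ul(final),
    core_ul = roi_volume_ul(core),
    final_over_acute = ifelse(roi_volume_ul(acute) > 0,
                              roi_volume_ul(final) / roi_volume_ul(acute), NA_real_),
    hemispheric_final = hemispheric_lesion_volume(final,
                                                  roi_intersect(hemi_right, brain)),
    sds = masks$synthetic_sds %||% NA_integer_,
    included = included
  )
  report <- build_roi_report(maps, core, core_contra, subject_id, group)
  structure(
    list(maps = maps, lesions = list(acute = acute, final = final,
                                     core = core, core_contra = core_contra),
         included = included, volumes = volumes, report = report,
         provenance = c(p, list(subject_id = subject_id, group = group))),
    class = "subject_result"
  )
}

# Long-format per-subject ROI table: raw core/contra means for ADC, T2, KI,
# CVR; relative regional indices for the perfusion quantities.
build_roi_report <- function(maps, core, core_contra, subject_id, group) {
  rows <- list()
  add <- function(session, region, quantity, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      subject = subject_id, group = group, session = session,
      region = region, quantity = quantity, value = value)
  }
  if (!any(core$data)) {
    return(dplyr::bind_rows(rows))
  }
  for (sess in names(maps)) {
    out <- maps[[sess]]
    for (q in c("adc", "t2", "ki", "cvr")) {
      if (is.null(out[[q]])) next
      add(sess, "core", toupper(q), mean(map_values(out[[q]], core)))
      add(sess, "core_contra", toupper(q),
          mean(map_values(out[[q]], core_contra)))
    }
    for (q in c("cbf", "cbv", "mtt")) {
      if (is.null(out[[q]])) next
      add(sess, "core", paste0("rr", toupper(q)),
          relative_regional_index(out[[q]], core, core_contra))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s (%s): acute %.1f uL, final %.1f uL, core %.1f uL, %s\n",
              x$provenance$subject_id, x$provenance$group,
              x$volumes$acute_ul, x$volumes$final_ul, x$volumes$core_ul,
              if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Simulate and analyse a two-group phantom cohort
#'
#' Generates `n_iso` isoflurane-like and `n_prop` propofol-like phantom
#' subjects (with mild seeded between-subject jitter of lesion size and truth
#' values), runs [run_subject()] on each, and applies the minimum-lesion
#' inclusion rule.
#'
#' @param n_iso,n_prop Group sizes.
#' @param seed Integer seed controlling subject jitter and all noise.
#' @param grid_shape,fov_mm Phantom grid passed to [phantom_config()].
#' @param jitter_sd SD of the lognormal between-subject jitter applied to
#'   lesion radii and day-4 effect values (0 disables).
#' @param lesion_radii_frac,lesion_center_frac Optional base lesion geometry
#'   (fractions of the grid) overriding the presets; the radii are still
#'   jittered per subject.
#' @param ... Further arguments to [phantom_config()].
#'
#' @return List of `subject_result`s (class `cohort_results`).
#' @export
simulate_cohort <- function(n_iso = 11, n_prop = 8, seed = 1L,
                            grid_shape = c(32L, 32L, 12L),
                            fov_mm = c(16, 16, 16),
                            jitter_sd = 0.05,
                            lesion_radii_frac = NULL,
                            lesion_center_frac = NULL, ...) {
  groups <- c(rep("isoflurane", n_iso), rep("propofol", n_prop))
  results <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sseed <- subseed(seed, i * 13)
    set.seed(sseed)
    # lognormal jitter truncated at 2 SD keeps every lesion inside the
    # hemisphere validity bounds of phantom_config
    jit <- function(n = 1, sd = jitter_sd) {
      exp(pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd))
    }
    base <- group_preset(groups[i])
    truth <- list(
      ki_lesion = base$ki_lesion * jit(),
      cvr_lesion = base$cvr_lesion * jit(),
      final_scale = base$final_scale * jit(sd = jitter_sd / 2)
    )
    radii <- (lesion_radii_frac %||% base$acute_radii_frac) * jit(3)
    cfg <- phantom_config(grid_shape = grid_shape, fov_mm = fov_mm,
                          group_preset = groups[i], seed = sseed,
                          lesion_radii_frac = radii,
                          lesion_center_frac = lesion_center_frac,
                          truth = truth, ...)
    subj <- generate_subject(cfg)
    results[[i]] <- run_subject(subj,
                                subject_id = sprintf("%s%02d", substr(groups[i], 1, 3), i))
  }
  structure(results, class = "cohort_results")
}

#' Summarize a cohort into long records and group statistics
#'
#' Stacks the per-subject ROI reports of included subjects into one long
#' table and computes descriptive group mean and SD per (group, session,
#' region, quantity) cell. Relative regional indices are reported for the
#' perfusion quantities only; Ki and CVR are reported per hemisphere
#' (lesion core and contralateral homologue). Inferential modeling is
#' deliberately left to external statistics tooling on the exported long
#' table.
#'
#' @param results A list of `subject_result`s (e.g. from
#'   [simulate_cohort()]).
#' @param include_excluded Keep subjects failing the minimum-lesion inclusion
#'   rule (default `FALSE`).
#'
#' @return A `cohort_summary`: list with `records` (long tibble), `summary`
#'   (group mean/SD/n per cell), `volumes` (per-subject lesion volumes and
#'   synthetic deficit scores) and `exclusions`.
#' @export
summarize_cohort <- function(results, include_excluded = FALSE) {
  if (!length(results)) stop("no subjects", call. = FALSE)
  volumes <- dplyr::bind_rows(lapply(results, function(r) r$volumes))
  keep <- if (include_excluded) rep(TRUE, length(results))
          else vapply(results, function(r) r$included, logical(1))
  if (!any(keep)) stop("no included subjects", call. = FALSE)
  records <- dplyr::bind_rows(lapply(results[keep], function(r) r$report))
  groups <- unique(records$group)
  if (any(!is.na(groups)) && any(table(records$group[!is.na(records$group)],
                                       records$subject[!is.na(records$group)]) < 0)) {
    stop("empty group", call. = FALSE)
  }
  summary <- records |>
    dplyr::group_by(.data$group, .data$session, .data$region,
                    .data$quantity) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  exclusions <- volumes |>
    dplyr::filter(!.data$included) |>
    dplyr::select("subject", "group", "acute_ul")
  structure(list(records = records, summary = summary, volumes = volumes,
                 exclusions = exclusions),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects (%d excluded), %d records\n",
              nrow(x$volumes), nrow(x$exclusions), nrow(x$records)))
  print(x$summary, n = 12)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) x$summary

#' @rdname summarize_cohort
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$volumes),
    n_included = nrow(x$volumes) - nrow(x$exclusions),
    n_records = nrow(x$records),
    n_groups = length(unique(x$volumes$group))
  )
}

#' Directional group contrasts of a phantom cohort
#'
#' Computes the group-mean differences the anesthesia presets are constructed
#' to produce: lesion growth (final/acute volume ratio), day-4 relative CBF
#' and MTT, and day-4 lesion-core Ki and CVR, each as isoflurane-like minus
#' propofol-like group mean.
#'
#' @param summary A `cohort_summary`.
#' @return Tibble with one row per contrast: `quantity`, the two group means,
#'   `difference`, and the `expected_sign` under the preset construction.
#' @export
group_contrasts <- function(summary) {
  sm <- summary$summary
  vol <- summary$volumes |>
    dplyr::filter(.data$subject %in% unique(summary$records$subject))
  cell <- function(grp, sess, region, quant) {
    v <- sm$mean[sm$group == grp & sm$session == sess &
                   sm$region == region & sm$quantity == quant]
    if (length(v)) v[1] else NA_real_
  }
  ratio <- vol |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$final_over_acute), .groups = "drop")
  rget <- function(grp) {
    v <- ratio$m[ratio$group == grp]
    if (length(v)) v[1] else NA_real_
  }
  rows <- tibble::tribble(
    ~quantity, ~isoflurane, ~propofol, ~expected_sign,
    "final_over_acute_volume", rget("isoflurane"), rget("propofol"), 1,
    "rrCBF_day4", cell("isoflurane", "day4", "core", "rrCBF"),
                  cell("propofol", "day4", "core", "rrCBF"), 1,
    "rrMTT_day4", cell("isoflurane", "day4", "core", "rrMTT"),
                  cell("propofol", "day4", "core", "rrMTT"), -1,
    "KI_core_day4", cell("isoflurane", "day4", "core", "KI"),
                    cell("propofol", "day4", "core", "KI"), 1,
    "CVR_core_day4", cell("isoflurane", "day4", "core", "CVR"),
                     cell("propofol", "day4", "core", "CVR"), -1
  )
  rows$difference <- rows$isoflurane - rows$propofol
  rows
}
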