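# ggplot2 views of maps, Patlak fits and cohort summaries.

#' Plot an axial slice of a parametric map
#'
#' @param map A [parametric_map()].
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = NULL) {
  d <- dim(map$data)
  slice <- slice %||% ((d[3] + 1) %/% 2)
  sl <- map$data[, , slice]
  if (!is.null(map$mask)) sl[!map$mask[, , slice]] <- NA
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = sprintf("%s [%s]", map$quantity,
                                                 map$units)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d", map$quantity, slice)) +
    ggplot2::theme_minimal()
}

#' Plot the Patlak linearization of one tissue curve
#'
#' @param tissue_curve Tissue delta-R1 per frame.
#' @param ref_curve Reference-tissue delta-R1 per frame.
#' @param frame_times Times in minutes.
#' @return A ggplot object showing the Patlak points and the fitted line whose
#'   slope is Ki.
#' @export
plot_patlak <- function(tissue_curve, ref_curve, frame_times) {
  ax <- patlak_axes(tissue_curve, ref_curve, frame_times)
  fit <- stats::lm(ax$y ~ ax$x)
  df <- data.frame(x = ax$x, y = ax$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = stats::coef(fit)[1],
                         slope = stats::coef(fit)[2], linetype = 2) +
    ggplot2::labs(
      x = "normalized integrated reference exposure X(t) [min]",
      y = "tissue / reference concentration Y(t)",
      title = sprintf("Patlak plot: Ki = %.4g 1/min, V0 = %.3g",
                      stats::coef(fit)[2], stats::coef(fit)[1])) +
    ggplot2::theme_minimal()
}

#' Plot group mean and SD of one quantity across sessions
#'
#' @param summary A `cohort_summary`.
#' @param quantity Quantity name as it appears in the records (e.g. `"ADC"`,
#'   `"rrCBF"`, `"KI"`).
#' @param region Region to plot (default `"core"`).
#' @return A ggplot object.
#' @export
plot_cohort_summary <- function(summary, quantity, region = "core") {
  df <- summary$summary |>
    dplyr::filter(.data$quantity == !!quantity, .data$region == !!region)
  if (!nrow(df)) stop("no records for that quantity/region", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$mean,
                                   group = .data$group,
                                   colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(y = quantity, x = NULL,
                  title = sprintf("%s in the %s region (group mean ± SD)",
                                  quantity, region)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
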