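# ggplot2 visualisations for each result type.

#' Plot a force-indentation curve with its Hertz-Sneddon fit
#'
#' @param ind Indentation tibble (`delta_nm`, `force_pN`).
#' @param fit A `cm_hertz_fit` for the same curve.
#' @param tip The [tip_geometry()] used in the fit.
#' @return A ggplot object.
#' @export
plot_force_indentation <- function(ind, fit, tip = tip_geometry()) {
  dd <- seq(0, max(ind$delta_nm), length.out = 200)
  model <- tibble::tibble(delta_nm = dd,
                          force_pN = hertz_sneddon_force(dd, fit$E_Pa, tip))
  ggplot2::ggplot(ind, ggplot2::aes(.data$delta_nm, .data$force_pN)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = model, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = fit$fit_range_max_nm, linetype = 2) +
    ggplot2::labs(x = "indentation (nm)", y = "force (pN)",
                  title = sprintf("E = %.0f Pa (r2 = %.3f)", fit$E_Pa, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Plot swelling tracks with the global fit
#'
#' @param tracks Track tibble ([link_tracks()] output).
#' @param t0_s Injection time, s.
#' @param global_fit Optional `cm_swell_fit` from [fit_swelling_global()].
#' @return A ggplot object (normalized radius vs time).
#' @export
plot_swelling <- function(tracks, t0_s, global_fit = NULL) {
  norm <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(r_norm = .data$radius_um /
                    mean(.data$radius_um[.data$time_s < t0_s])) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(norm, ggplot2::aes(.data$time_s, .data$r_norm,
                                          group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_vline(xintercept = t0_s, linetype = 3) +
    ggplot2::labs(x = "time (s)", y = expression(R / R["in"])) +
    ggplot2::theme_minimal()
  if (!is.null(global_fit)) {
    tt <- seq(min(norm$time_s), max(norm$time_s), length.out = 300)
    curve <- tibble::tibble(
      time_s = tt,
      r_norm = 1 + (global_fit$ratio - 1) *
        (1 - exp(-pmax(tt - t0_s, 0) / global_fit$tau_s)),
      cell_id = "global")
    p <- p + ggplot2::geom_line(data = curve, colour = "dodgerblue3",
                                linewidth = 1)
  }
  p
}

#' RT-DC deformation-versus-size scatter
#'
#' @param records Tibble from [rtdc_metrics()] (optionally gated).
#' @return A ggplot object.
#' @export
plot_deformation_area <- function(records) {
  if ("kept" %in% names(records)) records <- records[records$kept, , drop = FALSE]
  ggplot2::ggplot(records, ggplot2::aes(.data$area_um2, .data$deformation)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.5) +
    ggplot2::labs(x = expression("cell size (" * mu * m^2 * ")"),
                  y = "deformation") +
    ggplot2::theme_minimal()
}

#' Group scatter plot with medians and significance stars
#'
#' The cohort-comparison dot plot: one point per observation, a horizontal
#' median bar per group, and the Mann-Whitney stars for each pair.
#'
#' @param data Observation tibble.
#' @param metric,group_by Column names (strings).
#' @param comparisons Optional output of [stratify_and_compare()] for star
#'   annotations (single stratum).
#' @return A ggplot object.
#' @export
plot_group_scatter <- function(data, metric, group_by, comparisons = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data[[group_by]], .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "firebrick",
                          linewidth = 0.4) +
    ggplot2::theme_minimal()
  if (!is.null(comparisons) && nrow(comparisons)) {
    ymax <- max(data[[metric]], na.rm = TRUE)
    lab <- comparisons[1, ]
    p <- p + ggplot2::annotate("text", x = 1.5, y = 1.06 * ymax,
                               label = lab$stars)
  }
  p
}
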