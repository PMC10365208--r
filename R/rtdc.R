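# RT-DC shape analysis: contour descriptors, area-ratio gating, experiment
# summaries. Events are tabular: one row per event with a nested contour.

# Shoelace area (px^2, positive) and perimeter (px) of a closed polygon
# given as an n x 2 matrix of vertices (not repeating the first vertex).
polygon_area_px <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
polygon_perimeter_px <- function(xy) {
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(rowSums(d^2)))
}

# Simple self-intersection check: any non-adjacent edge pair crossing.
# O(n^2); contours are small (tens of vertices).
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

#' Area and perimeter of an event contour
#'
#' Shoelace area and arc-length perimeter of the closed contour polygon,
#' scaled to physical units.
#'
#' @param xy n x 2 matrix of contour vertices in px (closed implicitly; at
#'   least 8 vertices; must be simple).
#' @param pixel_size_um Pixel size, um/px.
#' @param check Validate simplicity (default TRUE; O(n^2)).
#' @return Named list: `area_um2`, `perimeter_um`.
#' @export
contour_area_perimeter <- function(xy, pixel_size_um = 1, check = TRUE) {
  xy <- as.matrix(xy)
  abort_if(nrow(xy) < 8, "contour needs at least 8 vertices")
  if (check) abort_if(!polygon_is_simple(xy), "self-intersecting contour")
  list(area_um2 = polygon_area_px(xy) * pixel_size_um^2,
       perimeter_um = polygon_perimeter_px(xy) * pixel_size_um)
}

#' RT-DC deformation (circularity deficit)
#'
#' `D = 1 - 2 * sqrt(pi * A) / P`: zero for a circle, growing as the shape
#' departs from circularity.
#'
#' @param area Cross-sectional area (any units).
#' @param perimeter Perimeter (matching length units).
#' @return Deformation, dimensionless.
#' @export
deformation <- function(area, perimeter) {
  abort_if(any(area <= 0), "area must be positive")
  abort_if(any(perimeter <= 0), "perimeter must be positive")
  1 - 2 * sqrt(pi * area) / perimeter
}

#' Area ratio of an event
#'
#' Ratio of the raw pixel-mask area to the polygon (contour) area. Rough or
#' concave boundaries that the contour smooths over push the ratio above 1;
#' the standard gate rejects events above 1.05, whose contour does not
#' represent the cell periphery.
#'
#' @param mask_area_px2 Pixel-mask area in px^2 (pixel count).
#' @param polygon_area_px2 Contour polygon area in px^2.
#' @return Dimensionless ratio.
#' @export
area_ratio <- function(mask_area_px2, polygon_area_px2) {
  abort_if(any(mask_area_px2 <= 0), "empty pixel mask")
  abort_if(any(polygon_area_px2 <= 0), "degenerate polygon")
  mask_area_px2 / polygon_area_px2
}

#' Per-event shape descriptors
#'
#' Computes area, perimeter, deformation and area ratio for every event in
#' a contour table.
#'
#' @param contours Long tibble: `event_id`, `x_px`, `y_px` (vertices in
#'   order, one closed polygon per event).
#' @param pixel_size_um um per px (default 1).
#' @param mask_areas Optional tibble `event_id`, `mask_area_px2`; events
#'   without a mask get `area_ratio = 1` and are flagged (`has_mask`).
#' @param check Validate polygon simplicity per event.
#' @return Tibble: `event_id`, `area_um2`, `perimeter_um`, `deformation`,
#'   `area_ratio`, `has_mask`.
#' @export
rtdc_metrics <- function(contours, pixel_size_um = 1, mask_areas = NULL,
                         check = FALSE) {
  abort_if(!all(c("event_id", "x_px", "y_px") %in% names(contours)),
           "contours need event_id, x_px, y_px")
  if (check) {
    contours |>
      dplyr::group_by(.data$event_id) |>
      dplyr::group_walk(function(df, key) {
        abort_if(nrow(df) < 8, "contour needs at least 8 vertices")
        abort_if(!polygon_is_simple(cbind(df$x_px, df$y_px)),
                 "self-intersecting contour")
      })
  }
  # vectorized shoelace/arc-length across all events at once
  out <- contours |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      area_px2 = abs(sum(.data$x_px * dplyr::lead(.data$y_px,
                                                  default = dplyr::first(.data$y_px)) -
                           dplyr::lead(.data$x_px,
                                       default = dplyr::first(.data$x_px)) *
                           .data$y_px)) / 2,
      perimeter_px = sum(sqrt(
        (dplyr::lead(.data$x_px, default = dplyr::first(.data$x_px)) - .data$x_px)^2 +
          (dplyr::lead(.data$y_px, default = dplyr::first(.data$y_px)) - .data$y_px)^2)),
      .groups = "drop") |>
    dplyr::mutate(area_um2 = .data$area_px2 * pixel_size_um^2,
                  perimeter_um = .data$perimeter_px * pixel_size_um,
                  deformation = deformation(.data$area_um2, .data$perimeter_um))
  if (!is.null(mask_areas)) {
    out <- out |>
      dplyr::left_join(mask_areas, by = "event_id") |>
      dplyr::mutate(
        has_mask = !is.na(.data$mask_area_px2),
        area_ratio = dplyr::if_else(.data$has_mask,
                                    .data$mask_area_px2 / .data$area_px2, 1))
  } else {
    out$has_mask <- FALSE
    out$area_ratio <- 1
  }
  dplyr::select(out, "event_id", "area_um2", "perimeter_um", "deformation",
                "area_ratio", "has_mask")
}

#' Gate events on area ratio and size
#'
#' Keeps events whose contour represents the cell periphery
#' (`area_ratio <= max_area_ratio`, boundary inclusive) and, optionally,
#' whose area lies within bounds.
#'
#' @param records Tibble from [rtdc_metrics()].
#' @param max_area_ratio Gate (default 1.05).
#' @param area_bounds_um2 Optional `c(min, max)` area gate.
#' @return The records with a logical `kept` column; attribute `counts`
#'   carries `c(n_before, n_after)`.
#' @export
gate_events <- function(records, max_area_ratio = 1.05,
                        area_bounds_um2 = NULL) {
  kept <- records$area_ratio <= max_area_ratio
  if (!is.null(area_bounds_um2)) {
    kept <- kept & records$area_um2 >= area_bounds_um2[1] &
      records$area_um2 <= area_bounds_um2[2]
  }
  out <- dplyr::mutate(records, kept = kept)
  attr(out, "counts") <- c(n_before = nrow(records), n_after = sum(kept))
  out
}

#' Summarize an RT-DC experiment
#'
#' Median deformation and mean cell size over gated (kept) events — the
#' per-experiment dot of cohort scatter plots.
#'
#' @param records Gated records ([gate_events()] output). Rows with
#'   `kept = FALSE` are excluded; if no `kept` column, all rows are used.
#' @return One-row tibble: `median_deformation`, `mean_area_um2`,
#'   `n_events`, `n_total`.
#' @export
summarize_experiment <- function(records) {
  n_total <- nrow(records)
  if ("kept" %in% names(records)) records <- records[records$kept, , drop = FALSE]
  abort_if(nrow(records) == 0, "no kept events to summarize")
  tibble::tibble(median_deformation = stats::median(records$deformation),
                 mean_area_um2 = mean(records$area_um2),
                 n_events = nrow(records), n_total = n_total)
}
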