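# Bright-field swelling analysis: H-maxima segmentation, tracking,
# exponential kinetics fits.

#' Segment cells in one bright-field frame
#'
#' Cells appear as dark disks on a bright background. The frame is inverted
#' and Gaussian-smoothed, H-maxima markers (maxima deeper than `h`) seed a
#' marker-based region growing (watershed-style, via Voronoi propagation on
#' the smoothed intensity) restricted to the foreground, and regions are
#' filtered by area. The ellipse-equivalent major axis comes from second
#' moments.
#'
#' @param frame Numeric matrix (2-D intensity image).
#' @param h H-maxima depth as a fraction of the frame dynamic range
#'   (default 0.1).
#' @param min_area_px,max_area_px Region area bounds in px.
#' @param smooth_sigma_px Gaussian smoothing before marker extraction
#'   (default 2).
#' @param pixel_size_nm Pixel size (nm/px) used for the radius column;
#'   `NULL` leaves radii in px.
#' @param marker_scale Integer down-sampling factor used only for the
#'   H-maxima marker search (default 2); region boundaries are always drawn
#'   at full resolution, so this trades marker-search cost, not accuracy.
#' @return List: `labels` (integer matrix) and `regions`, a tibble with
#'   `label`, `cx_px`, `cy_px`, `area_px`, `major_axis_px`, `radius_um`
#'   (NA if no pixel size given).
#' @export
segment_frame <- function(frame, h = 0.1, min_area_px = 50,
                          max_area_px = Inf, smooth_sigma_px = 2,
                          pixel_size_nm = NULL, marker_scale = 2L) {
  abort_if(!is.matrix(frame), "frame must be a 2-D matrix")
  abort_if(h <= 0, "`h` must be positive")
  rng <- range(frame)
  empty <- list(labels = matrix(0L, nrow(frame), ncol(frame)),
                regions = tibble::tibble(
                  label = integer(), cx_px = numeric(), cy_px = numeric(),
                  area_px = numeric(), major_axis_px = numeric(),
                  radius_um = numeric()))
  if (diff(rng) <= .Machine$double.eps) return(empty)
  inv <- max(frame) - frame                     # cells become bright
  sm <- if (smooth_sigma_px > 0) as.matrix(EBImage::gblur(inv, smooth_sigma_px)) else inv
  hb <- h * diff(range(sm))
  if (marker_scale > 1) {
    si <- seq(1, nrow(sm), by = marker_scale)
    sj <- seq(1, ncol(sm), by = marker_scale)
    mk_small <- hmaxima_markers(sm[si, sj, drop = FALSE], hb)
    # expand marked coarse pixels to blocks so each dome stays one component
    big <- kronecker(mk_small, matrix(TRUE, marker_scale, marker_scale))
    markers <- big[seq_len(nrow(sm)), seq_len(ncol(sm)), drop = FALSE]
  } else {
    markers <- hmaxima_markers(sm, hb)
  }
  # foreground: midpoint threshold between background and cell levels
  thr <- EBImage::otsu(EBImage::Image(sm / max(sm)))[1] * max(sm)
  fg <- sm > thr
  markers <- markers & fg
  if (!any(markers)) return(empty)
  seeds <- EBImage::bwlabel(EBImage::Image(markers * 1))
  labels <- EBImage::propagate(EBImage::Image(sm), seeds, mask = fg)
  labm <- matrix(as.integer(EBImage::imageData(labels)), nrow(frame), ncol(frame))
  tab <- tabulate(labm[labm > 0])
  keep <- which(tab >= min_area_px & tab <= max_area_px)
  if (!length(keep)) return(empty)
  labm[!(labm %in% keep)] <- 0L
  mom <- EBImage::computeFeatures.moment(labm)
  ids <- sort(unique(labm[labm > 0]))
  mom <- mom[ids, , drop = FALSE]
  regions <- tibble::tibble(
    label = ids,
    cx_px = mom[, "m.cx"], cy_px = mom[, "m.cy"],
    area_px = tabulate(labm[labm > 0], nbins = max(ids))[ids],
    major_axis_px = mom[, "m.majoraxis"],
    radius_um = if (is.null(pixel_size_nm)) NA_real_ else
      0.5 * mom[, "m.majoraxis"] * pixel_size_nm / 1000)
  list(labels = labm, regions = regions)
}

#' Radius from a segmented region
#'
#' The cell radius is half the ellipse-equivalent major axis of the region.
#'
#' @param major_axis_px Major axis length, px.
#' @param pixel_size_nm Pixel size, nm/px.
#' @return Radius in um.
#' @export
radius_from_region <- function(major_axis_px, pixel_size_nm) {
  0.5 * major_axis_px * pixel_size_nm / 1000
}

#' Link per-frame detections into cell tracks
#'
#' Greedy nearest-centroid frame-to-frame linking with a jump cap; gaps up
#' to `max_gap` frames are bridged with linearly interpolated radii; tracks
#' shorter than `min_track_len` frames are dropped.
#'
#' @param detections Tibble with `frame`, `time_s`, `cx_px`, `cy_px`,
#'   `radius_um` (e.g. stacked [segment_frame()] regions).
#' @param max_jump_px Maximum centroid displacement per frame (default 10;
#'   adhered cells barely move).
#' @param max_gap Maximum number of consecutive missed frames bridged
#'   (default 2).
#' @param min_track_len Minimum surviving track length in frames.
#' @return Tibble: `cell_id`, `frame`, `time_s`, `cx_px`, `cy_px`,
#'   `radius_um`, `interpolated`.
#' @export
link_tracks <- function(detections, max_jump_px = 10, max_gap = 2,
                        min_track_len = 10) {
  abort_if(length(unique(detections$frame)) < 2, "need at least 2 frames")
  det <- dplyr::arrange(tibble::as_tibble(detections), .data$frame)
  frames <- sort(unique(det$frame))
  # active track state: list of (id, last frame, cx, cy, rows)
  tracks <- list(); active <- integer(0); next_id <- 1L
  rows <- vector("list", 0)
  state <- new.env(parent = emptyenv())
  state$pos <- list()   # id -> c(frame, cx, cy)
  for (f in frames) {
    d <- det[det$frame == f, , drop = FALSE]
    taken <- rep(FALSE, nrow(d))
    # try to extend active tracks, oldest first
    for (id in active) {
      p <- state$pos[[as.character(id)]]
      if (f - p[1] > max_gap + 1) next
      if (!nrow(d)) break
      dist <- sqrt((d$cx_px - p[2])^2 + (d$cy_px - p[3])^2)
      dist[taken] <- Inf
      j <- which.min(dist)
      if (is.finite(dist[j]) && dist[j] <= max_jump_px * (f - p[1])) {
        taken[j] <- TRUE
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell_id = id, frame = f, time_s = d$time_s[j],
          cx_px = d$cx_px[j], cy_px = d$cy_px[j],
          radius_um = d$radius_um[j], interpolated = FALSE)
        state$pos[[as.character(id)]] <- c(f, d$cx_px[j], d$cy_px[j])
      }
    }
    # drop tracks that exceeded the gap cap
    active <- Filter(function(id) f - state$pos[[as.character(id)]][1] <= max_gap,
                     active)
    # new tracks from unmatched detections
    for (j in which(!taken)) {
      id <- next_id; next_id <- next_id + 1L
      active <- c(active, id)
      state$pos[[as.character(id)]] <- c(f, d$cx_px[j], d$cy_px[j])
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = id, frame = f, time_s = d$time_s[j],
        cx_px = d$cx_px[j], cy_px = d$cy_px[j],
        radius_um = d$radius_um[j], interpolated = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  # bridge gaps by interpolation, then filter by length
  out <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$frame)
      full <- tibble::tibble(frame = seq(min(df$frame), max(df$frame)))
      j <- dplyr::left_join(full, df, by = "frame")
      gap <- is.na(j$radius_um)
      if (any(gap)) {
        j$time_s <- stats::approx(df$frame, df$time_s, xout = j$frame)$y
        j$radius_um <- stats::approx(df$frame, df$radius_um, xout = j$frame)$y
        j$cx_px <- stats::approx(df$frame, df$cx_px, xout = j$frame)$y
        j$cy_px <- stats::approx(df$frame, df$cy_px, xout = j$frame)$y
        j$interpolated[gap] <- TRUE
      }
      j
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::n() >= min_track_len) |>
    dplyr::ungroup()
  dplyr::mutate(out, cell_id = sprintf("track%03d",
                                       match(.data$cell_id, unique(.data$cell_id))))
}

#' Fit the exponential swelling law to one cell track
#'
#' Fits `R(t) = R_in + (R_fin - R_in) * (1 - exp(-(t - t0)/tau))` to the
#' post-injection samples by nonlinear least squares. `R_in` is fixed to the
#' mean pre-injection radius (reduces parameter correlation); `R_fin` and
#' `tau` are free, with `tau` initialised at 100 s.
#'
#' @param track Tibble with `time_s`, `radius_um` for one cell.
#' @param t0_s Injection time, s.
#' @param tau_init_s Initial characteristic time for the optimiser.
#' @return A list of class `cm_swell_fit`: `R_in_um`, `R_fin_um`, `tau_s`,
#'   `ratio`, `rss`, `n`, `converged`, `identifiable`.
#' @export
fit_swelling <- function(track, t0_s, tau_init_s = 100) {
  pre <- track$time_s < t0_s
  post <- !pre
  abort_if(sum(post) < 10, "need at least 10 post-injection samples")
  R_in <- if (any(pre)) mean(track$radius_um[pre]) else track$radius_um[which(post)[1]]
  t <- track$time_s[post] - t0_s
  r <- track$radius_um[post]
  out <- list(R_in_um = R_in, R_fin_um = R_in, tau_s = NA_real_, ratio = 1,
              rss = sum((r - R_in)^2), n = length(r), converged = FALSE,
              identifiable = FALSE)
  # degenerate: essentially no radius change -> tau unidentifiable
  if (stats::sd(r) < 1e-9 || (max(r) - R_in) < 1e-6 * R_in) {
    out$converged <- TRUE
    class(out) <- "cm_swell_fit"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ R_in + (Rf - R_in) * (1 - exp(-t / tau)),
      start = list(Rf = max(stats::median(r[t > stats::median(t)]), R_in * 1.01),
                   tau = tau_init_s),
      lower = c(Rf = 0.1 * R_in, tau = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out$R_fin_um <- unname(cf["Rf"])
    out$tau_s <- unname(cf["tau"])
    out$ratio <- out$R_fin_um / R_in
    out$rss <- sum(stats::resid(fit)^2)
    out$converged <- fit$convInfo$isConv %||% TRUE
    out$identifiable <- TRUE
  }
  class(out) <- "cm_swell_fit"
  out
}

#' @export
print.cm_swell_fit <- function(x, ...) {
  cat(sprintf(
    "Swelling fit: R_in %.2f um, R_fin %.2f um, ratio %.3f, tau %.0f s (%s)\n",
    x$R_in_um, x$R_fin_um, x$ratio, x$tau_s %||% NA,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit swelling kinetics for every track in a table
#'
#' @param tracks Output of [link_tracks()] (or any tibble with `cell_id`,
#'   `time_s`, `radius_um`).
#' @inheritParams fit_swelling
#' @return Tibble, one row per cell: `cell_id`, `R_in_um`, `R_fin_um`,
#'   `tau_s`, `ratio`, `rss`, `n`, `converged`.
#' @export
fit_swelling_cells <- function(tracks, t0_s, tau_init_s = 100) {
  tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_swelling(df, t0_s, tau_init_s)
      tibble::tibble(R_in_um = f$R_in_um, R_fin_um = f$R_fin_um,
                     tau_s = f$tau_s, ratio = f$ratio, rss = f$rss,
                     n = f$n, converged = f$converged)
    }) |>
    dplyr::ungroup()
}

#' Global (pooled) swelling fit
#'
#' Normalizes every track by its own pre-injection mean radius, pools the
#' normalized samples and fits a shared pair `(ratio, tau)`:
#' `r(t) = 1 + (ratio - 1) * (1 - exp(-(t - t0)/tau))`.
#'
#' @inheritParams fit_swelling_cells
#' @return A list of class `cm_swell_fit` (with `R_in_um = 1`,
#'   normalized units) plus `n_cells`.
#' @export
fit_swelling_global <- function(tracks, t0_s, tau_init_s = 100) {
  ids <- unique(tracks$cell_id)
  abort_if(length(ids) < 2, "need at least 2 tracks for a global fit")
  norm <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(r_norm = .data$radius_um /
                    mean(.data$radius_um[.data$time_s < t0_s])) |>
    dplyr::ungroup()
  fit <- fit_swelling(
    tibble::tibble(time_s = norm$time_s, radius_um = norm$r_norm), t0_s,
    tau_init_s)
  fit$n_cells <- length(ids)
  fit
}
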