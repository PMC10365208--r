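# Synthetic RT-DC event contours with controlled area and deformation.

# Aspect ratio (a/b >= 1) of an ellipse with deformation D: solved from the
# circularity deficit using an accurate perimeter (Ramanujan II).
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
aspect_for_deformation <- function(D, n_vertices = 64) {
  # deformation of the inscribed n-gon of an ellipse with a/b = q (scale
  # free); solving on the polygon itself makes the generated contour's
  # descriptor equal the target exactly (no discretization offset)
  phis <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  d_poly <- function(q) {
    x <- sqrt(q) * cos(phis); y <- sin(phis) / sqrt(q)
    deformation(polygon_area_px(cbind(x, y)), polygon_perimeter_px(cbind(x, y)))
  }
  if (D <= d_poly(1)) return(1)
  stats::uniroot(function(q) d_poly(q) - D, c(1 + 1e-9, 200),
                 tol = 1e-10)$root
}

#' Simulate RT-DC event contours with ground truth
#'
#' Draws per-event areas and deformations, builds elliptical contour
#' polygons with those exact target descriptors, and rasterizes a pixel
#' mask per event. Events flagged `rough` get boundary spikes added to the
#' mask (not the contour), raising the area ratio above the 1.05 gate by
#' construction.
#'
#' @param n Number of events.
#' @param mean_area_um2,sd_area_um2 Area distribution (normal, truncated at
#'   20% of the mean). Default mean 35 um^2, the B-lymphocyte scale.
#' @param deformation_shape,deformation_rate Gamma distribution of true
#'   deformation (defaults give median about 0.03).
#' @param rough_fraction Fraction of events made rough (default 0).
#' @param roughness_px Spike radius in px for rough events (default 2).
#' @param pixel_size_um um/px (default 0.34, typical RT-DC optics).
#' @param n_vertices Contour vertices per event (default 64).
#' @param rasterize_masks Rasterize a pixel mask per event (default TRUE);
#'   turning it off skips the mask table for large smooth-only cohorts.
#' @param seed Integer seed.
#' @return List: `contours` (long tibble `event_id`, `x_px`, `y_px`),
#'   `mask_areas` (`event_id`, `mask_area_px2`), `truth`
#'   (id, stage, parameter, value, units).
#' @export
sim_rtdc_events <- function(n, mean_area_um2 = 35, sd_area_um2 = 6,
                            deformation_shape = 2.2, deformation_rate = 65,
                            rough_fraction = 0, roughness_px = 2,
                            pixel_size_um = 0.34, n_vertices = 64,
                            rasterize_masks = TRUE, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, {
    areas <- pmax(stats::rnorm(n, mean_area_um2, sd_area_um2),
                  0.2 * mean_area_um2)
    defs <- stats::rgamma(n, shape = deformation_shape,
                          rate = deformation_rate)
    defs <- pmin(defs, 0.25)
    rough <- stats::runif(n) < rough_fraction
    phis <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    ids <- sprintf("ev%05d", seq_len(n))
    # per-event geometry, vectorized: ellipse whose inscribed polygon area
    # equals the target exactly (inflate by the polygon area factor)
    area_px2 <- areas / pixel_size_um^2
    q <- vapply(defs, aspect_for_deformation, numeric(1),
                n_vertices = n_vertices)
    poly_factor <- n_vertices * sin(2 * pi / n_vertices) / (2 * pi)
    ab <- area_px2 / poly_factor / pi
    a <- sqrt(ab * q); b <- sqrt(ab / q)
    th <- stats::runif(n, 0, pi)
    cx <- 40 + stats::runif(n, 0, 2); cy <- 40 + stats::runif(n, 0, 2)
    # vertex matrices: n_vertices x n
    x0 <- outer(cos(phis), a); y0 <- outer(sin(phis), b)
    xs <- sweep(sweep(x0, 2, cos(th), "*") - sweep(y0, 2, sin(th), "*"), 2, cx, "+")
    ys <- sweep(sweep(x0, 2, sin(th), "*") + sweep(y0, 2, cos(th), "*"), 2, cy, "+")
    # truth deformation is the generated polygon's own descriptor (the
    # target ellipse value differs by a ~1e-3 discretization term)
    nxt <- c(2:n_vertices, 1)
    parea <- abs(colSums(xs * ys[nxt, , drop = FALSE] -
                           xs[nxt, , drop = FALSE] * ys)) / 2
    pperim <- colSums(sqrt((xs[nxt, , drop = FALSE] - xs)^2 +
                             (ys[nxt, , drop = FALSE] - ys)^2))
    d_poly <- deformation(parea, pperim)
    masks <- rep(NA_real_, n)
    if (rasterize_masks) {
      gx <- seq_len(80); gy <- seq_len(80)
      for (i in seq_len(n)) {
        u <- outer(gx - cx[i], rep(1, 80)); v <- outer(rep(1, 80), gy - cy[i])
        ru <- u * cos(th[i]) + v * sin(th[i])
        rv <- -u * sin(th[i]) + v * cos(th[i])
        inside <- (ru / a[i])^2 + (rv / b[i])^2 <= 1
        if (rough[i]) {
          # add spike disks on the boundary until the mask exceeds the gate
          # by a safe margin (>= 8% of the polygon area)
          target <- 0.08 * parea[i]
          added <- 0; kspike <- 0
          while (added < target && kspike < 60) {
            kspike <- kspike + 1
            phi <- stats::runif(1, 0, 2 * pi)
            bx <- cx[i] + (a[i] * cos(phi)) * cos(th[i]) -
              (b[i] * sin(phi)) * sin(th[i])
            by <- cy[i] + (a[i] * cos(phi)) * sin(th[i]) +
              (b[i] * sin(phi)) * cos(th[i])
            d2 <- outer((gx - bx)^2, (gy - by)^2, "+")
            newpx <- d2 <= roughness_px^2 & !inside
            inside <- inside | newpx
            added <- added + sum(newpx)
          }
        }
        masks[i] <- sum(inside)
      }
    }
    list(contours = tibble::tibble(event_id = rep(ids, each = n_vertices),
                                   x_px = as.vector(xs),
                                   y_px = as.vector(ys)),
         mask_areas = if (rasterize_masks)
           tibble::tibble(event_id = ids, mask_area_px2 = masks) else NULL,
         truth = tibble::tibble(
           id = rep(ids, each = 3), stage = "rtdc",
           parameter = rep(c("area", "deformation", "rough"), n),
           value = as.vector(rbind(areas, d_poly, as.numeric(rough))),
           units = rep(c("um2", "", ""), n)))
  })
}
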