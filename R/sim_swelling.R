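# Synthetic bright-field swelling stacks with known kinetics.

# Exponential swelling law: R(t) = R_in for t < t0, otherwise
# R_in + (R_fin - R_in) * (1 - exp(-(t - t0)/tau)).
swelling_radius <- function(t, t0, R_in, R_fin, tau) {
  R_in + (R_fin - R_in) * (1 - exp(-pmax(t - t0, 0) / tau))
}

# Render dark disks on a bright background with a smooth (sigmoidal) edge.
# centers_px: matrix [n x 2] (x, y); radii_px: vector. Intensities in [0, 1].
render_disks <- function(nx, ny, centers_px, radii_px, edge_px = 2,
                         bg = 0.85, fg = 0.25) {
  img <- matrix(bg, nrow = nx, ncol = ny)   # x = rows, y = cols
  xs <- seq_len(nx); ys <- seq_len(ny)
  for (i in seq_len(nrow(centers_px))) {
    r <- radii_px[i]
    cx <- centers_px[i, 1]; cy <- centers_px[i, 2]
    xi <- which(abs(xs - cx) <= r + 4 * edge_px)
    yi <- which(abs(ys - cy) <= r + 4 * edge_px)
    if (!length(xi) || !length(yi)) next
    d <- sqrt(outer((xs[xi] - cx)^2, (ys[yi] - cy)^2, "+"))
    # sigmoid edge centered on the true radius, ~edge_px wide
    w <- 1 / (1 + exp((d - r) / (edge_px / 4)))
    img[xi, yi] <- img[xi, yi] + (fg - bg) * w
  }
  img
}

#' Simulate a hypoosmotic swelling time-lapse stack
#'
#' Renders non-overlapping dark disks (bright-field-like cells) whose radii
#' follow the exponential swelling law after water injection at `t0_s`.
#' Default acquisition mirrors the standard protocol: injection after the
#' first 50 s, 1 frame/s, 30 min.
#'
#' @param cells Tibble/data frame with one row per cell: `cx_px`, `cy_px`
#'   (centers), `R_in_um`, `R_fin_um`, `tau_s`.
#' @param dim_px Image size `c(nx, ny)`.
#' @param t0_s Injection time, s (default 50).
#' @param duration_s Record length, s (default 1800).
#' @param frame_rate_hz Frames per second (default 1).
#' @param pixel_size_nm Pixel size, nm/px (default 200, cell-scale
#'   bright-field sampling).
#' @param radius_noise_frac Per-frame fractional jitter of the rendered
#'   radius (sd as fraction of `R_in`), default 0.
#' @param snr Additive Gaussian intensity noise: edge contrast over noise sd;
#'   `Inf` (default) for noise-free frames.
#' @param blur_sigma_px Gaussian blur applied after rendering (default 1).
#' @param seed Integer seed.
#' @return List: `frames` (list of matrices), `times_s`, `t0_s`,
#'   `pixel_size_nm`, `truth` (id, stage, parameter, value, units) and
#'   `masks` (list of per-frame integer truth label matrices).
#' @export
sim_swelling_stack <- function(cells, dim_px = c(256, 256), t0_s = 50,
                               duration_s = 1800, frame_rate_hz = 1,
                               pixel_size_nm = 200, radius_noise_frac = 0,
                               snr = Inf, blur_sigma_px = 1, seed = NULL) {
  cells <- tibble::as_tibble(cells)
  need <- c("cx_px", "cy_px", "R_in_um", "R_fin_um", "tau_s")
  abort_if(!all(need %in% names(cells)), "cells need cx_px, cy_px, R_in_um, R_fin_um, tau_s")
  abort_if(any(cells$R_in_um <= 0) || any(cells$R_fin_um < cells$R_in_um),
           "need R_fin >= R_in > 0")
  px_um <- pixel_size_nm / 1000
  rfin_px <- cells$R_fin_um / px_um
  # reject overlap at final size (with a small guard band)
  if (nrow(cells) > 1) {
    dd <- as.matrix(stats::dist(cells[, c("cx_px", "cy_px")]))
    lim <- outer(rfin_px, rfin_px, "+") + 4
    diag(dd) <- Inf
    abort_if(any(dd < lim), "cells overlap at their final radius")
  }
  times <- seq(0, duration_s, by = 1 / frame_rate_hz)
  with_seed(seed, {
    frames <- vector("list", length(times))
    masks <- vector("list", length(times))
    for (fi in seq_along(times)) {
      r_um <- swelling_radius(times[fi], t0_s, cells$R_in_um, cells$R_fin_um,
                              cells$tau_s)
      if (radius_noise_frac > 0)
        r_um <- pmax(r_um + stats::rnorm(nrow(cells), 0,
                                         radius_noise_frac * cells$R_in_um),
                     0.2 * cells$R_in_um)
      r_px <- r_um / px_um
      img <- render_disks(dim_px[1], dim_px[2],
                          as.matrix(cells[, c("cx_px", "cy_px")]), r_px)
      if (blur_sigma_px > 0) img <- as.matrix(EBImage::gblur(img, blur_sigma_px))
      if (is.finite(snr)) img <- img + stats::rnorm(length(img), 0, 0.6 / snr)
      frames[[fi]] <- img
      lab <- matrix(0L, dim_px[1], dim_px[2])
      xs <- seq_len(dim_px[1]); ys <- seq_len(dim_px[2])
      for (i in seq_len(nrow(cells))) {
        d2 <- outer((xs - cells$cx_px[i])^2, (ys - cells$cy_px[i])^2, "+")
        lab[d2 <= r_px[i]^2] <- i
      }
      masks[[fi]] <- lab
    }
    truth <- purrr::map_dfr(seq_len(nrow(cells)), function(i) tibble::tibble(
      id = sprintf("cell%03d", i), stage = "swelling",
      parameter = c("R_in", "R_fin", "tau", "ratio", "cx", "cy"),
      value = c(cells$R_in_um[i], cells$R_fin_um[i], cells$tau_s[i],
                cells$R_fin_um[i] / cells$R_in_um[i],
                cells$cx_px[i], cells$cy_px[i]),
      units = c("um", "um", "s", "", "px", "px")))
    list(frames = frames, times_s = times, t0_s = t0_s,
         pixel_size_nm = pixel_size_nm, truth = truth, masks = masks)
  })
}

#' Lay out a cohort of swelling cells on a grid
#'
#' Convenience builder for [sim_swelling_stack()]: places `n` cells on a
#' regular grid with spacing safe for their final radii and draws per-cell
#' kinetic parameters around the cohort targets.
#'
#' @param n Number of cells.
#' @param R_in_um Mean initial radius, um (default 4, lymphocyte scale).
#' @param ratio Cohort swelling ratio `R_fin/R_in`.
#' @param tau_s Characteristic time, s.
#' @param cv Between-cell coefficient of variation applied to `R_in` and
#'   `ratio - 1` (default 0.05).
#' @param pixel_size_nm Pixel size used to convert radii to spacing.
#' @param seed Integer seed.
#' @return List: `cells` tibble for [sim_swelling_stack()] and `dim_px`.
#' @export
sim_swelling_cohort <- function(n, R_in_um = 4, ratio = 1.5, tau_s = 200,
                                cv = 0.05, pixel_size_nm = 200, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, {
    px_um <- pixel_size_nm / 1000
    R_in <- R_in_um * pmax(1 + stats::rnorm(n, 0, cv), 0.5)
    rat <- 1 + (ratio - 1) * pmax(1 + stats::rnorm(n, 0, cv), 0.2)
    R_fin <- R_in * rat
    spacing <- ceiling(2 * max(R_fin) / px_um) + 12
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    idx <- seq_len(n) - 1L
    cells <- tibble::tibble(
      cx_px = (idx %% ncol_g) * spacing + spacing / 2 + 4,
      cy_px = (idx %/% ncol_g) * spacing + spacing / 2 + 4,
      R_in_um = R_in, R_fin_um = R_fin, tau_s = tau_s)
    list(cells = cells,
         dim_px = c(ncol_g * spacing + 8, nrow_g * spacing + 8))
  })
}
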