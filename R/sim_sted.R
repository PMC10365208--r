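# Synthetic STED-like filament images and two-channel colocalization pairs.

# Rasterize a polyline onto a matrix: marks every pixel whose center lies
# within `width_px`/2 of the segment (dense sampling along the path).
rasterize_polyline <- function(mask, verts_px, width_px = 1.5) {
  n <- nrow(mask); p <- ncol(mask)
  for (i in seq_len(nrow(verts_px) - 1)) {
    a <- verts_px[i, ]; b <- verts_px[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 3)))
    xs <- a[1] + ts * (b[1] - a[1])
    ys <- a[2] + ts * (b[2] - a[2])
    r <- width_px / 2
    for (j in seq_along(ts)) {
      xi <- max(1, floor(xs[j] - r)):min(n, ceiling(xs[j] + r))
      yi <- max(1, floor(ys[j] - r)):min(p, ceiling(ys[j] + r))
      d2 <- outer((xi - xs[j])^2, (yi - ys[j])^2, "+")
      mask[xi, yi][d2 <= r^2] <- TRUE
    }
  }
  mask
}

# Geodesic length of a polyline (sum of segment lengths).
polyline_length <- function(verts) sum(sqrt(rowSums(diff(verts)^2)))

#' Simulate a STED-like filament image with ground truth
#'
#' Draws filaments (polylines; optionally with side branches) on a dark
#' background, blurs with a Gaussian point-spread function and applies
#' Poisson shot noise plus Gaussian read noise. The truth table records each
#' filament's geodesic length and branch-point count before blurring.
#'
#' @param filaments List, one element per filament: a list with `verts`
#'   (n x 2 matrix, px, the main path) and optionally `branches` (list of
#'   n x 2 matrices, each a side branch starting on the main path).
#' @param dim_px Image size `c(nx, ny)`.
#' @param pixel_size_nm nm per pixel (default 20, STED-scale sampling).
#' @param psf_fwhm_nm Point-spread FWHM, nm (default 60); must be at least
#'   `2 * pixel_size_nm` so the image is adequately sampled.
#' @param intensity Peak photon count per filament pixel (default 100).
#' @param line_width_px Drawn filament width before blurring (default 1.5).
#' @param poisson Apply Poisson shot noise (default TRUE).
#' @param read_noise_sd Gaussian read noise sd in counts (default 2).
#' @param seed Integer seed.
#' @return List: `image` (matrix, counts), `pixel_size_nm`, `truth`
#'   (id, stage, parameter, value, units) and `mask` (pre-blur binary truth).
#' @export
sim_filament_image <- function(filaments, dim_px = c(256, 256),
                               pixel_size_nm = 20, psf_fwhm_nm = 60,
                               intensity = 100, line_width_px = 1.5,
                               poisson = TRUE, read_noise_sd = 2,
                               seed = NULL) {
  abort_if(pixel_size_nm > psf_fwhm_nm / 2,
           "undersampled: need pixel_size_nm <= psf_fwhm_nm / 2")
  for (fl in filaments) {
    v <- rbind(fl$verts, do.call(rbind, fl$branches %||% list()))
    abort_if(any(v[, 1] < 1 | v[, 1] > dim_px[1] | v[, 2] < 1 | v[, 2] > dim_px[2]),
             "polyline outside image bounds")
  }
  with_seed(seed, {
    img <- matrix(0, dim_px[1], dim_px[2])
    mask <- matrix(FALSE, dim_px[1], dim_px[2])
    truths <- list()
    for (i in seq_along(filaments)) {
      fl <- filaments[[i]]
      m <- matrix(FALSE, dim_px[1], dim_px[2])
      m <- rasterize_polyline(m, fl$verts, line_width_px)
      len_um <- polyline_length(fl$verts) * pixel_size_nm / 1000
      nb <- length(fl$branches %||% list())
      for (b in fl$branches %||% list()) {
        m <- rasterize_polyline(m, b, line_width_px)
        len_um <- len_um + polyline_length(b) * pixel_size_nm / 1000
      }
      mask <- mask | m
      img[m] <- intensity
      truths[[i]] <- tibble::tibble(
        id = sprintf("fil%03d", i), stage = "sted",
        parameter = c("length", "branches"),
        value = c(len_um, nb), units = c("um", "count"))
    }
    sigma_px <- fwhm_to_sigma(psf_fwhm_nm) / pixel_size_nm
    blurred <- as.matrix(EBImage::gblur(img, sigma_px))
    blurred[blurred < 0] <- 0
    noisy <- if (poisson) matrix(stats::rpois(length(blurred), blurred),
                                 nrow(blurred)) else blurred
    if (read_noise_sd > 0)
      noisy <- noisy + stats::rnorm(length(noisy), 0, read_noise_sd)
    list(image = pmax(noisy, 0), pixel_size_nm = pixel_size_nm,
         truth = dplyr::bind_rows(truths), mask = mask)
  })
}

#' Random filament field specification
#'
#' Samples straight filaments (optionally with one side branch each) with
#' bounding boxes kept apart so components stay separable, for use with
#' [sim_filament_image()].
#'
#' @param n Number of filaments.
#' @param dim_px Image size.
#' @param length_um_range Min/max filament length, um.
#' @param branch_prob Probability a filament carries one side branch.
#' @param pixel_size_nm nm per pixel.
#' @param min_sep_px Minimum distance between filament bounding boxes.
#' @param seed Integer seed.
#' @return List of filament specs (`verts`, `branches`).
#' @export
sim_filament_field <- function(n, dim_px = c(360, 360),
                               length_um_range = c(0.5, 1.2),
                               branch_prob = 0.3, pixel_size_nm = 20,
                               min_sep_px = 12, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, {
    px_um <- pixel_size_nm / 1000
    specs <- list(); boxes <- list()
    tries <- 0
    while (length(specs) < n && tries < 8000) {
      tries <- tries + 1
      L <- stats::runif(1, length_um_range[1], length_um_range[2]) / px_um
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, 1.1 * L / 2 + 8, dim_px[1] - 1.1 * L / 2 - 8)
      cy <- stats::runif(1, 1.1 * L / 2 + 8, dim_px[2] - 1.1 * L / 2 - 8)
      v <- rbind(c(cx - cos(th) * L / 2, cy - sin(th) * L / 2),
                 c(cx + cos(th) * L / 2, cy + sin(th) * L / 2))
      branches <- list()
      if (stats::runif(1) < branch_prob) {
        t0 <- stats::runif(1, 0.35, 0.65)
        p0 <- v[1, ] + t0 * (v[2, ] - v[1, ])
        bl <- stats::runif(1, 0.35, 0.6) * L
        bth <- th + sample(c(1, -1), 1) * stats::runif(1, pi / 4, pi / 2.2)
        p1 <- p0 + bl * c(cos(bth), sin(bth))
        p1 <- pmin(pmax(p1, 2), dim_px - 2)
        branches <- list(rbind(p0, p1))
      }
      allv <- rbind(v, do.call(rbind, branches))
      box <- c(min(allv[, 1]), max(allv[, 1]), min(allv[, 2]), max(allv[, 2]))
      ok <- TRUE
      for (b in boxes) {
        if (!(box[2] + min_sep_px < b[1] || b[2] + min_sep_px < box[1] ||
              box[4] + min_sep_px < b[3] || b[4] + min_sep_px < box[3])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      boxes[[length(boxes) + 1]] <- box
      specs[[length(specs) + 1]] <- list(verts = v, branches = branches)
    }
    abort_if(length(specs) < n, "could not place filaments; enlarge dim_px")
    specs
  })
}

#' Simulate a two-channel image pair with controlled colocalization
#'
#' Builds a channel-2 (e.g. myosin) structure mask of random blobs and a
#' channel-1 (e.g. actin) structure whose intensity is split so that exactly
#' `coloc_fraction` of its total lies inside the channel-2 mask. The truth
#' table records the constructed fraction computed directly from the noise
#' free images.
#'
#' @param dim_px Image size.
#' @param coloc_fraction Fraction in `[0, 1]` of channel-1 intensity inside
#'   the channel-2 structure.
#' @param n_blobs Number of channel-2 blobs.
#' @param blob_r_px Blob radius, px.
#' @param intensity Structure intensity, counts.
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return List: `ch1`, `ch2` (matrices), `roi` (logical matrix, full frame),
#'   `truth`.
#' @export
sim_coloc_pair <- function(dim_px = c(192, 192), coloc_fraction = 0.5,
                           n_blobs = 6, blob_r_px = 14, intensity = 100,
                           noise_sd = 0, seed = NULL) {
  abort_if(coloc_fraction < 0 || coloc_fraction > 1,
           "coloc_fraction must lie in [0, 1]")
  with_seed(seed, {
    xs <- seq_len(dim_px[1]); ys <- seq_len(dim_px[2])
    # channel-2 blobs on the left half, guaranteed-disjoint zone on the right
    ch2mask <- matrix(FALSE, dim_px[1], dim_px[2])
    half <- floor(dim_px[1] / 2)
    for (i in seq_len(n_blobs)) {
      cx <- stats::runif(1, blob_r_px + 2, half - blob_r_px - 2)
      cy <- stats::runif(1, blob_r_px + 2, dim_px[2] - blob_r_px - 2)
      d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
      ch2mask <- ch2mask | (d2 <= blob_r_px^2)
    }
    inside <- which(ch2mask)
    outside <- which(!ch2mask & row(ch2mask) > half + 4)
    # split channel-1 intensity: coloc_fraction inside ch2, rest outside
    n1 <- 1200L
    n_in <- round(coloc_fraction * n1)
    pick_in <- sample(inside, min(n_in, length(inside)))
    pick_out <- sample(outside, min(n1 - n_in, length(outside)))
    ch1 <- matrix(0, dim_px[1], dim_px[2])
    ch1[pick_in] <- intensity
    ch1[pick_out] <- intensity
    ch2 <- matrix(0, dim_px[1], dim_px[2])
    ch2[ch2mask] <- intensity
    truth_frac <- if (sum(ch1) > 0) 100 * sum(ch1[ch2mask]) / sum(ch1) else NA_real_
    if (noise_sd > 0) {
      ch1 <- pmax(ch1 + stats::rnorm(length(ch1), 0, noise_sd), 0)
      ch2 <- pmax(ch2 + stats::rnorm(length(ch2), 0, noise_sd), 0)
    }
    list(ch1 = ch1, ch2 = ch2,
         roi = matrix(TRUE, dim_px[1], dim_px[2]),
         truth = tibble::tibble(
           id = "pair001", stage = "coloc", parameter = "coloc_fraction",
           value = truth_frac, units = "%"))
  })
}
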