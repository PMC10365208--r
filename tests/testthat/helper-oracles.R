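# Independent oracles used across the suite. These never call the code
# paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all labelings of
# the pooled sample (tie-free data only).
mwu_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: labelings at least as extreme (by distance from the mean)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force 1-D scan for the Young's modulus minimizing the rss of the
# quadratic contact model on a force-indentation curve.
brute_force_E <- function(delta_nm, force_pN, theta_deg = 17.5, nu = 0.5,
                          E_grid = seq(10, 5000, by = 1)) {
  coef <- tan(theta_deg * pi / 180) / sqrt(2) / (1 - nu^2) * 1e-6
  rss <- vapply(E_grid, function(E)
    sum((force_pN - coef * E * delta_nm^2)^2), numeric(1))
  E_grid[which.min(rss)]
}

# Coarse grid-search oracle for the exponential swelling parameters with
# R_in fixed; returns c(ratio, tau).
grid_search_swelling <- function(time_s, radius_um, t0_s, R_in,
                                 ratio_grid = seq(1.0, 2.5, by = 0.005),
                                 tau_grid = seq(20, 600, by = 5)) {
  t <- time_s[time_s >= t0_s] - t0_s
  r <- radius_um[time_s >= t0_s]
  best <- c(NA, NA); best_rss <- Inf
  for (ratio in ratio_grid) {
    Rf <- ratio * R_in
    for (tau in tau_grid) {
      pred <- R_in + (Rf - R_in) * (1 - exp(-t / tau))
      rss <- sum((r - pred)^2)
      if (rss < best_rss) { best_rss <- rss; best <- c(ratio, tau) }
    }
  }
  best
}

# High-resolution polygonal perimeter of an ellipse (quadrature oracle).
ellipse_perimeter_quadrature <- function(a, b, n = 200000) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  x <- a * cos(th); y <- b * sin(th)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# IoU of two logical masks.
mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# Match each truth cell (by centroid) to a segmented region and return IoU.
segmentation_ious <- function(labels, truth_labels, centers) {
  vapply(seq_len(nrow(centers)), function(i) {
    tmask <- truth_labels == i
    rc <- which(tmask, arr.ind = TRUE)
    lab_hits <- labels[rc]
    lab <- as.integer(names(which.max(table(lab_hits[lab_hits > 0]))))
    if (!length(lab) || is.na(lab)) return(0)
    mask_iou(labels == lab, tmask)
  }, numeric(1))
}

# Small synthetic AFM batch used by several tests.
make_afm_batch <- function(n_cells, E, noise = 0, seed = 1, grid_points = 4) {
  sim_force_curves(n_cells = n_cells, E_true_Pa = E,
                   grid_points = grid_points, noise_sd_pN = noise,
                   seed = seed)
}
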