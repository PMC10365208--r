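# Synthetic AFM force curves with known ground truth.

# Exact forward-generated force at piezo separation s = z - z0 for a
# quadratic (pyramid/cone) tip, accounting for cantilever bending:
# the recorded F satisfies F = C*E*1e-6 * ((s - F*1e-3/k))^2, whose
# physical root is closed-form.
force_at_separation <- function(s_nm, E_Pa, k, tip) {
  ce <- hertz_prefactor(tip) * E_Pa * 1e-6   # F = ce * delta^2
  a <- 1e-3 / k                              # deflection per pN, nm
  # ce*a^2*F^2 - (2*ce*a*s + 1)*F + ce*s^2 = 0 ; discriminant = 4*ce*a*s + 1
  s <- pmax(s_nm, 0)
  (2 * ce * a * s + 1 - sqrt(4 * ce * a * s + 1)) / (2 * ce * a^2)
}

#' Simulate AFM approach curves with ground truth
#'
#' Generates per-cell grids of pyramidal-tip approach curves: a flat
#' pre-contact baseline (noise only) followed by the exact Hertz-Sneddon
#' response including cantilever bending, plus optional Gaussian deflection
#' noise. Defaults follow the standard cortical-stiffness protocol: 0.1 N/m
#' lever, 4 um ramp, 4 x 4 grid per cell.
#'
#' @param n_cells Number of cells.
#' @param E_true_Pa True Young's modulus per cell, Pa (length 1 or `n_cells`).
#' @param grid_points Curves per cell (default 16, the 4 x 4 grid).
#' @param k Spring constant, N/m (default 0.1).
#' @param tip A [tip_geometry()].
#' @param z0_nm Contact point, nm; a length-2 range from which per-curve
#'   contact points are drawn uniformly, or a single value used verbatim.
#' @param ramp_nm Ramp length, nm (default 4000).
#' @param n_samples Samples per curve (default 800).
#' @param noise_sd_pN Gaussian force noise sd, pN (default 0 = noiseless).
#' @param seed Integer seed; same seed and arguments give identical output.
#' @return List with `curves` (long tibble: cell_id, curve_id, grid_row,
#'   grid_col, k_N_per_m, z_nm, force_pN) and `truth` (tibble:
#'   id, stage, parameter, value, units).
#' @examples
#' sim <- sim_force_curves(n_cells = 1, E_true_Pa = 1000, grid_points = 1,
#'                         noise_sd_pN = 0, seed = 1)
#' @export
sim_force_curves <- function(n_cells, E_true_Pa, grid_points = 16,
                             k = 0.1, tip = tip_geometry(),
                             z0_nm = c(1200, 2600), ramp_nm = 4000,
                             n_samples = 800, noise_sd_pN = 0, seed = NULL) {
  abort_if(ramp_nm <= 0 || n_samples <= 1, "invalid ramp or sample count")
  abort_if(n_cells <= 0 || grid_points <= 0, "invalid cell/grid counts")
  abort_if(any(E_true_Pa <= 0), "E_true_Pa must be positive")
  E_true_Pa <- rep_len(E_true_Pa, n_cells)
  side <- max(1L, ceiling(sqrt(grid_points)))
  with_seed(seed, {
    rows <- list(); truths <- list()
    z <- seq(0, ramp_nm, length.out = n_samples)
    for (ci in seq_len(n_cells)) {
      cell <- sprintf("cell%03d", ci)
      for (gi in seq_len(grid_points)) {
        z0 <- if (length(z0_nm) == 2) stats::runif(1, z0_nm[1], z0_nm[2]) else z0_nm
        f <- force_at_separation(z - z0, E_true_Pa[ci], k, tip)
        f[z < z0] <- 0
        if (noise_sd_pN > 0) f <- f + stats::rnorm(length(f), 0, noise_sd_pN)
        id <- sprintf("%s_c%02d", cell, gi)
        rows[[id]] <- tibble::tibble(
          cell_id = cell, curve_id = id,
          grid_row = (gi - 1L) %/% side, grid_col = (gi - 1L) %% side,
          k_N_per_m = k, z_nm = z, force_pN = f)
        truths[[id]] <- tibble::tibble(
          id = id, stage = "afm",
          parameter = c("E_true", "z0"),
          value = c(E_true_Pa[ci], z0),
          units = c("Pa", "nm"))
      }
    }
    list(curves = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truths))
  })
}
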