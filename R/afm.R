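#' Indenter tip geometry
#'
#' Describes the AFM probe used for Hertz-Sneddon analysis. The default is a
#' four-sided pyramidal probe (face half-angle to the axis 17.5 degrees, the
#' nominal geometry of soft biology levers such as the MLCT family) on an
#' incompressible sample (Poisson ratio 0.5).
#'
#' @param shape `"four_sided_pyramid"`, `"cone"` or `"sphere"`.
#' @param theta_deg Face (pyramid) or opening (cone) half-angle to the axis,
#'   degrees; ignored for spheres.
#' @param nu Poisson ratio of the sample, in `[0, 0.5]`. The incompressible
#'   limit `nu = 0.5` gives `1 - nu^2 = 0.75` (no singularity).
#' @param radius_nm Tip radius in nm, spheres only.
#' @return A list of class `cm_tip` with the validated fields.
#' @examples
#' tip_geometry()                       # pyramidal default
#' tip_geometry("sphere", radius_nm = 1000)
#' @export
tip_geometry <- function(shape = c("four_sided_pyramid", "cone", "sphere"),
                         theta_deg = 17.5, nu = 0.5, radius_nm = NULL) {
  shape <- match.arg(shape)
  abort_if(!is.numeric(nu) || nu < 0 || nu > 0.5,
           "`nu` must lie in [0, 0.5]")
  if (shape == "sphere") {
    abort_if(is.null(radius_nm) || radius_nm <= 0,
             "spherical tips need a positive `radius_nm`")
  } else {
    abort_if(theta_deg <= 0 || theta_deg >= 90,
             "`theta_deg` must lie in (0, 90)")
  }
  structure(list(shape = shape, theta_deg = theta_deg, nu = nu,
                 radius_nm = radius_nm),
            class = "cm_tip")
}

# Dimensionless prefactor C such that F[pN] = C * E[Pa] * delta[nm]^2 * 1e-6
# (pyramid/cone); spheres handled separately in hertz_sneddon_force().
hertz_prefactor <- function(tip) {
  th <- tip$theta_deg * pi / 180
  switch(tip$shape,
    four_sided_pyramid = tan(th) / sqrt(2) / (1 - tip$nu^2),
    cone               = (2 / pi) * tan(th) / (1 - tip$nu^2),
    rlang::abort("no quadratic prefactor for spherical tips"))
}

#' Hertz-Sneddon forward model
#'
#' Force exerted by an elastic half-space of Young's modulus `E_Pa` on an
#' indenter at indentation depth `delta_nm`:
#' \itemize{
#'   \item four-sided pyramid: `F = (tan(theta)/sqrt(2)) * E/(1-nu^2) * delta^2`
#'   \item cone: `F = (2/pi) * tan(theta) * E/(1-nu^2) * delta^2`
#'   \item sphere: `F = (4/3) * E/(1-nu^2) * sqrt(R) * delta^(3/2)`
#' }
#' Inputs are nm and Pa; the returned force is in pN (conversions internal).
#'
#' @param delta_nm Indentation depth(s), nm, non-negative.
#' @param E_Pa Young's modulus, Pa.
#' @param tip A [tip_geometry()].
#' @return Force in pN, same length as `delta_nm`.
#' @examples
#' hertz_sneddon_force(500, 1000, tip_geometry())
#' @export
hertz_sneddon_force <- function(delta_nm, E_Pa, tip = tip_geometry()) {
  abort_if(any(delta_nm < 0), "indentation `delta_nm` must be non-negative")
  abort_if(E_Pa <= 0, "`E_Pa` must be positive")
  if (tip$shape == "sphere") {
    (4 / 3) * E_Pa / (1 - tip$nu^2) * sqrt(tip$radius_nm) * delta_nm^1.5 * 1e-6
  } else {
    hertz_prefactor(tip) * E_Pa * delta_nm^2 * 1e-6
  }
}

#' Baseline-correct a force curve
#'
#' Fits a straight line to the far-field (pre-contact) portion of the
#' approach curve and subtracts it, removing photodiode offset and drift tilt
#' so the free cantilever reads zero force.
#'
#' @param curve Data frame with columns `z_nm`, `force_pN` (one curve).
#' @param baseline_fraction Fraction of the earliest samples (smallest `z_nm`,
#'   far from the surface) used to fit the baseline. Default 0.5.
#' @return The curve with `force_pN` corrected, as a tibble.
#' @export
baseline_correct <- function(curve, baseline_fraction = 0.5) {
  abort_if(!all(c("z_nm", "force_pN") %in% names(curve)),
           "curve needs `z_nm` and `force_pN` columns")
  n <- nrow(curve)
  nb <- floor(n * baseline_fraction)
  abort_if(nb < 10, "fewer than 10 baseline samples; increase `baseline_fraction`")
  ord <- order(curve$z_nm)
  idx <- ord[seq_len(nb)]
  fit <- stats::lm.fit(cbind(1, curve$z_nm[idx]), curve$force_pN[idx])
  pred <- cbind(1, curve$z_nm) %*% fit$coefficients
  dplyr::mutate(tibble::as_tibble(curve), force_pN = .data$force_pN - drop(pred))
}

#' Convert a force curve to a force-indentation curve
#'
#' Subtracts the cantilever bending from the piezo travel beyond the contact
#' point: `delta = (z - z0) - F/k`. Samples before contact are dropped.
#'
#' @param curve Data frame with `z_nm`, `force_pN`.
#' @param z0_nm Contact point in piezo coordinates, nm.
#' @param k Cantilever spring constant, N/m.
#' @return Tibble with columns `delta_nm`, `force_pN`.
#' @export
to_indentation <- function(curve, z0_nm, k) {
  abort_if(k <= 0, "spring constant `k` must be positive")
  abort_if(z0_nm < min(curve$z_nm) || z0_nm > max(curve$z_nm),
           "`z0_nm` outside the recorded z range")
  post <- curve$z_nm >= z0_nm
  tibble::tibble(
    delta_nm = (curve$z_nm[post] - z0_nm) - deflection_nm(curve$force_pN[post], k),
    force_pN = curve$force_pN[post])
}

# Profiled least-squares E for given indentations/forces (linear in E for
# quadratic tips, and in the sphere case linear in E against delta^1.5).
# Returns c(E, rss).
profile_E <- function(delta_nm, force_pN, tip) {
  x <- if (tip$shape == "sphere") {
    (4 / 3) / (1 - tip$nu^2) * sqrt(tip$radius_nm) * delta_nm^1.5 * 1e-6
  } else {
    hertz_prefactor(tip) * delta_nm^2 * 1e-6
  }
  sxx <- sum(x * x)
  E <- if (sxx > 0) max(sum(x * force_pN) / sxx, 0) else 0
  c(E = E, rss = sum((force_pN - E * x)^2))
}

# Total piecewise rss for a candidate contact point: flat zero before z0,
# Hertz-Sneddon beyond. The whole post-contact ramp is scored so that a
# misplaced candidate cannot hide the contact region from the model.
contact_rss <- function(curve, z0, k, tip) {
  pre <- curve$z_nm < z0
  delta <- (curve$z_nm[!pre] - z0) - deflection_nm(curve$force_pN[!pre], k)
  f <- curve$force_pN[!pre]
  keep <- delta >= 0
  pe <- profile_E(delta[keep], f[keep], tip)
  list(rss = sum(curve$force_pN[pre]^2) + sum(f[!keep]^2) + pe[["rss"]],
       E = pe[["E"]], n_fit = sum(keep))
}

#' Locate the tip-sample contact point
#'
#' Joint piecewise fit: the force is modelled as zero before the contact
#' point `z0` and as the Hertz-Sneddon law beyond it. Every sample index in
#' the central 80% of the ramp is tried as a candidate `z0` (with the
#' modulus profiled out by linear least squares at each candidate), and the
#' best grid point is refined by local 1-D optimisation. The curve should be
#' baseline-corrected first.
#'
#' @inheritParams to_indentation
#' @param k Spring constant, N/m.
#' @param tip A [tip_geometry()].
#' @return List with `z0_nm`, `E_Pa` (profiled), `rss`, `valid` (FALSE when
#'   no candidate beats the flat no-contact model).
#' @export
find_contact_point <- function(curve, k, tip = tip_geometry()) {
  curve <- curve[order(curve$z_nm), , drop = FALSE]
  n <- nrow(curve)
  abort_if(n < 50, "need at least 50 samples")
  lo <- floor(0.1 * n) + 1
  hi <- ceiling(0.9 * n)
  cand <- curve$z_nm[lo:hi]
  scores <- vapply(cand, function(z0)
    contact_rss(curve, z0, k, tip)$rss, numeric(1))
  best <- which.min(scores)
  dz <- stats::median(diff(curve$z_nm))
  opt <- stats::optimize(function(z0)
    contact_rss(curve, z0, k, tip)$rss,
    lower = cand[best] - 2 * dz, upper = cand[best] + 2 * dz)
  res <- contact_rss(curve, opt$minimum, k, tip)
  rss_flat <- sum(curve$force_pN^2)
  # require a real improvement over "no contact anywhere in the ramp"
  valid <- res$rss < 0.95 * rss_flat && res$E > 0 && res$n_fit >= 10
  list(z0_nm = opt$minimum, E_Pa = res$E, rss = res$rss, valid = valid)
}

#' Fit the Hertz-Sneddon model to a force-indentation curve
#'
#' Least-squares Young's modulus over the capped indentation range
#' (default 500 nm, probing the actin-rich cortex). Validity requires an
#' adequate goodness of fit and a physically plausible modulus.
#'
#' @param ind Data frame with `delta_nm`, `force_pN` (from [to_indentation()]).
#' @param tip A [tip_geometry()].
#' @param fit_range_max_nm Indentation cap, nm (default 500).
#' @param max_force_pN Optional force cap applied after the indentation cap
#'   (acquisition setpoint; default `Inf`).
#' @param r2_min,E_bounds_Pa Validity thresholds: minimum coefficient of
#'   determination and admissible modulus range.
#' @return A list of class `cm_hertz_fit`: `E_Pa`, `rss`, `r2`, `n_fit`,
#'   `fit_range_max_nm`, `valid`.
#' @export
fit_hertz_sneddon <- function(ind, tip = tip_geometry(), fit_range_max_nm = 500,
                              max_force_pN = Inf, r2_min = 0.9,
                              E_bounds_Pa = c(10, 1e5)) {
  keep <- ind$delta_nm >= 0 & ind$delta_nm <= fit_range_max_nm &
    ind$force_pN <= max_force_pN
  d <- ind$delta_nm[keep]; f <- ind$force_pN[keep]
  if (length(d) < 10) {
    return(structure(list(E_Pa = NA_real_, rss = NA_real_, r2 = NA_real_,
                          n_fit = length(d), fit_range_max_nm = fit_range_max_nm,
                          valid = FALSE),
                     class = "cm_hertz_fit"))
  }
  pe <- profile_E(d, f, tip)
  tss <- sum((f - mean(f))^2)
  r2 <- if (tss > 0) 1 - pe[["rss"]] / tss else as.numeric(pe[["rss"]] < 1e-12)
  valid <- is.finite(r2) && r2 >= r2_min &&
    pe[["E"]] >= E_bounds_Pa[1] && pe[["E"]] <= E_bounds_Pa[2]
  structure(list(E_Pa = pe[["E"]], rss = pe[["rss"]], r2 = r2,
                 n_fit = length(d), fit_range_max_nm = fit_range_max_nm,
                 valid = valid),
            class = "cm_hertz_fit")
}

#' @export
print.cm_hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz-Sneddon fit: E = %.1f Pa (r2 = %.3f, n = %d, %s)\n",
              x$E_Pa, x$r2, x$n_fit, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Analyse a table of AFM approach curves
#'
#' Full per-curve pipeline: baseline correction, contact-point search,
#' bending correction, capped Hertz-Sneddon fit. This is the data-frame
#' front end used on generated or imported curve sets.
#'
#' @param curves Long tibble with columns `cell_id`, `curve_id`, `z_nm`,
#'   `force_pN` and (constant per curve) `k_N_per_m`; optional `grid_row`,
#'   `grid_col`.
#' @param tip A [tip_geometry()].
#' @param fit_range_max_nm Indentation cap for the modulus fit, nm.
#' @param baseline_fraction Passed to [baseline_correct()].
#' @return Tibble, one row per curve: `cell_id`, `curve_id`, `grid_row`,
#'   `grid_col`, `E_Pa`, `z0_nm`, `r2`, `valid`.
#' @export
afm_fit_curves <- function(curves, tip = tip_geometry(), fit_range_max_nm = 500,
                           baseline_fraction = 0.5) {
  abort_if(!all(c("cell_id", "curve_id", "z_nm", "force_pN", "k_N_per_m") %in%
                  names(curves)),
           "curves need cell_id, curve_id, z_nm, force_pN, k_N_per_m")
  curves |>
    dplyr::group_by(.data$cell_id, .data$curve_id) |>
    dplyr::group_modify(function(df, key) {
      k <- df$k_N_per_m[1]
      cur <- baseline_correct(df[, c("z_nm", "force_pN")], baseline_fraction)
      cp <- find_contact_point(cur, k, tip)
      row <- tibble::tibble(
        grid_row = if ("grid_row" %in% names(df)) df$grid_row[1] else NA_integer_,
        grid_col = if ("grid_col" %in% names(df)) df$grid_col[1] else NA_integer_,
        E_Pa = NA_real_, z0_nm = NA_real_, r2 = NA_real_, valid = FALSE)
      if (!cp$valid) return(row)
      fit <- fit_hertz_sneddon(to_indentation(cur, cp$z0_nm, k), tip,
                               fit_range_max_nm)
      row$E_Pa <- fit$E_Pa; row$z0_nm <- cp$z0_nm; row$r2 <- fit$r2
      row$valid <- fit$valid
      row
    }) |>
    dplyr::ungroup()
}

#' Per-cell cortical stiffness summary
#'
#' Reduces the per-curve moduli of each cell (a 4 x 4 grid of indentations
#' over 1 x 1 um^2 in the standard protocol) to a single robust stiffness:
#' the median over valid fits. Cells with fewer than `min_valid` usable
#' curves are flagged and get `NA`.
#'
#' @param fits Per-curve tibble from [afm_fit_curves()].
#' @param min_valid Minimum number of valid curves per cell (default 4).
#' @return Tibble: `cell_id`, `E_cell_Pa`, `n_valid`, `n_total`, `defined`.
#' @export
afm_summarize_cells <- function(fits, min_valid = 4) {
  abort_if(nrow(fits) == 0, "empty fit table")
  fits |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      E_cell_Pa = {
        e <- .data$E_Pa[.data$valid]
        if (length(e) >= min_valid) stats::median(e) else NA_real_
      },
      n_valid = sum(.data$valid),
      n_total = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(defined = !is.na(.data$E_cell_Pa))
}
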