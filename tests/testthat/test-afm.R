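# AFM force-spectroscopy: forward model, baseline, contact point,
# Hertz-Sneddon fitting, per-cell summaries.

test_that("forward model matches closed-form values and scaling laws", {
  tip <- tip_geometry()
  # hand arithmetic in SI units: (tan 17.5deg / sqrt(2)) * (1000/0.75) * (5e-7 m)^2
  f_si <- tan(17.5 * pi / 180) / sqrt(2) * (1000 / 0.75) * (500e-9)^2 * 1e12
  expect_equal(hertz_sneddon_force(500, 1000, tip), f_si, tolerance = 1e-12)
  expect_equal(hertz_sneddon_force(0, 1000, tip), 0)
  cone <- tip_geometry("cone", theta_deg = 20)
  sph <- tip_geometry("sphere", radius_nm = 1000)
  expect_equal(hertz_sneddon_force(0, 500, cone), 0)
  expect_equal(hertz_sneddon_force(0, 500, sph), 0)
  # quadratic scaling for pyramid and cone
  for (tp in list(tip, cone)) {
    expect_equal(hertz_sneddon_force(600, 800, tp) /
                   hertz_sneddon_force(300, 800, tp), 4)
  }
  # sphere: 3/2-power scaling
  expect_equal(hertz_sneddon_force(600, 800, sph) /
                 hertz_sneddon_force(300, 800, sph), 2^1.5)
  expect_error(hertz_sneddon_force(-5, 1000, tip), "non-negative")
})

test_that("baseline correction removes offset and tilt", {
  z <- seq(0, 4000, length.out = 500)
  flat <- tibble::tibble(z_nm = z, force_pN = rep(0, 500))
  expect_equal(baseline_correct(flat)$force_pN, rep(0, 500), tolerance = 1e-10)

  tilted <- tibble::tibble(z_nm = z, force_pN = 50 + 0.01 * z)
  corr <- baseline_correct(tilted)
  # independent linear regression on the far field
  fit <- lm(force_pN ~ z_nm, data = corr[z < 2000, ])
  expect_lt(abs(coef(fit)[2]), 1e-4)
  expect_lt(abs(mean(corr$force_pN[z < 2000])), 1)
  expect_error(baseline_correct(flat[1:12, ], baseline_fraction = 0.5),
               "baseline samples")
})

test_that("bending correction converts z to indentation", {
  k <- 0.1
  z <- seq(0, 2000, length.out = 100)
  # rigid surface: F = k * (z - z0) in nm deflection units -> delta == 0
  z0 <- 500
  f_rigid <- ifelse(z >= z0, (z - z0) * k * 1e3, 0)   # pN
  ind <- to_indentation(tibble::tibble(z_nm = z, force_pN = f_rigid), z0, k)
  expect_equal(max(abs(ind$delta_nm)), 0, tolerance = 1e-9)
  # unit arithmetic: z - z0 = 1000 nm, F = 500 pN, k = 0.1 -> delta = 995 nm
  one <- to_indentation(tibble::tibble(z_nm = c(0, 1000), force_pN = c(0, 500)),
                        0, k)
  expect_equal(one$delta_nm[2], 995)
  # soft sample: bending positive, delta < z - z0 beyond contact
  sim <- make_afm_batch(1, 500, seed = 5, grid_points = 1)
  cur <- sim$curves
  z0t <- sim$truth$value[sim$truth$parameter == "z0"]
  ind <- to_indentation(cur[, c("z_nm", "force_pN")], z0t, k)
  post <- ind$force_pN > 1e-9
  expect_true(all(ind$delta_nm[post] < cur$z_nm[cur$z_nm >= z0t][post] - z0t))
  expect_error(to_indentation(cur[, c("z_nm", "force_pN")], z0t, k = 0),
               "positive")
})

test_that("noiseless round trip recovers E and z0 to fit precision", {
  for (E in c(100, 1000, 5000)) {
    sim <- sim_force_curves(1, E, grid_points = 1, z0_nm = 2000,
                            noise_sd_pN = 0, seed = 2)
    fit <- afm_fit_curves(sim$curves)
    expect_true(fit$valid)
    expect_equal(fit$E_Pa, E, tolerance = 1e-3)
    dz <- 4000 / (800 - 1)
    expect_lt(abs(fit$z0_nm - 2000), dz)
  }
})

test_that("noisy fits agree with a brute-force modulus scan", {
  sim <- sim_force_curves(5, 500, grid_points = 1, z0_nm = 2000,
                          noise_sd_pN = 5, seed = 31)
  per_curve <- split(sim$curves, sim$curves$curve_id)
  for (cur in per_curve) {
    ind <- to_indentation(cur[, c("z_nm", "force_pN")], 2000, 0.1)
    keep <- ind$delta_nm <= 500
    fit <- fit_hertz_sneddon(ind)
    e_scan <- brute_force_E(ind$delta_nm[keep], ind$force_pN[keep])
    expect_lt(abs(fit$E_Pa - e_scan), 1.01)  # within scan resolution
  }
})

test_that("fit uses only samples within the indentation cap", {
  sim <- sim_force_curves(1, 800, grid_points = 1, z0_nm = 1500,
                          noise_sd_pN = 0, seed = 3)
  cur <- sim$curves
  ind <- to_indentation(cur[, c("z_nm", "force_pN")], 1500, 0.1)
  expect_gt(max(ind$delta_nm), 1000)   # data extend well past the cap
  fit_full <- fit_hertz_sneddon(ind)
  fit_trunc <- fit_hertz_sneddon(ind[ind$delta_nm <= 500, ])
  expect_identical(fit_full$E_Pa, fit_trunc$E_Pa)
  expect_identical(fit_full$n_fit, fit_trunc$n_fit)
})

test_that("scale covariance: scaling forces scales the fitted modulus", {
  sim <- sim_force_curves(1, 700, grid_points = 1, z0_nm = 2000,
                          noise_sd_pN = 0, seed = 4)
  ind <- to_indentation(sim$curves[, c("z_nm", "force_pN")], 2000, 0.1)
  f1 <- fit_hertz_sneddon(ind)
  ind2 <- dplyr::mutate(ind, force_pN = force_pN * 3)
  f2 <- fit_hertz_sneddon(ind2)
  expect_equal(f2$E_Pa / f1$E_Pa, 3, tolerance = 1e-9)
})

test_that("pure-noise curves are flagged as no contact", {
  set.seed(7)
  cur <- tibble::tibble(z_nm = seq(0, 4000, length.out = 400),
                        force_pN = rnorm(400, 0, 5))
  cp <- find_contact_point(baseline_correct(cur), k = 0.1)
  expect_false(cp$valid)
})

test_that("per-cell summary takes the median of valid fits", {
  fits <- tibble::tibble(
    cell_id = "c1", curve_id = sprintf("c1_%02d", 1:16),
    E_Pa = c(400, 450, 500, 600, rep(500, 11), 9000),
    z0_nm = 2000, r2 = 0.99,
    valid = c(rep(TRUE, 4), rep(TRUE, 11), FALSE))
  s <- afm_summarize_cells(fits)
  expect_equal(s$n_valid, 15)
  expect_equal(s$n_total, 16)
  expect_equal(s$E_cell_Pa, median(c(400, 450, 500, 600, rep(500, 11))))
  # arithmetic median check on 4 values
  s4 <- afm_summarize_cells(fits[1:4, ])
  expect_equal(s4$E_cell_Pa, 475)
  # below the minimum-valid threshold the summary is undefined
  s2 <- afm_summarize_cells(fits[1:3, ], min_valid = 4)
  expect_false(s2$defined)
  expect_error(afm_summarize_cells(fits[0, ]), "empty")
})
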