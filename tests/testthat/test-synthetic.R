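# Synthetic-data generators: determinism, truth-table bookkeeping,
# input validation, forward-model fidelity.

test_that("noiseless force curves equal the forward model exactly", {
  sim <- sim_force_curves(1, 1000, grid_points = 1, z0_nm = 1000,
                          noise_sd_pN = 0, seed = 1)
  cur <- sim$curves
  k <- cur$k_N_per_m[1]
  post <- cur$z_nm >= 1000
  # delta from the recorded force, then forward model must reproduce force
  delta <- (cur$z_nm[post] - 1000) - cur$force_pN[post] * 1e-3 / k
  expect_equal(cur$force_pN[post], hertz_sneddon_force(delta, 1000),
               tolerance = 1e-9)
  expect_equal(cur$force_pN[!post], rep(0, sum(!post)))
  # defaults: 4 um ramp, 0.1 N/m lever
  expect_equal(max(cur$z_nm), 4000)
  expect_equal(k, 0.1)
})

test_that("generators are deterministic given a seed", {
  a <- sim_force_curves(2, 600, grid_points = 2, noise_sd_pN = 5, seed = 7)
  b <- sim_force_curves(2, 600, grid_points = 2, noise_sd_pN = 5, seed = 7)
  expect_identical(a, b)
  c1 <- sim_coloc_pair(coloc_fraction = 0.4, noise_sd = 3, seed = 9)
  c2 <- sim_coloc_pair(coloc_fraction = 0.4, noise_sd = 3, seed = 9)
  expect_identical(c1, c2)
  e1 <- sim_rtdc_events(40, rough_fraction = 0.2, seed = 5)
  e2 <- sim_rtdc_events(40, rough_fraction = 0.2, seed = 5)
  expect_identical(e1, e2)
  f1 <- sim_filament_field(4, seed = 3)
  f2 <- sim_filament_field(4, seed = 3)
  expect_identical(f1, f2)
})

test_that("generator seeds do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(sim_force_curves(1, 500, grid_points = 1, noise_sd_pN = 1, seed = 9))
  expect_identical(runif(1), before)
})

test_that("invalid generator specs are rejected", {
  expect_error(sim_force_curves(1, 500, ramp_nm = -1, seed = 1), "ramp")
  expect_error(sim_force_curves(0, 500, seed = 1), "cell")
  expect_error(sim_force_curves(1, -5, seed = 1), "positive")
  expect_error(sim_rtdc_events(0, seed = 1), "positive")
  expect_error(sim_coloc_pair(coloc_fraction = 1.2, seed = 1), "0, 1")
  # overlapping swelling cells at final radius
  cells <- tibble::tibble(cx_px = c(50, 60), cy_px = c(50, 50),
                          R_in_um = 4, R_fin_um = 6, tau_s = 200)
  expect_error(sim_swelling_stack(cells, dim_px = c(128, 128), seed = 1),
               "overlap")
  # out-of-bounds polyline
  expect_error(
    sim_filament_image(list(list(verts = rbind(c(-5, 10), c(50, 50)))),
                       dim_px = c(64, 64), seed = 1),
    "bounds")
  # undersampling guard
  expect_error(
    sim_filament_image(list(list(verts = rbind(c(10, 10), c(50, 50)))),
                       dim_px = c(64, 64), pixel_size_nm = 40,
                       psf_fwhm_nm = 60, seed = 1),
    "undersampled")
})

test_that("truth tables are complete and consistent", {
  sim <- sim_force_curves(2, c(400, 900), grid_points = 3, seed = 2)
  expect_equal(nrow(sim$truth), 2 * 3 * 2)  # E_true + z0 per curve
  expect_true(all(sim$truth$stage == "afm"))
  expect_equal(anyDuplicated(paste(sim$truth$id, sim$truth$parameter)), 0)

  cells <- tibble::tibble(cx_px = c(40, 100, 40), cy_px = c(40, 40, 100),
                          R_in_um = 4, R_fin_um = 5, tau_s = 150)
  st <- sim_swelling_stack(cells, dim_px = c(140, 140), duration_s = 60,
                           frame_rate_hz = 0.1, seed = 3)
  expect_equal(sum(st$truth$parameter == "ratio"), 3)
  expect_true(all(st$truth$stage == "swelling"))

  ev <- sim_rtdc_events(10, seed = 4)
  expect_equal(nrow(ev$truth), 30)
  expect_equal(dplyr::n_distinct(ev$truth$id), 10)
})

test_that("swelling stack renders the analytic radius law", {
  # R_in = 4 um, ratio 1.68, tau = 200 s: radius at t0 + tau is
  # R_in + (R_fin - R_in) * (1 - exp(-1))
  cells <- tibble::tibble(cx_px = 64, cy_px = 64, R_in_um = 4,
                          R_fin_um = 4 * 1.68, tau_s = 200)
  st <- sim_swelling_stack(cells, dim_px = c(128, 128), t0_s = 50,
                           duration_s = 260, frame_rate_hz = 0.1, seed = 6)
  r_expect <- 4 + (4 * 1.68 - 4) * (1 - exp(-1))
  fi <- which(st$times_s == 250)
  mask_r_px <- sqrt(sum(st$masks[[fi]] == 1) / pi)
  expect_equal(mask_r_px * 0.2, r_expect, tolerance = 0.02)
  # degenerate: R_fin = R_in gives a constant-radius movie
  cc <- tibble::tibble(cx_px = 64, cy_px = 64, R_in_um = 4, R_fin_um = 4,
                       tau_s = 100)
  stc <- sim_swelling_stack(cc, dim_px = c(128, 128), duration_s = 100,
                            frame_rate_hz = 0.1, seed = 7)
  areas <- vapply(stc$masks, function(m) sum(m == 1), numeric(1))
  expect_equal(max(areas) - min(areas), 0)
})

test_that("filament truth records construction lengths and branches", {
  # single straight 1.0 um segment at 20 nm/px: 50 px
  v <- rbind(c(20, 30), c(70, 30))
  sim <- sim_filament_image(list(list(verts = v)), dim_px = c(96, 96),
                            poisson = FALSE, read_noise_sd = 0, seed = 1)
  expect_equal(sim$truth$value[sim$truth$parameter == "length"], 1.0)
  expect_equal(sim$truth$value[sim$truth$parameter == "branches"], 0)
  # Y-junction: one branch
  yspec <- list(verts = rbind(c(20, 50), c(60, 50)),
                branches = list(rbind(c(40, 50), c(55, 70))))
  simy <- sim_filament_image(list(yspec), dim_px = c(96, 96), seed = 2)
  expect_equal(simy$truth$value[simy$truth$parameter == "branches"], 1)
  # a 0.20 um segment sits below the 260 nm retention cutoff
  short <- sim_filament_image(list(list(verts = rbind(c(20, 20), c(30, 20)))),
                              dim_px = c(64, 64), seed = 3)
  expect_lt(short$truth$value[short$truth$parameter == "length"] * 1000, 260)
})

test_that("coloc pairs hit the constructed fraction exactly", {
  for (f in c(0, 0.5, 1)) {
    p <- sim_coloc_pair(coloc_fraction = f, seed = 11)
    expect_equal(p$truth$value, 100 * f)
    # direct summation on the emitted images
    ch2mask <- p$ch2 > 0
    expect_equal(100 * sum(p$ch1[ch2mask]) / sum(p$ch1), 100 * f)
  }
})

test_that("rtdc truth deformation is the generated polygon's descriptor", {
  sim <- sim_rtdc_events(25, seed = 12)
  met <- rtdc_metrics(sim$contours, pixel_size_um = 0.34)
  tr <- sim$truth[sim$truth$parameter == "deformation", ]
  expect_equal(met$deformation[match(tr$id, met$event_id)], tr$value,
               tolerance = 1e-9)
  # deformation 0 requests a circle (aspect ratio 1)
  circ <- sim_rtdc_events(1, deformation_shape = 1e-9,
                          deformation_rate = 1e9, seed = 1)
  m1 <- rtdc_metrics(circ$contours)
  expect_lt(m1$deformation, 1e-3)
  # roughness 0: area ratio about 1 up to rasterization
  smooth <- sim_rtdc_events(20, rough_fraction = 0, seed = 13)
  m2 <- rtdc_metrics(smooth$contours, mask_areas = smooth$mask_areas)
  expect_true(all(abs(m2$area_ratio - 1) < 0.03))
})
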