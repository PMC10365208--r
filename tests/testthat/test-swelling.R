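# Swelling kinetics: segmentation, radius extraction, tracking, fits.

make_small_stack <- function(n = 3, ratio = 1.5, tau = 150, seed = 21,
                             noise = 0, snr = Inf, duration = 400) {
  co <- sim_swelling_cohort(n, ratio = ratio, tau_s = tau, cv = 0,
                            seed = seed)
  st <- sim_swelling_stack(co$cells, dim_px = co$dim_px, duration_s = duration,
                           frame_rate_hz = 0.1, radius_noise_frac = noise,
                           snr = snr, seed = seed + 1)
  list(co = co, st = st)
}

detect_all <- function(st) {
  purrr::map_dfr(seq_along(st$frames), function(fi) {
    seg <- segment_frame(st$frames[[fi]], pixel_size_nm = st$pixel_size_nm)
    dplyr::mutate(seg$regions, frame = fi, time_s = st$times_s[fi])
  })
}

test_that("blank frames yield zero regions", {
  seg <- segment_frame(matrix(0.8, 64, 64))
  expect_equal(nrow(seg$regions), 0)
  expect_true(all(seg$labels == 0))
})

test_that("rendered disks are segmented with accurate radii", {
  cells <- tibble::tibble(cx_px = c(45, 140, 45), cy_px = c(45, 45, 150),
                          R_in_um = c(4, 5, 6), R_fin_um = c(4, 5, 6),
                          tau_s = 100)
  st <- sim_swelling_stack(cells, dim_px = c(200, 210), duration_s = 10,
                           frame_rate_hz = 0.1, seed = 8)
  seg <- segment_frame(st$frames[[1]], pixel_size_nm = 200)
  expect_equal(nrow(seg$regions), 3)
  got <- unname(sort(seg$regions$radius_um))
  expect_equal(got, c(4, 5, 6), tolerance = 0.1 / 4)  # within 0.1 um
})

test_that("touching cells with distinct minima are split by markers", {
  # hand-rendered frame: two sigmoid-edged dark disks touching at one point
  n <- 140; r <- 21
  img <- matrix(0.85, n, 100)
  for (ctr in list(c(49, 50), c(91, 50))) {
    d <- sqrt(outer((seq_len(n) - ctr[1])^2, (seq_len(100) - ctr[2])^2, "+"))
    img <- img - 0.6 / (1 + exp((d - r) / 0.5))
  }
  seg <- segment_frame(img, pixel_size_nm = 200)
  expect_equal(nrow(seg$regions), 2)
  expect_equal(unname(sort(seg$regions$radius_um)), c(4.2, 4.2),
               tolerance = 0.05)
})

test_that("radius definition is half the major axis", {
  expect_equal(radius_from_region(40, 200), 4)
  # ellipse: radius comes from the major axis
  img <- matrix(0.85, 120, 120)
  xs <- seq_len(120)
  d <- outer((xs - 60)^2 / 40^2, (xs - 60)^2 / 20^2, "+")
  img[d <= 1] <- 0.25
  seg <- segment_frame(img, pixel_size_nm = 200)
  expect_equal(seg$regions$major_axis_px, 80, tolerance = 0.04)
})

test_that("tracking links stationary cells and bridges gaps", {
  s <- make_small_stack(n = 4, duration = 300)
  dets <- detect_all(s$st)
  tr <- link_tracks(dets, min_track_len = 20)
  expect_equal(dplyr::n_distinct(tr$cell_id), 4)
  expect_true(all(dplyr::count(tr, cell_id)$n == length(s$st$frames)))
  # remove one frame of one cell: still one continuous track, interpolated
  drop_frame <- 15
  victim <- dets$cx_px == min(dets$cx_px) & dets$cy_px < 60  # one cell only
  dets2 <- dets[!(victim & dets$frame == drop_frame), ]
  tr2 <- link_tracks(dets2, max_gap = 2, min_track_len = 20)
  expect_equal(dplyr::n_distinct(tr2$cell_id), 4)
  expect_equal(sum(tr2$interpolated), 1)
  # distant cells are never merged under a small jump cap
  expect_true(all(dplyr::count(tr2, cell_id)$n == length(s$st$frames)))
})

test_that("per-cell fit recovers noiseless kinetics to high precision", {
  t <- seq(0, 1250, by = 10)
  R_in <- 4; ratio <- 1.68; tau <- 200; t0 <- 50
  r <- R_in + (R_in * ratio - R_in) * (1 - exp(-pmax(t - t0, 0) / tau))
  fit <- fit_swelling(tibble::tibble(time_s = t, radius_um = r), t0)
  expect_equal(fit$ratio, ratio, tolerance = 0.005)
  expect_equal(fit$tau_s, tau, tolerance = 0.005 * tau)
  expect_true(fit$converged)
})

test_that("constant-radius tracks give ratio 1 and are unidentifiable", {
  t <- seq(0, 500, by = 10)
  fit <- fit_swelling(tibble::tibble(time_s = t, radius_um = rep(4, length(t))),
                      t0_s = 50)
  expect_equal(fit$ratio, 1)
  expect_false(fit$identifiable)
})

test_that("noisy per-cell fits agree with a grid-search oracle", {
  set.seed(33)
  t <- seq(0, 1250, by = 10)
  R_in <- 4; ratio <- 1.5; tau <- 180; t0 <- 50
  r <- R_in + (R_in * ratio - R_in) * (1 - exp(-pmax(t - t0, 0) / tau)) +
    rnorm(length(t), 0, 0.02 * R_in)
  track <- tibble::tibble(time_s = t, radius_um = r)
  fit <- fit_swelling(track, t0)
  R_in_hat <- mean(r[t < t0])
  oracle <- grid_search_swelling(t, r, t0, R_in_hat)
  expect_equal(fit$ratio, oracle[1], tolerance = 0.01)
  expect_equal(fit$tau_s, oracle[2], tolerance = 0.06 * tau)
})

test_that("ratio and tau are invariant to radius scaling and time shifts", {
  t <- seq(0, 800, by = 10)
  r <- 4 + 2 * (1 - exp(-pmax(t - 50, 0) / 150)) +
    sin(seq_along(t)) * 0.01           # deterministic wiggle
  track <- tibble::tibble(time_s = t, radius_um = r)
  f1 <- fit_swelling(track, 50)
  f2 <- fit_swelling(dplyr::mutate(track, radius_um = radius_um * 3.2), 50)
  expect_equal(f2$ratio, f1$ratio, tolerance = 1e-6)
  expect_equal(f2$tau_s, f1$tau_s, tolerance = 1e-6)
  f3 <- fit_swelling(dplyr::mutate(track, time_s = time_s + 500), 550)
  expect_equal(f3$ratio, f1$ratio, tolerance = 1e-6)
  expect_equal(f3$tau_s, f1$tau_s, tolerance = 1e-6)
})

test_that("global fit matches per-cell estimates for identical cells", {
  t <- seq(0, 800, by = 10)
  mk <- function(R_in) tibble::tibble(
    cell_id = paste0("c", R_in), time_s = t,
    radius_um = R_in * (1 + 0.5 * (1 - exp(-pmax(t - 50, 0) / 150))))
  tracks <- dplyr::bind_rows(mk(3), mk(4), mk(5))
  g <- fit_swelling_global(tracks, 50)
  expect_equal(g$ratio, 1.5, tolerance = 1e-3)
  expect_equal(g$tau_s, 150, tolerance = 0.01 * 150)
  # heterogeneous tau: pooled estimate lies within the per-cell range
  mk2 <- function(tau) tibble::tibble(
    cell_id = paste0("t", tau), time_s = t,
    radius_um = 4 * (1 + 0.5 * (1 - exp(-pmax(t - 50, 0) / tau))))
  tracks2 <- dplyr::bind_rows(mk2(100), mk2(300))
  g2 <- fit_swelling_global(tracks2, 50)
  expect_gt(g2$tau_s, 100)
  expect_lt(g2$tau_s, 300)
})
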