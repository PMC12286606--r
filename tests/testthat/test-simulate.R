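test_that("noiseless ballistic track is exactly linear in time", {
  p <- motion_params("directed", v = 0.1, D = 0, direction = c(1, 0, 0),
                     sigma_loc = 0, dt = 10, n_frames = 8)
  tr <- simulate_track(p, start = c(0, 0, 0))
  expect_equal(tr$x_um, 0:7, tolerance = 1e-12)
  expect_equal(tr$y_um, rep(0, 8))
  expect_equal(tr$z_um, rep(0, 8))
  expect_equal(tr$t_s, (0:7) * 10)
})

test_that("Brownian increments have variance 2 D dt per axis", {
  p <- motion_params("brownian", D = 0.01, sigma_loc = 0, dt = 5,
                     n_frames = 10001, seed = 101)
  tr <- simulate_track(p)
  for (ax in c("x_um", "y_um", "z_um")) {
    v <- var(diff(tr[[ax]]))
    expect_lt(abs(v - 0.1) / 0.1, 0.05)
  }
})

test_that("confined track never leaves the corral", {
  p <- motion_params("confined", D = 0.05, R_conf = 0.5, sigma_loc = 0,
                     dt = 5, n_frames = 500, seed = 7)
  tr <- simulate_track(p, start = c(1, 2, 3))
  r <- sqrt((tr$x_um - 1)^2 + (tr$y_um - 2)^2 + (tr$z_um - 3)^2)
  expect_true(all(r <= 0.5 + 1e-12))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  mix <- list(list(params = motion_params("brownian", D = 0.01), count = 5),
              list(params = motion_params("directed", v = 0.05), count = 3))
  a <- simulate_trackset(mix, seed = 42)
  b <- simulate_trackset(mix, seed = 42)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$labels, b$labels)
})

test_that("mixtures preserve counts and labels", {
  mix <- list(list(params = motion_params("brownian", D = 0.01), count = 5),
              list(params = motion_params("directed", v = 0.05), count = 3))
  ts <- simulate_trackset(mix, seed = 1)
  expect_equal(length(unique(ts$tracks$track_id)), 8)
  expect_equal(sum(ts$labels$label == "brownian"), 5)
  expect_equal(sum(ts$labels$label == "directed"), 3)
  expect_setequal(ts$labels$track_id, unique(ts$tracks$track_id))
  expect_error(simulate_trackset(list()), "non-empty")
})

test_that("base-directed tracks in a tilted cell move within 90 deg of the axis", {
  g <- cell_geometry(c(0, 0, 0), c(10 * cos(pi / 6), 10 * sin(pi / 6), 0),
                     nucleus_plane = 5) # axis angle 30 deg
  mix <- list(list(params = motion_params("directed", v = 0.1, D = 0,
                                          direction = "base", sigma_loc = 0),
                   count = 6))
  ts <- simulate_trackset(mix, geometry = g, seed = 3)
  ang <- track_angles(ts$tracks, g)
  expect_true(all(ang$angle_deg < 90))
})

test_that("comet fields have the requested polarity structure", {
  g <- make_geom()
  cf <- simulate_comet_field(g, n = 30, p_base = 1, jitter_deg = 0,
                             sigma_loc = 0, seed = 5)
  ang <- track_angles(cf$tracks, g)
  expect_equal(max(ang$angle_deg), 0, tolerance = 1e-9)

  cf6 <- simulate_comet_field(g, n = 25, lifetime_frames = 6, seed = 5)
  expect_true(all(table(cf6$tracks$track_id) == 6))

  n <- 2598
  cf8 <- simulate_comet_field(g, n = n, p_base = 0.8, seed = 11)
  obs <- mean(cf8$labels$label == "base")
  ci <- qbinom(c(0.005, 0.995), n, 0.8) / n
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
  expect_error(simulate_comet_field(g, n = 0), "n must be")
})

test_that("ensemble Brownian MSD matches 6 D tau at small lags", {
  D <- 0.01; dt <- 5; n_tracks <- 500; n_frames <- 60
  acc <- 0
  set.seed(202)
  for (i in seq_len(n_tracks)) {
    tr <- simulate_track(motion_params("brownian", D = D, sigma_loc = 0,
                                       dt = dt, n_frames = n_frames))
    acc <- acc + compute_msd(tr)$msd_um2
  }
  m <- acc / n_tracks
  tau <- seq_len(n_frames - 1) * dt
  k_small <- seq_len(floor((n_frames - 1) * 0.25))
  rel <- abs(m[k_small] / (6 * D * tau[k_small]) - 1)
  expect_true(all(rel < 0.05))
})

test_that("confined long-lag MSD matches the uniform-ball Monte-Carlo oracle", {
  R <- 0.5
  # independent oracle: E|X - Y|^2 for two uniform points in the ball,
  # by direct Monte-Carlo (rejection sampling), not via the simulator
  set.seed(303)
  rball <- function(n) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      cand <- matrix(runif(3 * 2 * n, -R, R), ncol = 3)
      cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
      out <- rbind(out, cand)
    }
    out[seq_len(n), ]
  }
  mc <- mean(rowSums((rball(20000) - rball(20000))^2))
  expect_equal(mc, 6 * R^2 / 5, tolerance = 0.02) # oracle sanity

  acc <- 0; n_tracks <- 200; n_frames <- 80
  for (i in seq_len(n_tracks)) {
    tr <- simulate_track(motion_params("confined", D = 0.02, R_conf = R,
                                       sigma_loc = 0, dt = 5,
                                       n_frames = n_frames))
    acc <- acc + compute_msd(tr)$msd_um2
  }
  plateau <- mean((acc / n_tracks)[40:60])
  expect_lt(abs(plateau - mc) / mc, 0.10)
})

test_that("fusion pair scenarios produce the constructed outcomes", {
  # positive: coincidence covering >= 5 simulated minutes
  fp <- simulate_fusion_pair(meet_frame = 10, post_frames = 10,
                             params = list(dt = 50), seed = 3)
  ev <- detect_fusions(rbind(fp$track_a, fp$track_b), fusion_params(dt = 50))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$merge_frame, fp$event$merge_frame)

  # negative: crossing at one frame, then diverging
  fn <- simulate_fusion_pair(meet_frame = 10, post_frames = 0,
                             params = list(dt = 50), seed = 3)
  ev0 <- detect_fusions(rbind(fn$track_a, fn$track_b), fusion_params(dt = 50))
  expect_equal(nrow(ev0), 0)

  # remaining-timelapse rule: meet 2 min before the end, coincident to end
  fe <- simulate_fusion_pair(meet_frame = 10, post_frames = 2,
                             params = list(dt = 60), seed = 4)
  tl_end <- max(fe$track_a$t_s)
  eve <- detect_fusions(rbind(fe$track_a, fe$track_b),
                        fusion_params(dt = 60), timelapse_end_s = tl_end)
  expect_equal(nrow(eve), 1)
  expect_true(eve$reaches_end)
  expect_lt(eve$co_persistence_s, 300)
})
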