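test_that("MSD of a noiseless ballistic track is exactly v^2 tau^2", {
  p <- motion_params("directed", v = 0.1, D = 0, sigma_loc = 0, dt = 10,
                     n_frames = 20)
  pr <- compute_msd(simulate_track(p))
  expect_equal(pr$msd_um2, (0.1 * pr$lag_s)^2, tolerance = 1e-12)
  expect_equal(pr$n_pairs, 19:1)
})

test_that("MSD of a stationary track is zero and its fit is degenerate", {
  tr <- data.frame(frame = 1:12, t_s = (0:11) * 5, x_um = 2, y_um = 3,
                   z_um = 1)
  pr <- compute_msd(tr)
  expect_true(all(pr$msd_um2 == 0))
  expect_error(fit_alpha(pr), "degenerate")
})

test_that("MSD eligibility and uniform sampling are enforced", {
  tr <- data.frame(frame = 1:8, t_s = (0:7) * 5, x_um = 1:8, y_um = 0,
                   z_um = 0)
  expect_error(compute_msd(tr), "8 points")
  tr2 <- data.frame(frame = 1:12, t_s = c((0:10) * 5, 70), x_um = 1:12,
                    y_um = 0, z_um = 0)
  expect_error(compute_msd(tr2), "non-uniform")
})

test_that("pairs spanning a gap-closed frame are excluded from the MSD", {
  fr <- setdiff(1:13, 7)
  tr <- data.frame(frame = fr, t_s = (fr - 1) * 5, x_um = 0.1 * fr,
                   y_um = 0, z_um = 0)
  pr <- compute_msd(tr)
  # lag 1: pairs (6,7) and (7,8) are gone -> 10 of 12
  expect_equal(pr$n_pairs[1], 10)
  # surviving pairs still measure the exact ballistic law
  ok <- pr$n_pairs > 0
  expect_equal(pr$msd_um2[ok], (0.1 / 5 * pr$lag_s[ok])^2, tolerance = 1e-12)
})

test_that("alpha hits the closed-form limits exactly", {
  # ballistic: alpha = 2
  p <- motion_params("directed", v = 0.1, D = 0, sigma_loc = 0, dt = 5,
                     n_frames = 40)
  fit2 <- fit_alpha(compute_msd(simulate_track(p)))
  expect_equal(fit2$alpha, 2.0, tolerance = 1e-9)
  # exactly linear MSD profile: alpha = 1
  prof <- data.frame(lag_s = (1:40) * 5, msd_um2 = 6 * 0.01 * (1:40) * 5,
                     n_pairs = 40:1)
  fit1 <- fit_alpha(prof)
  expect_equal(fit1$alpha, 1.0, tolerance = 1e-9)
})

test_that("median alpha recovers each simulated motion class", {
  set.seed(404)
  med_alpha <- function(p) {
    a <- vapply(seq_len(120), function(i)
      fit_alpha(compute_msd(simulate_track(p)))$alpha, numeric(1))
    median(a)
  }
  m_br <- med_alpha(motion_params("brownian", D = 0.01, sigma_loc = 0,
                                  dt = 5, n_frames = 100))
  expect_gt(m_br, 0.9); expect_lt(m_br, 1.1)
  m_co <- med_alpha(motion_params("confined", D = 0.01, R_conf = 0.25,
                                  sigma_loc = 0, dt = 5, n_frames = 100))
  expect_lt(m_co, 1)
  m_di <- med_alpha(motion_params("directed", v = 0.05, D = 0.002,
                                  sigma_loc = 0, dt = 5, n_frames = 100))
  expect_gt(m_di, 1)
})

test_that("the exponent rule classifies motion with alpha = 1 confined", {
  expect_equal(classify_motion(1.5), "directional")
  expect_equal(classify_motion(0.5), "confined")
  expect_equal(classify_motion(1.0), "confined") # boundary tie-break
  expect_error(classify_motion(NaN), "finite")
})

test_that("track displacement is start-to-end Euclidean with a strict 1 um rule", {
  tr <- data.frame(frame = 1:3, x_um = c(0, 7, 3), y_um = c(0, -2, 4),
                   z_um = 0)
  d <- track_displacement(tr)
  expect_equal(d$displacement_um, 5) # 3-4-5 triangle
  expect_true(d$long_track)

  tr1 <- data.frame(frame = 1:2, x_um = c(0, 0.6), y_um = c(0, 0.8), z_um = 0)
  d1 <- track_displacement(tr1)
  expect_equal(d1$displacement_um, 1.0)
  expect_false(d1$long_track) # strict >

  loop <- data.frame(frame = 1:5, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0), z_um = 0)
  expect_equal(track_displacement(loop)$displacement_um, 0)
})

test_that("displacement is invariant under rigid motions", {
  set.seed(14)
  tr <- data.frame(frame = 1:10, x_um = cumsum(rnorm(10)),
                   y_um = cumsum(rnorm(10)), z_um = cumsum(rnorm(10)))
  d0 <- track_displacement(tr)$displacement_um
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos <- as.matrix(tr[, c("x_um", "y_um", "z_um")]) %*% R
  tr2 <- data.frame(frame = tr$frame, x_um = pos[, 1] + 5,
                    y_um = pos[, 2] - 3, z_um = pos[, 3] + 1)
  expect_equal(track_displacement(tr2)$displacement_um, d0, tolerance = 1e-12)
})

test_that("direction and position follow the axis geometry", {
  g <- make_geom() # axis along +y, angle 90
  along <- data.frame(frame = 1:2, x_um = 5, y_um = c(2, 5), z_um = 1)
  dp <- assign_direction_and_position(along, g)
  expect_equal(dp$direction, "base")

  perp <- data.frame(frame = 1:2, x_um = c(5, 8), y_um = 2, z_um = 1)
  expect_equal(assign_direction_and_position(perp, g)$direction,
               "undetermined") # 90 deg, inside the default band

  toward_apex <- data.frame(frame = 1:2, x_um = 5, y_um = c(5, 2), z_um = 1)
  expect_equal(assign_direction_and_position(toward_apex, g)$direction,
               "apex")

  basal <- data.frame(frame = 1:3, x_um = 5, y_um = c(7, 7.5, 8), z_um = 1)
  expect_equal(assign_direction_and_position(basal, g)$position,
               "below_nucleus")
  apical <- data.frame(frame = 1:3, x_um = 5, y_um = c(1.5, 2, 2.5), z_um = 1)
  expect_equal(assign_direction_and_position(apical, g)$position,
               "above_nucleus")
})

test_that("summaries report the right fractions and partitions", {
  cls <- data.frame(track_id = 1:5, n_spots = 20,
                    displacement_um = c(2, 0.5, 0.5, 0.5, 0.5),
                    long_track = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    alpha = c(1.6, 0.7, 0.8, 0.9, 0.5),
                    r_squared = 0.99,
                    motion_class = c("directional", rep("confined", 4)),
                    direction = c("base", NA, NA, NA, NA),
                    position = c("below_nucleus", NA, NA, NA, NA))
  s <- summarize_motion(cls)
  expect_equal(s$directional_fraction, 0.2)
  expect_equal(s$confined_fraction, 0.8)
  expect_equal(s$directional_fraction + s$confined_fraction, 1)
  expect_equal(s$long_fraction, 0.2)
  expect_equal(unname(s$direction_breakdown["base"]), 1)
  expect_error(summarize_motion(cls[0, ]), "empty")
})

test_that("a labeled directed/confined mixture is classified to >= 95%", {
  g <- make_geom()
  mix <- list(
    list(params = motion_params("directed", v = 0.05, D = 0.002,
                                direction = "base", sigma_loc = 0,
                                dt = 5, n_frames = 100), count = 30),
    list(params = motion_params("confined", D = 0.01, R_conf = 0.25,
                                sigma_loc = 0, dt = 5, n_frames = 100),
         count = 70))
  ts <- simulate_trackset(mix, geometry = g, seed = 21)
  cls <- analyze_tracks(ts$tracks, g)
  truth <- ts$labels$label[match(cls$track_id, ts$labels$track_id)]
  pred <- ifelse(cls$motion_class == "directional", "directed", "confined")
  acc <- mean(pred == truth)
  expect_gte(acc, 0.95)
  # recovered directional fraction within 5 points of the planted 30%
  s <- summarize_motion(cls)
  expect_lt(abs(s$directional_fraction - 0.30), 0.05)
})
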