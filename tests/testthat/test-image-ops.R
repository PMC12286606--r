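test_that("constructed drift is recovered and undone", {
  rp <- render_params(noise_model = "none", stack_shape = c(48, 48, 10))
  v1 <- render_stack(rbind(c(0.8, 0.9, 0.8), c(1.2, 1.3, 1.2)), rp)$data
  arr <- array(0, c(dim(v1), 4))
  arr[, , , 1] <- v1
  for (t in 2:4) arr[, , , t] <- ribbonmotion:::shift_volume(v1, c(3 * (t - 1), 0, 0))
  st <- image_stack(arr, rp$voxel_size, dt = 10)
  cd <- correct_drift(st)
  expect_equal(unname(cd$offsets[, "row"]), c(0, 3, 6, 9), tolerance = 0.2)
  expect_equal(unname(cd$offsets[, "col"]), rep(0, 4), tolerance = 0.2)
  # registered frames put the spots back where frame 1 has them
  pk1 <- which(v1 == max(v1), arr.ind = TRUE)[1, ]
  pk4 <- which(cd$registered$data[, , , 4] == max(cd$registered$data[, , , 4]),
               arr.ind = TRUE)[1, ]
  expect_true(all(abs(pk1 - pk4) <= 1))
})

test_that("identical frames register with zero offsets", {
  rp <- render_params(noise_model = "none", stack_shape = c(32, 32, 6))
  v <- render_stack(rbind(c(0.6, 0.6, 0.5)), rp)$data
  arr <- array(rep(v, 3), c(dim(v), 3))
  cd <- correct_drift(image_stack(arr, rp$voxel_size, dt = 5))
  expect_equal(max(abs(cd$offsets)), 0, tolerance = 1e-9)
})

test_that("registration refuses frames without signal", {
  arr <- array(0, c(8, 8, 2, 3))
  expect_error(correct_drift(image_stack(arr, c(0.04, 0.04, 0.17), dt = 1)),
               "all-zero")
})

test_that("spot detection localizes a noiseless spot to subvoxel accuracy", {
  rp <- render_params(noise_model = "none", stack_shape = c(48, 48, 12))
  truth <- c(0.93, 0.81, 1.00)
  st <- render_stack(rbind(truth), rp)
  sp <- detect_spots(st, expected_diameter_um = 0.427, quality_threshold = 5)
  expect_equal(nrow(sp), 1)
  err_vox <- abs(c(sp$x_um - truth[1], sp$y_um - truth[2]) / rp$voxel_size[1:2])
  expect_true(all(err_vox < 0.5))
  expect_lt(abs(sp$z_um - truth[3]) / rp$voxel_size[3], 0.5)
})

test_that("a flat image yields no detections", {
  st <- image_stack(array(5, c(24, 24, 6)), c(0.04, 0.04, 0.17))
  sp <- detect_spots(st, 0.427, quality_threshold = 5)
  expect_equal(nrow(sp), 0)
})

test_that("detection at SNR 10 finds nearly all spots with no false positives", {
  set.seed(31)
  # 20 spots on a jittered grid, pairwise well separated
  gx <- rep(seq(0.6, 3.4, length.out = 5), 4)
  gy <- rep(seq(0.6, 3.4, length.out = 4), each = 5)
  pts <- cbind(gx + runif(20, -0.1, 0.1), gy + runif(20, -0.1, 0.1),
               runif(20, 0.8, 1.8))
  bg <- 100 # Poisson noise sd = 10 at the background: peak SNR = 10
  rp <- render_params(noise_model = "poisson", spot_amplitude = 100,
                      background = bg, stack_shape = c(100, 100, 16))
  st <- render_stack(pts, rp, seed = 32)
  sp <- detect_spots(st, expected_diameter_um = 0.427, quality_threshold = 5)
  # match detections to truth within one diameter
  dmat <- as.matrix(dist(rbind(pts, as.matrix(sp[, c("x_um", "y_um", "z_um")]))))
  dmat <- dmat[seq_len(20), -seq_len(20), drop = FALSE]
  matched <- apply(dmat, 2, min) < 0.427
  expect_true(all(matched))            # no false positives
  expect_gte(sum(apply(dmat, 1, min) < 0.427), 19) # at least 19 of 20 found
})

test_that("watershed splitting separates touching spot pairs", {
  rp <- render_params(noise_model = "none", spot_amplitude = 200,
                      psf_sigma = c(0.05, 0.2), stack_shape = c(64, 64, 12))
  pts <- rbind(c(1.18, 1.28, 1.0), c(1.38, 1.28, 1.0)) # 0.2 um apart
  st <- render_stack(pts, rp)
  merged <- segment_puncta_3d(st, 60, split_touching = FALSE)
  split <- segment_puncta_3d(st, 60, split_touching = TRUE,
                             seed_sep_um = 0.15)
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
})

test_that("the object-counter size filter excludes oversized objects exactly", {
  # constructed object of 200,000 voxels in a 100 x 100 x 25 volume
  arr <- array(0, c(100, 100, 25))
  arr[1:80, 1:100, 1:25] <- 50
  expect_equal(sum(arr > 0), 200000)
  st <- image_stack(arr, c(0.04, 0.04, 0.17))
  rec_excl <- segment_puncta_3d(st, 25, split_touching = FALSE,
                                max_size_vox = 183500)
  expect_equal(nrow(rec_excl), 0)
  rec_keep <- segment_puncta_3d(st, 25, split_touching = FALSE,
                                max_size_vox = 200000)
  expect_equal(nrow(rec_keep), 1)
  expect_equal(rec_keep$volume_voxels, 200000)
})

test_that("raising the threshold never grows the segmented volume", {
  rp <- render_params(noise_model = "poisson", stack_shape = c(48, 48, 10))
  st <- render_stack(rbind(c(0.8, 0.8, 0.8), c(1.5, 1.4, 1.0)), rp, seed = 8)
  vol_at <- function(thr) {
    recs <- segment_puncta_3d(st, thr, split_touching = FALSE, min_size_vox = 0)
    sum(recs$volume_voxels)
  }
  vols <- vapply(c(20, 40, 60, 90, 130), vol_at, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("apical/basal labels follow the nucleus plane and partition the set", {
  g <- make_geom()
  apex_df <- data.frame(x_um = g$apex_point[1], y_um = g$apex_point[2],
                        z_um = g$apex_point[3])
  base_df <- data.frame(x_um = g$base_point[1], y_um = g$base_point[2],
                        z_um = g$base_point[3])
  expect_equal(classify_apical_basal(apex_df, g)$compartment, "apical")
  expect_equal(classify_apical_basal(base_df, g)$compartment, "basal")

  set.seed(12)
  pts <- data.frame(x_um = runif(40, 0, 10), y_um = runif(40, 0, 10),
                    z_um = runif(40, 0, 2))
  cl <- classify_apical_basal(pts, g)
  cnt <- attr(cl, "counts")
  expect_equal(sum(cnt), 40)
})

test_that("2D areas match the analytic Gaussian level set", {
  # amplitude A over zero background; the super-threshold region of a 2D
  # Gaussian is a disc with r^2 = 2 sigma^2 log(A / thr)
  rp <- render_params(noise_model = "none", spot_amplitude = 200,
                      background = 0, psf_sigma = c(0.2, 0.25),
                      stack_shape = c(64, 64, 8))
  st <- render_stack(rbind(c(1.28, 1.28, 0.6)), rp)
  thr <- 100
  areas <- quantify_areas_2d(st, rolling_ball_radius_px = 30, threshold = thr)
  analytic <- pi * 2 * 0.2^2 * log(200 / thr)
  expect_equal(length(areas), 1)
  expect_lt(abs(areas - analytic) / analytic, 0.15)
})

test_that("the 2D minimum-size filter drops sub-0.002 um^2 objects", {
  arr <- array(0, c(32, 32, 2))
  arr[5, 5, 1] <- 50        # one pixel: 0.0016 um^2 < 0.002
  arr[20, 20:21, 1] <- 50   # two pixels: 0.0032 um^2
  st <- image_stack(arr, c(0.04, 0.04, 0.17))
  areas <- quantify_areas_2d(st, rolling_ball_radius_px = 5, threshold = 25,
                             split_touching = FALSE)
  expect_equal(length(areas), 1)
  expect_equal(areas, 2 * 0.04^2, tolerance = 1e-12)
})

test_that("a flat image yields no areas (with a warning)", {
  st <- image_stack(array(3, c(24, 24, 2)), c(0.04, 0.04, 0.17))
  expect_warning(areas <- quantify_areas_2d(st, 10, threshold = 50),
                 "threshold")
  expect_equal(length(areas), 0)
})

test_that("areas are invariant to an added constant background", {
  rp <- render_params(noise_model = "none", spot_amplitude = 200,
                      background = 0, psf_sigma = c(0.2, 0.25),
                      stack_shape = c(64, 64, 4))
  st <- render_stack(rbind(c(1.0, 1.0, 0.3), c(1.9, 1.9, 0.3)), rp)
  a0 <- quantify_areas_2d(st, 30, threshold = 80)
  st_bg <- image_stack(st$data + 40, st$voxel_size)
  a1 <- quantify_areas_2d(st_bg, 30, threshold = 80)
  expect_equal(sort(a0), sort(a1))
})

test_that("kinocilium staging reproduces the height bins", {
  expect_equal(stage_cell(10)$stage, "intermediate") # 4.25 um
  expect_equal(stage_cell(2)$stage, "early")         # 0.85 um
  expect_equal(stage_cell(48)$stage, "mature")       # 20.4 um
  # boundary heights via a unit z interval
  expect_equal(stage_cell(1, 1.5)$stage, "intermediate")  # 1.5 -> [1.5,10)
  expect_equal(stage_cell(1, 10)$stage, "late")           # 10 -> [10,18]
  expect_equal(stage_cell(1, 18)$stage, "late")           # 18 still late
  expect_equal(stage_cell(1, 18.001)$stage, "mature")
  expect_equal(stage_cell(0)$stage, "early")
  expect_error(stage_cell(-1), ">= 0")
  # total and single-valued on a height sweep
  sweep <- stage_cell(seq(0, 60, by = 1), z_interval_um = 0.425)
  expect_true(all(sweep$stage %in% c("early", "intermediate", "late", "mature")))
  expect_equal(nrow(sweep), 61)
})
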