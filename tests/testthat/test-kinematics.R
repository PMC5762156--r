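# Reaching kinematics: closed-form paths, ground-truth recovery, metric
# invariances, paw tracking.

test_that("speed is exact for uniform straight motion and zero when stationary", {
  t <- seq(0, 1, by = 1 / 120)
  traj <- tibble::tibble(t = t, x = 30 * t, y = 0)
  sp <- speed_profile(traj, smoothing_window = 1)
  expect_equal(sp$v[2:(length(t) - 1)], rep(30, length(t) - 2), tolerance = 1e-9)

  still <- tibble::tibble(t = t, x = rep(1, length(t)), y = rep(2, length(t)))
  expect_true(all(speed_profile(still)$v == 0))
})

test_that("arc length and enclosed area match closed forms on canonical paths", {
  # straight out and back along one line: zero enclosed area
  out_back <- polyline_trajectory(rbind(c(0, 0), c(10, 0), c(0, 0)))
  km1 <- kinematic_metrics(out_back)
  expect_equal(km1$arc_len_mm, 20, tolerance = 1e-9)
  expect_equal(km1$auc_mm2, 0, tolerance = 1e-9)

  # square loop of side 10
  sq <- polyline_trajectory(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0)))
  km2 <- kinematic_metrics(sq)
  expect_equal(km2$arc_len_mm, 40, tolerance = 1e-9)
  expect_equal(km2$auc_mm2, 100, tolerance = 1e-9)

  # open path: polygon is closed by the endpoint chord
  tri <- polyline_trajectory(rbind(c(0, 0), c(10, 0), c(10, 10)))
  expect_equal(kinematic_metrics(tri)$auc_mm2, 50, tolerance = 1e-9)
})

test_that("smoothness equals the injected submovement count for 1 to 5 bells", {
  for (n in 1:5) {
    traj <- gen_reach_trajectory(reach_config(n_submovements = n, seed = n,
                                              total_duration = 1.5))
    km <- kinematic_metrics(traj)
    expect_equal(km$smoothness, n)
  }
})

test_that("generated trajectories recover their ground-truth metrics", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 3, seed = 9,
                                            total_duration = 2))
  gt <- attr(traj, "ground_truth")
  km <- kinematic_metrics(traj)
  expect_equal(km$arc_len_mm, gt$arc_len_mm, tolerance = 0.02)
  expect_equal(km$auc_mm2, gt$auc_mm2, tolerance = 0.02)
  expect_equal(km$mean_speed_mms, gt$mean_speed_mms, tolerance = 0.05)
})

test_that("arc length and area are invariant under rigid motion", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 2, seed = 5))
  km <- kinematic_metrics(traj)
  th <- 0.7
  rot <- traj
  rot$x <- cos(th) * traj$x - sin(th) * traj$y + 12
  rot$y <- sin(th) * traj$x + cos(th) * traj$y - 3
  km_rot <- kinematic_metrics(rot)
  expect_equal(km_rot$arc_len_mm, km$arc_len_mm, tolerance = 1e-9)
  expect_equal(km_rot$auc_mm2, km$auc_mm2, tolerance = 1e-9)
})

test_that("mean speed times duration approximates arc length", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 3, seed = 2,
                                            total_duration = 2))
  sp <- speed_profile(traj, smoothing_window = 1)
  km <- kinematic_metrics(traj, speed = sp)
  dur <- max(traj$t) - min(traj$t)
  expect_lt(abs(km$mean_speed_mms * dur - km$arc_len_mm) / km$arc_len_mm, 0.02)
})

test_that("smoothness is non-decreasing as the prominence floor drops", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 4, seed = 8,
                                            noise_sd_xy = 0.05))
  sp <- speed_profile(traj)
  counts <- vapply(c(0.5, 0.2, 0.1, 0.02),
                   function(f) kinematic_metrics(traj, sp,
                                                 peak_prominence_frac = f)$smoothness,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("doubling the frame rate changes arc length by less than 1%", {
  cfg_lo <- reach_config(n_submovements = 3, seed = 4, frame_rate = 120)
  cfg_hi <- reach_config(n_submovements = 3, seed = 4, frame_rate = 240)
  a_lo <- kinematic_metrics(gen_reach_trajectory(cfg_lo))$arc_len_mm
  a_hi <- kinematic_metrics(gen_reach_trajectory(cfg_hi))$arc_len_mm
  expect_lt(abs(a_hi - a_lo) / a_lo, 0.01)
})

test_that("the tracker follows a rendered disc to sub-pixel accuracy", {
  # disc moving exactly 1 px per frame
  mmpx <- 0.1
  pos <- tibble::tibble(x = (0:19) * mmpx, y = rep(0, 20))
  frames <- render_reach_frames(pos, mm_per_px = mmpx, dims = c(60, 80),
                                radius_px = 5, origin_px = c(20, 30))
  traj <- track_paw(frames, mm_per_px = mmpx)
  steps_px <- diff(traj$x) / mmpx
  expect_true(all(abs(steps_px - 1) < 0.1))

  # centroid follows the larger of two blobs
  fr2 <- render_reach_frames(tibble::tibble(x = 0, y = 0), mm_per_px = mmpx,
                             dims = c(60, 80), radius_px = 8,
                             origin_px = c(30, 30))
  small <- render_reach_frames(tibble::tibble(x = 0, y = 0), mm_per_px = mmpx,
                               dims = c(60, 80), radius_px = 3,
                               origin_px = c(65, 30))
  fr2[, , 2, 1] <- pmax(fr2[, , 2, 1], small[, , 2, 1])
  tr2 <- track_paw(fr2, mm_per_px = mmpx)
  expect_lt(abs(tr2$x[1] / mmpx - 30), 1)
})

test_that("trials with mostly empty masks are rejected", {
  gray <- array(90, dim = c(40, 40, 3, 8))
  expect_error(track_paw(gray, mm_per_px = 0.1), class = "strokelab_track_rejected")

  # a minority of empty frames is interpolated and flagged instead
  pos <- tibble::tibble(x = (0:9) * 0.1, y = rep(0, 10))
  frames <- render_reach_frames(pos, mm_per_px = 0.1, dims = c(60, 80),
                                radius_px = 5, origin_px = c(20, 30))
  frames[, , , 5] <- 90
  traj <- track_paw(frames, mm_per_px = 0.1)
  expect_true(traj$interpolated[5])
  expect_equal(traj$x[5], (traj$x[4] + traj$x[6]) / 2, tolerance = 1e-9)
})

test_that("baseline normalization subtracts per-animal baseline means", {
  d <- tibble::tibble(
    animal = rep(c("a", "b"), each = 4),
    session = rep(c("base1", "base2", "d2", "d9"), 2),
    arc = c(10, 14, 15, 20, 6, 6, 9, 6)
  )
  out <- baseline_normalize(d, arc, session, c("base1", "base2"), animal)
  expect_equal(out$arc_norm, c(-2, 2, 3, 8, 0, 0, 3, 0))
  expect_error(
    baseline_normalize(d, arc, session, "nonexistent", animal),
    "baseline"
  )
})
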