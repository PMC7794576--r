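test_that("pinhole projection matches hand-computed screen positions", {
  cam <- camera_model()
  # 10 m directly ahead on the ground: centred horizontally, below centre
  # by (eye_height/10) on the unit plane scaled into the vertical FOV
  p <- world_to_screen(cam, c(0, 0), 0, cbind(10, 0))
  expect_equal(p$screen_x, 0.5, tolerance = 1e-12)
  expect_equal(p$screen_y, 0.5 - (1.2 / 10) / (2 * tan(29 * pi / 180)),
               tolerance = 1e-12)
  # the vehicle's own position has zero depth: behind/undefined
  p0 <- world_to_screen(cam, c(3, 4), 1.1, cbind(3, 4))
  expect_true(p0$behind)
  expect_true(is.na(p0$screen_x))
  # far-ahead points converge to the vanishing point at eye level
  pf <- world_to_screen(cam, c(0, 0), 0, cbind(1e7, 0))
  expect_equal(pf$screen_x, 0.5, tolerance = 1e-6)
  expect_equal(pf$screen_y, 0.5, tolerance = 1e-6)
})

test_that("projection respects yaw and flags points behind the camera", {
  cam <- camera_model()
  # heading +z; a point ahead on +z projects to centre column
  p <- world_to_screen(cam, c(0, 0), pi / 2, cbind(0, 10))
  expect_equal(p$screen_x, 0.5, tolerance = 1e-12)
  # a point to the right of heading lands right of centre
  pr <- world_to_screen(cam, c(0, 0), pi / 2, cbind(5, 10))
  expect_gt(pr$screen_x, 0.5)
  # and a point behind is flagged
  pb <- world_to_screen(cam, c(0, 0), pi / 2, cbind(0, -10))
  expect_true(pb$behind)
})

test_that("camera model validates its fields", {
  expect_error(camera_model(fov_h_deg = 190), "0, 180")
  expect_error(camera_model(screen_distance_m = 0), "positive")
})

test_that("gaze on a projected midline point maps back to that point", {
  ml <- default_midline()
  cam <- camera_model()
  # vehicle at arc 50 on the first straight; gaze exactly at the projection
  # of the midline point 16 m ahead
  veh_arc <- 50
  pos <- arc_to_world(ml, veh_arc)[1, ]
  yaw <- arc_to_heading(ml, veh_arc)
  target <- arc_to_world(ml, veh_arc + 16)
  scr <- world_to_screen(cam, pos, yaw, target)
  ref <- gaze_to_midline_reference(cam, pos, yaw, veh_arc, ml,
                                   c(scr$screen_x, scr$screen_y))
  expect_equal(ref$ref_arc_m, veh_arc + 16, tolerance = ml$cfg$resolution_m)
  expect_lt(ref$angular_error_deg, 0.01)
  # and the headway of that reference is 2.0 s exactly at 8 m/s
  expect_equal(compute_time_headway(veh_arc, veh_arc + 16, 8,
                                    ml$total_arc_m), 2.0)
})

test_that("small vertical gaze offsets keep the same reference", {
  ml <- default_midline()
  cam <- camera_model()
  veh_arc <- 50
  pos <- arc_to_world(ml, veh_arc)[1, ]
  yaw <- arc_to_heading(ml, veh_arc)
  target <- arc_to_world(ml, veh_arc + 16)
  scr <- world_to_screen(cam, pos, yaw, target)
  # perturb 0.5 degrees horizontally (perpendicular to the straight's
  # screen-vertical midline image): reference unchanged, error ~ 0.5 deg
  dx <- tan(0.5 * pi / 180) / (2 * cam$tan_h)
  ref <- gaze_to_midline_reference(cam, pos, yaw, veh_arc, ml,
                                   c(scr$screen_x + dx, scr$screen_y))
  expect_equal(ref$ref_arc_m, veh_arc + 16, tolerance = 0.5)
  expect_equal(ref$angular_error_deg, 0.5, tolerance = 0.05)
  # brute-force nearest search over a dense forward window agrees
  arcs <- seq(veh_arc, veh_arc + 64, by = ml$cfg$resolution_m)
  cand <- world_to_screen(cam, pos, yaw, arc_to_world(ml, arcs))
  d2 <- (cand$screen_x - (scr$screen_x + dx))^2 +
    (cand$screen_y - scr$screen_y)^2
  expect_equal(ref$ref_arc_m, arcs[which.min(d2)],
               tolerance = ml$cfg$resolution_m / 2)
})

test_that("gaze far from the road is excluded as far_from_midline", {
  s <- sim_trial(seed = 11, angular_noise_deg = 0, noise_frac = 0)
  g <- s$gaze[1:10, ]
  g$screen_x <- 0.98; g$screen_y <- 0.98  # screen corner, off the road
  th <- estimate_th(s$vehicle[1:10, ], g, s$midline, s$cam, s$window)
  expect_true(all(th$excluded))
  expect_true(all(th$reason == "far_from_midline"))
  expect_true(all(th$angular_error_deg > 20, na.rm = TRUE))
})

test_that("exclusion filters apply in order with first-hit reasons", {
  df <- data.frame(
    confidence = c(0.59, 1.0, 1.0, 0.5, 1.0),
    screen_x = c(0.5, 0.5, 0.5, 1.4, 0.025),
    screen_y = c(0.4, 0.4, 0.4, 0.5, 0.025),
    angular_error_deg = c(2, 25, 5, 30, 3))
  out <- apply_exclusions(df)
  expect_equal(out$reason,
               c("low_confidence", "far_from_midline", NA, "low_confidence",
                 "on_marker"))
  expect_equal(out$excluded, c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("fixating one world point yields a headway slope of -1", {
  ml <- default_midline()
  cam <- camera_model()
  track <- default_track()
  win <- default_trial_window(track)
  traj <- simulate_trajectory(ml, win)
  # synthetic trace fixating the fixed point 4 s past the window start for
  # the first 3 s of the trial
  rows <- 1:180
  target <- arc_to_world(ml, win$start_arc_m + 4 * 8)
  scr <- world_to_screen(cam, c(0, 0), 0, matrix(0, 1, 2)) # shape only
  gx <- gy <- numeric(length(rows))
  for (i in seq_along(rows)) {
    p <- world_to_screen(cam, c(traj$x[rows[i]], traj$z[rows[i]]),
                         traj$yaw[rows[i]], target)
    gx[i] <- p$screen_x; gy[i] <- p$screen_y
  }
  gaze <- data.frame(t = traj$t[rows], screen_x = gx, screen_y = gy,
                     confidence = 1)
  th <- estimate_th(traj[rows, ], gaze, ml, cam, win)
  fit <- stats::lm(th_s ~ time_into_trial_s, data = th[!th$excluded, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.01)
  # estimated headway matches the analytic arc distance over speed
  analytic <- (win$start_arc_m + 32 - traj$arc_m[rows]) / 8
  expect_lt(max(abs(th$th_s - analytic)), ml$cfg$resolution_m / 8 + 1e-6)
})

test_that("headway advances down by exactly the elapsed time for a fixed ref", {
  ml <- default_midline()
  th0 <- compute_time_headway(50, 66, 8, ml$total_arc_m)
  th1 <- compute_time_headway(58, 66, 8, ml$total_arc_m)  # 1 s later
  expect_equal(th0 - th1, 1.0)
  expect_equal(compute_time_headway(66, 66, 8, ml$total_arc_m), 0)
  # wrap-aware: reference just past the origin, vehicle just before it
  expect_equal(compute_time_headway(ml$total_arc_m - 8, 8, 8,
                                    ml$total_arc_m), 2.0)
})

test_that("injected off-task artefacts drive the exclusion fraction", {
  s <- sim_trial_th(seed = 5, angular_noise_deg = 0, noise_frac = 0.05)
  is_noise <- s$truth$label == "noise"
  # on-task samples are almost never excluded (only gaze that has tracked a
  # target to the display edge can be)
  expect_lt(mean(s$th$excluded[!is_noise]), 0.02)
  # the excluded share of artefacts reflects the share whose drawn
  # confidence/position fails a filter (binomial error at n ~ 45)
  expect_gt(mean(s$th$excluded[is_noise]), 0.4)
  expect_lt(mean(s$th$excluded), 0.05 + 0.02)
})

test_that("moderate angular noise barely moves the median headway", {
  base <- sim_trial_th(seed = 21, angular_noise_deg = 0, noise_frac = 0)
  pert <- sim_trial_th(seed = 21, angular_noise_deg = 0.5, noise_frac = 0)
  m0 <- median(base$th$th_s[!base$th$excluded])
  m1 <- median(pert$th$th_s[!pert$th$excluded])
  expect_lt(abs(m1 - m0), 0.1)
})

test_that("log readers remap configurable column layouts", {
  dir <- withr::local_tempdir()
  df <- data.frame(time = c(0, 1), px = c(1, 2), pz = c(3, 4),
                   heading = c(0, 0.1), m = "Manual", tr = 1L, subj = 2L)
  write.csv(df, file.path(dir, "veh.csv"), row.names = FALSE)
  out <- read_vehicle_log(file.path(dir, "veh.csv"),
                          cols = c(t = "time", x = "px", z = "pz",
                                   yaw = "heading", mode = "m", trial = "tr",
                                   participant = "subj"))
  expect_named(out, c("t", "x", "z", "yaw", "mode", "trial", "participant"))
  expect_equal(out$x, c(1, 2))
  expect_error(read_gaze_log(file.path(dir, "veh.csv")), "missing columns")
})
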