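# Build an angle-space sawtooth: pursuits of given durations drifting at
# `slope` deg/s in elevation, rejoined by instantaneous upward jumps.
make_sawtooth <- function(durations, slope = -8, jump = 3, hz = 60,
                          noise = 0) {
  t <- c(); el <- c(); cur <- 0; tt <- 0; brk <- c()
  for (d in durations) {
    nfr <- round(d * hz)
    t <- c(t, tt + (seq_len(nfr) - 1) / hz)
    el <- c(el, cur + (seq_len(nfr) - 1) / hz * slope)
    tt <- tt + nfr / hz
    cur <- cur + slope * d + jump
    brk <- c(brk, tt)
  }
  if (noise > 0) el <- el + rnorm(length(el), 0, noise)
  az <- if (noise > 0) rnorm(length(el), 0, noise) else numeric(length(el))
  list(t = t, az = az, el = el, breaks = brk[-length(brk)])
}

test_that("noiseless sawtooth is segmented at the true breakpoints", {
  sw <- make_sawtooth(rep(0.4, 5), jump = 3)
  segs <- segment_trace(sw$t, sw$az, sw$el)
  cl <- classify_segments(segs)
  # five pursuits and the four jumps between them
  expect_gte(nrow(cl), 9)
  expect_equal(sum(cl$kind == "saccade"), 4)
  sacc_mid <- (cl$t_start[cl$kind == "saccade"] +
                 cl$t_end[cl$kind == "saccade"]) / 2
  expect_true(all(vapply(sw$breaks, function(b)
    min(abs(sacc_mid - b)) <= 1 / 60 + 1e-9, logical(1))))
  # pursuit slopes recovered
  trk <- cl[cl$kind == "tracking", ]
  expect_true(all(abs(trk$slope_el - (-8)) < 0.2))
})

test_that("degenerate traces yield the degenerate segmentations", {
  t <- (0:199) / 60
  expect_equal(nrow(segment_trace(t, rep(1, 200), rep(2, 200))), 1)
  # pure white noise with a large penalty collapses to one segment
  set.seed(31)
  expect_equal(nrow(segment_trace(t, rnorm(200), rnorm(200),
                                  penalty = 1e3)), 1)
  expect_equal(nrow(segment_trace(t[1:3], rnorm(3), rnorm(3))), 0)
})

test_that("the calibrated penalty keeps a noisy constant trace whole", {
  t <- (0:889) / 60
  for (s in 1:5) {
    set.seed(s)
    segs <- segment_trace(t, rnorm(890, 0, 0.5), rnorm(890, 0, 0.5))
    expect_equal(nrow(segs), 1)
  }
})

test_that("dynamic programme matches brute-force enumeration on tiny traces", {
  brute_force_cost <- function(t, y, penalty, min_len = 2) {
    n <- length(t)
    seg_sse <- function(a, b) {
      sse <- 0
      for (c in seq_len(ncol(y))) {
        f <- stats::lm.fit(cbind(1, t[a:b]), y[a:b, c])
        sse <- sse + sum(f$residuals^2)
      }
      sse
    }
    best <- Inf; best_brk <- NULL
    # enumerate all compositions of n into parts >= min_len
    recurse <- function(start, brks, acc) {
      if (start > n) {
        if (acc < best) { best <<- acc; best_brk <<- brks }
        return(invisible())
      }
      if (n - start + 1 < min_len) return(invisible())
      for (end in seq(start + min_len - 1, n)) {
        recurse(end + 1, c(brks, end),
                acc + seg_sse(start, end) + penalty)
      }
    }
    recurse(1, c(), 0)
    list(cost = best, ends = best_brk)
  }
  set.seed(41)
  t <- (0:7) / 60
  y <- cbind(c(0, 0.1, -0.1, 3, 3.2, 2.9, 3.1, 3), rnorm(8, 0, 0.1))
  for (pen in c(0.05, 0.5, 5)) {
    dp <- gazeway:::cpp_segment_dp(t, y, pen, 2L)
    bf <- brute_force_cost(t, y, pen)
    dp_cost <- sum(vapply(seq_along(dp$start), function(k) {
      a <- dp$start[k]; b <- dp$end[k]
      sse <- 0
      for (c in 1:2) {
        f <- stats::lm.fit(cbind(1, t[a:b]), y[a:b, c])
        sse <- sse + sum(f$residuals^2)
      }
      sse + pen
    }, numeric(1)))
    expect_equal(dp_cost, bf$cost, tolerance = 1e-8)
    expect_equal(dp$end, bf$ends)
  }
})

test_that("decreasing the penalty never decreases the segment count", {
  set.seed(43)
  sw <- make_sawtooth(rep(0.4, 8), noise = 0.3)
  counts <- vapply(c(100, 20, 5, 1, 0.2),
                   function(p) nrow(segment_trace(sw$t, sw$az, sw$el,
                                                  penalty = p)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("segments partition the trace without gaps or overlaps", {
  set.seed(47)
  sw <- make_sawtooth(rep(0.35, 10), jump = 3, noise = 0.5)
  cl <- classify_segments(segment_trace(sw$t, sw$az, sw$el))
  expect_true(all(cl$t_end > cl$t_start))
  expect_equal(cl$t_start[1], sw$t[1])
  expect_equal(cl$t_end[nrow(cl)], sw$t[length(sw$t)])
  expect_true(all(abs(cl$t_start[-1] - cl$t_end[-nrow(cl)]) < 1e-9))
})

test_that("classification applies the speed x duration rule table", {
  row <- function(speed, dur, n = max(2, round(dur * 60))) {
    data.frame(chunk = 1L, i_start = 1L, i_end = n, t_start = 0,
               t_end = dur, t_first = 0, t_last = dur, slope_az = speed,
               slope_el = 0, az_start = 0, az_end = speed * dur,
               el_start = 0, el_end = 0, mean_speed_deg_s = speed,
               duration_s = dur, n = n)
  }
  # classify one segment at a time so merging cannot collapse the table
  kind_of <- function(seg)
    classify_segments(seg, jump_threshold_deg = Inf)$kind
  expect_equal(kind_of(row(200, 0.02)), "saccade")   # fast and short
  expect_equal(kind_of(row(3, 0.4)), "tracking")     # slow and long
  expect_equal(kind_of(row(80, 0.4)), "tracking")    # fast but too long
  expect_equal(kind_of(row(3, 0.02)), "tracking")    # short but slow
})

test_that("saccade counts are recovered within ten percent across seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    durations <- pmax(0.1, rnorm(30, 0.37, 0.05))
    sw <- make_sawtooth(durations, jump = rnorm(1, 3, 0.3), noise = 0.5)
    cl <- classify_segments(segment_trace(sw$t, sw$az, sw$el))
    sum(cl$kind == "saccade") - (length(durations) - 1)
  }, numeric(1))
  expect_lt(abs(mean(errs)) / 29, 0.10)
})

test_that("bend-restricted tracking durations recover the generator median", {
  s <- sim_trial(seed = 1)
  bend <- c(5, 5 + pi * 25 / 8)
  durs <- c()
  # regular waypoint schedule (small headway spread) so that every
  # inter-episode saccade is large enough to resolve at this noise level
  cfg <- synth_config(angular_noise_deg = 0.5, noise_frac = 0,
                      tracking_dur_sd_s = 0.05, gf_sd_s = 0.05, seed = 1)
  for (k in 1:12) {
    set.seed(4000 + k)
    sim <- simulate_gaze(s$traj, s$midline, s$cam, cfg, mode = "Manual")
    th <- estimate_th(s$vehicle, sim$gaze, s$midline, s$cam, s$window)
    seqr <- sequence_all_trials(th, s$cam, bend)
    durs <- c(durs, seqr$tracking$duration_s)
  }
  expect_equal(median(durs), 0.35, tolerance = 0.02 / 0.35)
})

test_that("launch and land headways recover a deterministic jump schedule", {
  # waypoints held at 2.0 s headway, tracked for 0.6 s: every forward
  # saccade launches from 1.7 s and lands at 2.3 s
  s <- sim_trial(seed = 1)
  cfg <- synth_config(gf_mean_th_s = 2, gf_sd_s = 0.02,
                      tracking_dur_mean_s = 0.6, tracking_dur_sd_s = 0.01,
                      ef_episode_prob = 0, noise_frac = 0,
                      angular_noise_deg = 0.5, seed = 1)
  bend <- c(5, 5 + pi * 25 / 8)
  ev <- list()
  for (k in 1:8) {
    set.seed(5000 + k)
    sim <- simulate_gaze(s$traj, s$midline, s$cam, cfg, mode = "Manual")
    th <- estimate_th(s$vehicle, sim$gaze, s$midline, s$cam, s$window)
    seqr <- sequence_all_trials(th, s$cam, bend)
    ev[[k]] <- seqr$events
  }
  ev <- do.call(rbind, ev)
  fwd <- ev[ev$forward, ]
  expect_equal(median(fwd$launch_th_s), 1.7, tolerance = 0.05 / 1.7)
  expect_equal(median(fwd$land_th_s), 2.3, tolerance = 0.05 / 2.3)
  # definitional: forward events have launch <= land
  expect_true(all(fwd$launch_th_s <= fwd$land_th_s))
})

test_that("saccades with an excluded boundary are dropped from the stats", {
  s <- sim_trial_th(seed = 9, angular_noise_deg = 0.5, noise_frac = 0)
  bend <- c(5, 5 + pi * 25 / 8)
  seqr <- sequence_all_trials(s$th, s$cam, bend)
  n0 <- nrow(seqr$events)
  expect_gt(n0, 0)
  # exclude the headway samples around one detected saccade boundary
  th2 <- s$th
  sac_t <- seqr$events$t_start[1]
  th2$excluded[abs(th2$t - sac_t) <= 2 / 60] <- TRUE
  ang <- screen_to_angles(s$cam, th2$screen_x, th2$screen_y)
  segs <- classify_segments(segment_trace(th2$t, ang$azimuth_deg,
                                          ang$elevation_deg))
  st <- saccade_th_stats(segs, th2, bend)
  expect_lt(nrow(st$events), n0 + 1)  # never gains events
  # directly: an event whose boundary has no included headway is absent
  has_near <- vapply(st$events$t_start, function(tt)
    abs(tt - sac_t) < 1 / 120, logical(1))
  expect_false(any(has_near))
})
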