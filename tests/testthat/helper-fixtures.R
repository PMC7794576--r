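# Shared small fixtures, built in code at test time.

default_track <- function() track_config()

default_midline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_midline(track_config())
    cache
  }
})

# One simulated trial (trajectory + gaze) under a given config; returns the
# pieces most tests need.
sim_trial <- function(seed = 1, mode = "Manual", cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- synth_config(seed = seed, ...)
  track <- track_config()
  ml <- default_midline()
  cam <- camera_model()
  win <- default_trial_window(track, mode = mode)
  traj <- simulate_trajectory(ml, win)
  set.seed(seed)
  sim <- simulate_gaze(traj, ml, cam, cfg, mode = mode)
  veh <- cbind(data.frame(participant = 1L, mode = mode, trial = 1L),
               traj[, c("t", "x", "z", "yaw")])
  list(track = track, midline = ml, cam = cam, window = win, traj = traj,
       vehicle = veh, gaze = sim$gaze, truth = sim$truth,
       events = sim$events, cfg = cfg)
}

# Trial plus its estimated headway table.
sim_trial_th <- function(seed = 1, mode = "Manual", cfg = NULL, ...) {
  s <- sim_trial(seed = seed, mode = mode, cfg = cfg, ...)
  s$th <- estimate_th(s$vehicle, s$gaze, s$midline, s$cam, s$window)
  s
}

# Draw a two-cluster mixture sample with known ground truth directly in
# (time-into-trial, headway) coordinates (no projection involved): component
# membership is independent of x, guiding fixations i.i.d. around mu_gf,
# entry fixations on the slope -1 line y = c_ef - x.
sim_mixture_data <- function(n = 2000, w = c(0.6, 0.3, 0.1), mu_gf = 2,
                             sigma_gf = 0.3, c_ef = 30, sigma_ef = 0.2,
                             x_range = c(0, 15), noise_max = 8, seed = 1) {
  set.seed(seed)
  comp <- sample(c("gf", "ef", "noise"), n, replace = TRUE, prob = w)
  x <- runif(n, x_range[1], x_range[2])
  y <- numeric(n)
  y[comp == "gf"] <- rnorm(sum(comp == "gf"), mu_gf, sigma_gf)
  y[comp == "ef"] <- c_ef - x[comp == "ef"] +
    rnorm(sum(comp == "ef"), 0, sigma_ef)
  y[comp == "noise"] <- runif(sum(comp == "noise"), 0, noise_max)
  list(x = x, y = y, comp = comp)
}
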