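#' Synthetic gaze generator configuration
#'
#' Parameters of the generative sawtooth model: drivers saccade to a waypoint
#' on the midline, track it (so its headway decays at slope -1), then saccade
#' on. During the bend approach, episodes may instead target a fixed attractor
#' point just past the bend entry (entry fixations). A fraction of samples is
#' replaced by off-task noise, and all gaze is passed through the camera with
#' additive angular measurement noise.
#'
#' @param gf_mean_th_s,gf_sd_s Mean and SD of the guiding-fixation waypoint
#'   headway draw, seconds.
#' @param tracking_dur_mean_s,tracking_dur_sd_s Tracking-episode duration
#'   distribution, seconds (truncated positive).
#' @param ef_point_offset_s Attractor location past the bend entry, seconds
#'   along the midline.
#' @param ef_onset_lead_s How early (time-to-attractor) entry-fixation
#'   episodes may begin, seconds.
#' @param ef_episode_prob Probability that a new episode during the approach
#'   targets the attractor.
#' @param noise_frac Fraction of samples replaced by off-task noise.
#' @param angular_noise_deg SD of the angular measurement noise, degrees.
#' @param mode_shift_s Named additive shift of the waypoint headway mean per
#'   driving mode, seconds.
#' @param saccade_dur_s Saccade duration, seconds.
#' @param participant_sd_s SD of the participant-level random offset on the
#'   waypoint headway mean, seconds.
#' @param n_trials Trials per participant and mode.
#' @param n_participants Number of participants.
#' @param seed Integer seed; mandatory for dataset generation.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(gf_mean_th_s = 2.0, gf_sd_s = 0.3,
                         tracking_dur_mean_s = 0.35,
                         tracking_dur_sd_s = 0.08,
                         ef_point_offset_s = 1.0, ef_onset_lead_s = 3.5,
                         ef_episode_prob = 0.4, noise_frac = 0.05,
                         angular_noise_deg = 1.5,
                         mode_shift_s = c("Manual" = 0, "Auto-Replay" = 0.17,
                                          "Auto-Stock" = 0.22),
                         saccade_dur_s = 2 / 60,
                         participant_sd_s = 0.15,
                         n_trials = 6, n_participants = 11, seed = 1) {
  stopifnot(gf_sd_s > 0, tracking_dur_sd_s > 0,
            ef_episode_prob >= 0, ef_episode_prob <= 1,
            noise_frac >= 0, noise_frac <= 1,
            angular_noise_deg >= 0, saccade_dur_s >= 0,
            n_trials >= 0, n_participants >= 1)
  if (is.null(seed) || !is.finite(seed))
    stop("synth_config: an integer seed is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

#' Simulate a constant-speed vehicle trajectory
#'
#' 60 Hz vehicle states advancing along the midline at the configured speed,
#' with yaw from the midline tangent.
#'
#' @param midline A [build_midline()] result.
#' @param window A [trial_window()] (or a list with `start_arc_m`,
#'   `end_arc_m`).
#' @param hz Sampling rate.
#' @return Data frame `t`, `x`, `z`, `yaw`, `arc_m`, `time_into_trial_s`.
#' @export
simulate_trajectory <- function(midline, window, hz = 60) {
  speed <- midline$cfg$speed_mps
  len <- window$end_arc_m - window$start_arc_m
  n <- floor(len * hz / speed) + 1L
  if (len <= 0) n <- 0L
  if (n <= 0)
    return(data.frame(t = numeric(0), x = numeric(0), z = numeric(0),
                      yaw = numeric(0), arc_m = numeric(0),
                      time_into_trial_s = numeric(0)))
  arc <- window$start_arc_m + speed * (seq_len(n) - 1L) / hz
  pts <- arc_to_world(midline, arc)
  data.frame(t = (seq_len(n) - 1L) / hz, x = pts[, "x"], z = pts[, "z"],
             yaw = arc_to_heading(midline, arc), arc_m = arc,
             time_into_trial_s = (arc - window$start_arc_m) / speed)
}

#' Simulate a gaze trace for one trial
#'
#' Generative sawtooth process with full ground truth. Each episode draws a
#' waypoint headway `w ~ Normal(gf_mean + shift, gf_sd)` truncated to
#' `(0.5, 6)` s and fixates the world point whose headway at saccade landing
#' is `w + dur/2`, so that tracked headway decays at slope -1 through `w` and
#' the emitted headway marginal is centred on the drawn value. During the
#' approach (time-to-attractor within `ef_onset_lead_s`), a new episode
#' becomes an entry fixation with probability `ef_episode_prob`, targeting
#' the fixed attractor point past the bend entry. Saccades are linear
#' screen-space interpolations over `saccade_dur_s`. Gaze is emitted through
#' the camera with additive Gaussian angular noise, and `noise_frac` of
#' samples are replaced by uniform off-task positions with uniform
#' confidence.
#'
#' @param traj From [simulate_trajectory()].
#' @param midline,cam Track midline and camera.
#' @param cfg A [synth_config()].
#' @param mode Driving-mode label (selects the headway shift).
#' @param gf_offset_s Additional participant-level shift, seconds.
#' @param attractor_arc_m Attractor arc position; defaults to the bend entry
#'   plus `ef_point_offset_s` at track speed.
#' @return List: `gaze` (`t`, `screen_x`, `screen_y`, `confidence`), `truth`
#'   (`t`, `label` in GF/EF/noise, `episode`, `target_arc_m`), `events`
#'   (per-episode kind, target, saccade/tracking boundaries, true duration).
#' @export
simulate_gaze <- function(traj, midline, cam, cfg, mode = "Manual",
                          gf_offset_s = 0, attractor_arc_m = NULL) {
  n <- nrow(traj)
  if (n == 0)
    return(list(gaze = data.frame(t = numeric(0), screen_x = numeric(0),
                                  screen_y = numeric(0),
                                  confidence = numeric(0)),
                truth = data.frame(t = numeric(0), label = character(0),
                                   episode = integer(0),
                                   target_arc_m = numeric(0)),
                events = NULL))
  speed <- midline$cfg$speed_mps
  hz <- 1 / (traj$t[2] - traj$t[1])
  if (is.null(attractor_arc_m))
    attractor_arc_m <- midline$cfg$straight_length_m +
      cfg$ef_point_offset_s * speed
  shift <- gf_offset_s + unname(cfg$mode_shift_s[mode])
  if (is.na(shift)) stop("simulate_gaze: unknown mode '", mode, "'",
                         call. = FALSE)
  n_sacc <- round(cfg$saccade_dur_s * hz)

  sx <- numeric(n); sy <- numeric(n)
  label <- character(n); episode <- integer(n); target <- numeric(n)
  events <- list()
  # projection of one fixed world point across a block of vehicle frames
  proj_at <- function(frames, arc) {
    p <- arc_to_world(midline, arc)
    dx <- p[1, 1] - traj$x[frames]; dz <- p[1, 2] - traj$z[frames]
    yaw <- traj$yaw[frames]
    fwd <- dx * cos(yaw) + dz * sin(yaw)
    lat <- dx * sin(yaw) - dz * cos(yaw)
    fwd[fwd <= 1e-9] <- NA_real_
    list(screen_x = 0.5 + (lat / fwd) / (2 * cam$tan_h),
         screen_y = 0.5 + (-cam$eye_height_m / fwd) / (2 * cam$tan_v))
  }
  i <- 1L; ep <- 0L; prev_arc <- NA_real_
  while (i <= n) {
    ep <- ep + 1L
    tta <- (attractor_arc_m - traj$arc_m[i]) / speed
    is_ef <- tta > 0 && tta <= cfg$ef_onset_lead_s &&
      runif(1) < cfg$ef_episode_prob
    dur <- rtrunc_norm(1, cfg$tracking_dur_mean_s, cfg$tracking_dur_sd_s,
                       lower = 0.05)
    k_sacc <- if (ep == 1L) 0L else n_sacc
    land <- min(i + k_sacc, n)
    if (is_ef) {
      target_arc <- attractor_arc_m
    } else {
      w <- rtrunc_norm(1, cfg$gf_mean_th_s + shift, cfg$gf_sd_s,
                       lower = 0.5, upper = 6)
      target_arc <- traj$arc_m[land] + (w + dur / 2) * speed
    }
    kind <- if (is_ef) "EF" else "GF"
    # saccade: linear screen interpolation from the previous target's
    # current projection to the new target's current projection
    if (k_sacc > 0) {
      frames <- i:min(i + k_sacc - 1L, n)
      a <- proj_at(frames, prev_arc); b <- proj_at(frames, target_arc)
      f <- seq_along(frames) / (k_sacc + 1)
      sx[frames] <- (1 - f) * a$screen_x + f * b$screen_x
      sy[frames] <- (1 - f) * a$screen_y + f * b$screen_y
      label[frames] <- kind; episode[frames] <- ep
      target[frames] <- target_arc
    }
    # tracking: gaze on the fixed world point until the drawn duration ends,
    # the vehicle all but reaches the point, or the point leaves the display
    n_track <- max(1L, round(dur * hz))
    frames <- land:min(land + n_track - 1L, n)
    frames <- frames[(target_arc - traj$arc_m[frames]) / speed > 0.1]
    if (!length(frames)) frames <- land  # degenerate: point all but reached
    p <- proj_at(frames, target_arc)
    off <- which(is.na(p$screen_x) | p$screen_x < 0 | p$screen_x > 1 |
                   p$screen_y < 0 | p$screen_y > 1)
    if (length(off) && off[1] > 1) {
      frames <- frames[seq_len(off[1] - 1L)]
      p <- lapply(p, `[`, seq_len(off[1] - 1L))
    }
    sx[frames] <- p$screen_x; sy[frames] <- p$screen_y
    label[frames] <- kind; episode[frames] <- ep; target[frames] <- target_arc
    j <- frames[length(frames)] + 1L
    events[[ep]] <- data.frame(episode = ep, kind = kind,
                               target_arc_m = target_arc,
                               t_sacc_start = traj$t[i],
                               t_track_start = traj$t[land],
                               t_track_end = traj$t[min(j - 1L, n)],
                               duration_s = (min(j - 1L, n) - land + 1L) / hz)
    prev_arc <- target_arc
    i <- j
  }

  # angular measurement noise, exact in azimuth/elevation
  if (cfg$angular_noise_deg > 0) {
    nr <- cfg$angular_noise_deg * pi / 180
    X <- (sx - 0.5) * 2 * cam$tan_h
    Y <- (sy - 0.5) * 2 * cam$tan_v
    X <- tan(atan(X) + rnorm(n, 0, nr))
    Y <- tan(atan(Y) + rnorm(n, 0, nr))
    sx <- 0.5 + X / (2 * cam$tan_h)
    sy <- 0.5 + Y / (2 * cam$tan_v)
  }
  confidence <- runif(n, 0.7, 1)
  # off-task noise replacement
  noise_idx <- which(runif(n) < cfg$noise_frac)
  if (length(noise_idx)) {
    sx[noise_idx] <- runif(length(noise_idx))
    sy[noise_idx] <- runif(length(noise_idx))
    confidence[noise_idx] <- runif(length(noise_idx))
    label[noise_idx] <- "noise"
    episode[noise_idx] <- NA_integer_
    target[noise_idx] <- NA_real_
  }
  list(gaze = data.frame(t = traj$t, screen_x = sx, screen_y = sy,
                         confidence = confidence),
       truth = data.frame(t = traj$t, label = label, episode = episode,
                          target_arc_m = target),
       events = do.call(rbind, events))
}

derive_seed <- function(seed, p = 0L, m = 0L, trial = 0L) {
  (((as.numeric(seed) %% 100000) * 1000003 + p * 10007 + m * 101 + trial) %%
     2147483647) + 1
}

#' Simulate a full multi-participant dataset
#'
#' `n_participants x 3 modes x n_trials` trials over the default analysis
#' window (approach straight plus bend). Participant-level offsets on the
#' waypoint headway mean are drawn `Normal(0, participant_sd_s)`. One RNG
#' stream per trial is derived from `(seed, participant, mode, trial)` so the
#' dataset is reproducible under partial regeneration.
#'
#' @param cfg A [synth_config()].
#' @param track A [track_config()].
#' @param cam A [camera_model()].
#' @return List: `vehicle`, `gaze`, `truth`, `events` (labelled data frames
#'   over all trials), `participant_offsets`, plus the `midline`, `cam`,
#'   `cfg`, `track` and the per-mode `windows` used.
#' @export
simulate_dataset <- function(cfg = synth_config(), track = track_config(),
                             cam = camera_model()) {
  midline <- build_midline(track)
  set.seed(derive_seed(cfg$seed))
  offsets <- rnorm(cfg$n_participants, 0, cfg$participant_sd_s)
  veh <- list(); gz <- list(); tr <- list(); ev <- list()
  for (p in seq_len(cfg$n_participants)) {
    for (mi in seq_along(MODE_LEVELS)) {
      mode <- MODE_LEVELS[mi]
      for (trial in seq_len(cfg$n_trials)) {
        set.seed(derive_seed(cfg$seed, p, mi, trial))
        window <- default_trial_window(track, participant = p, trial = trial,
                                       mode = mode)
        traj <- simulate_trajectory(midline, window)
        sim <- simulate_gaze(traj, midline, cam, cfg, mode = mode,
                             gf_offset_s = offsets[p])
        lab <- data.frame(participant = p, mode = mode, trial = trial)
        veh[[length(veh) + 1]] <- cbind(lab,
                                        traj[, c("t", "x", "z", "yaw")],
                                        row.names = NULL)
        gz[[length(gz) + 1]] <- cbind(lab, sim$gaze, row.names = NULL)
        tr[[length(tr) + 1]] <- cbind(lab, sim$truth, row.names = NULL)
        if (!is.null(sim$events))
          ev[[length(ev) + 1]] <- cbind(lab, sim$events, row.names = NULL)
      }
    }
  }
  list(vehicle = do.call(rbind, veh), gaze = do.call(rbind, gz),
       truth = do.call(rbind, tr), events = do.call(rbind, ev),
       participant_offsets = offsets, midline = midline, cam = cam,
       cfg = cfg, track = track)
}

#' Write a simulated dataset as plain-text logs
#'
#' One vehicle and one gaze CSV per trial (the formats [read_vehicle_log()]
#' and [read_gaze_log()] read back), plus a pooled ground-truth CSV.
#'
#' @param ds From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key <- unique(ds$vehicle[, c("participant", "mode", "trial")])
  for (i in seq_len(nrow(key))) {
    p <- key$participant[i]; m <- key$mode[i]; trial <- key$trial[i]
    tag <- sprintf("p%02d_%s_t%02d", p, gsub("[^A-Za-z]", "", m), trial)
    sel <- ds$vehicle$participant == p & ds$vehicle$mode == m &
      ds$vehicle$trial == trial
    write.csv(ds$vehicle[sel, ], file.path(dir, paste0("vehicle_", tag,
                                                       ".csv")),
              row.names = FALSE)
    sel <- ds$gaze$participant == p & ds$gaze$mode == m &
      ds$gaze$trial == trial
    write.csv(ds$gaze[sel, c("t", "screen_x", "screen_y", "confidence")],
              file.path(dir, paste0("gaze_", tag, ".csv")),
              row.names = FALSE)
  }
  write.csv(ds$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
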