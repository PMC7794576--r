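#' Segment a gaze-angle trace by penalised segmented regression
#'
#' Parses a uniformly sampled two-channel gaze signal (azimuth and elevation,
#' degrees) into piecewise-linear segments by exact dynamic-programming
#' minimisation of total squared residual plus `penalty` per segment. Gaps of
#' more than `max_gap_frames` frames split the trace into independently
#' segmented chunks; chunks shorter than `min_frames` yield no segments.
#'
#' @param t Sample times, seconds (nominally 60 Hz).
#' @param azimuth_deg,elevation_deg Gaze angles, degrees; samples with `NA`
#'   in either channel are treated as gaps.
#' @param penalty Cost per additional segment, squared degrees. The default
#'   is calibrated so that a constant trace with 0.5 degree angular noise is
#'   returned as a single segment.
#' @param min_frames Minimum trace length to attempt segmentation.
#' @param min_seg_frames Minimum samples per segment (2: a line needs two
#'   points).
#' @param max_gap_frames Gap length (in frames) above which the trace is
#'   split.
#' @param hz Nominal sampling rate, used to convert the gap rule to seconds.
#' @return Data frame of segments: `chunk`, `i_start`, `i_end` (indices into
#'   the input), `t_start`, `t_end` (segment boundaries; adjacent segments
#'   share endpoints at the midpoint between samples), `slope_az`, `slope_el`
#'   (deg/s), `mean_speed_deg_s`, `duration_s`, `n`.
#' @export
segment_trace <- function(t, azimuth_deg, elevation_deg,
                          penalty = default_segment_penalty(),
                          min_frames = 5, min_seg_frames = 2,
                          max_gap_frames = 3, hz = 60) {
  ok <- is.finite(t) & is.finite(azimuth_deg) & is.finite(elevation_deg)
  idx <- which(ok)
  if (length(idx) < min_frames) return(empty_segments())
  # split into chunks at temporal gaps
  dt <- diff(t[idx])
  brk <- which(dt > max_gap_frames / hz + 1e-9)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  out <- list()
  for (ci in seq_along(starts)) {
    sel <- idx[starts[ci]:ends[ci]]
    if (length(sel) < min_frames) next
    dp <- cpp_segment_dp(t[sel], cbind(azimuth_deg[sel], elevation_deg[sel]),
                         penalty, as.integer(min_seg_frames))
    if (length(dp$start) == 0) next
    segs <- summarise_segments(t, azimuth_deg, elevation_deg, sel,
                               dp$start, dp$end, ci)
    out[[length(out) + 1]] <- segs
  }
  if (!length(out)) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

summarise_segments <- function(t, az, el, sel, start, end, chunk) {
  n_seg <- length(start)
  rows <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    i <- sel[start[k]:end[k]]
    tt <- t[i]
    fit_az <- stats::lm.fit(cbind(1, tt - tt[1]), az[i])$coefficients
    fit_el <- stats::lm.fit(cbind(1, tt - tt[1]), el[i])$coefficients
    s_az <- unname(fit_az[2]); s_el <- unname(fit_el[2])
    span <- tt[length(tt)] - tt[1]
    # boundary at the midpoint between the last sample of this segment and
    # the first of the next, so adjacent segments share endpoints
    t0 <- if (k == 1) t[i[1]] else (t[i[1]] + t[sel[end[k - 1]]]) / 2
    t1 <- if (k == n_seg) t[i[length(i)]] else
      (t[i[length(i)]] + t[sel[start[k + 1]]]) / 2
    rows[[k]] <- data.frame(chunk = chunk, i_start = i[1],
                            i_end = i[length(i)],
                            t_start = t0, t_end = t1,
                            t_first = tt[1], t_last = tt[length(tt)],
                            slope_az = s_az, slope_el = s_el,
                            az_start = unname(fit_az[1]),
                            az_end = unname(fit_az[1]) + s_az * span,
                            el_start = unname(fit_el[1]),
                            el_end = unname(fit_el[1]) + s_el * span,
                            mean_speed_deg_s = sqrt(s_az^2 + s_el^2),
                            duration_s = t1 - t0, n = length(i))
  }
  do.call(rbind, rows)
}

empty_segments <- function() {
  data.frame(chunk = integer(0), i_start = integer(0), i_end = integer(0),
             t_start = numeric(0), t_end = numeric(0), t_first = numeric(0),
             t_last = numeric(0), slope_az = numeric(0),
             slope_el = numeric(0), az_start = numeric(0),
             az_end = numeric(0), el_start = numeric(0), el_end = numeric(0),
             mean_speed_deg_s = numeric(0), duration_s = numeric(0),
             n = integer(0))
}

#' Default segmentation penalty
#'
#' Cost (squared degrees) per additional segment. Calibrated so that a 60 Hz
#' constant trace with 0.5 degree Gaussian angular noise is returned as one
#' segment while 2-frame saccades of ordinary amplitude (> 1 degree) are
#' still split out.
#'
#' @export
default_segment_penalty <- function() 5

#' Classify segments as tracking or saccades
#'
#' A segment is a saccade iff its mean angular speed exceeds
#' `speed_threshold_deg_s` *and* its duration is at most `max_saccade_dur_s`
#' (fast-but-long smooth drifts remain tracking); everything else, pursuits
#' and fixations alike, is tracking.
#'
#' Because the piecewise fit permits discontinuities, a saccade that is too
#' brief or too small to be isolated as its own segment still shows up as a
#' jump in the fitted gaze position at the boundary between two tracking
#' segments: gaze cannot move discontinuously, so a fitted discontinuity
#' larger than `jump_threshold_deg` is itself evidence of a saccade faster
#' than one sample. Such boundaries get a one-frame saccade segment inserted.
#' Finally, consecutive segments of the same kind are merged (speeds
#' combined duration-weighted).
#'
#' @param segments From [segment_trace()].
#' @param speed_threshold_deg_s Saccade speed threshold, deg/s.
#' @param max_saccade_dur_s Maximum saccade duration, seconds.
#' @param jump_threshold_deg Fitted-position discontinuity (visual angle)
#'   above which a boundary between tracking segments is marked as a
#'   saccade. Must exceed the fit uncertainty at segment ends (about
#'   `2 * noise / sqrt(n)` per channel) and stay below the smallest saccade
#'   of interest.
#' @return Segments with a `kind` column, jump saccades inserted, merged.
#' @export
classify_segments <- function(segments, speed_threshold_deg_s = 40,
                              max_saccade_dur_s = 0.12,
                              jump_threshold_deg = 1) {
  if (nrow(segments) == 0) {
    segments$kind <- character(0)
    return(segments)
  }
  segments$kind <- ifelse(
    segments$mean_speed_deg_s > speed_threshold_deg_s &
      segments$duration_s <= max_saccade_dur_s,
    "saccade", "tracking")
  segments <- insert_jump_saccades(segments, jump_threshold_deg)
  merge_segments(segments)
}

insert_jump_saccades <- function(segments, jump_threshold_deg) {
  out <- list()
  n <- nrow(segments)
  for (k in seq_len(n)) {
    s <- segments[k, , drop = FALSE]
    out[[length(out) + 1]] <- s
    if (k == n) break
    nx <- segments[k + 1, , drop = FALSE]
    if (s$chunk != nx$chunk) next
    if (s$kind != "tracking" || nx$kind != "tracking") next
    jump <- sqrt((nx$az_start - s$az_end)^2 + (nx$el_start - s$el_end)^2)
    if (jump <= jump_threshold_deg) next
    dt <- nx$t_first - s$t_last
    sac <- s
    sac$i_start <- s$i_end; sac$i_end <- nx$i_start
    sac$t_start <- s$t_last; sac$t_end <- nx$t_first
    sac$t_first <- s$t_last; sac$t_last <- nx$t_first
    sac$slope_az <- (nx$az_start - s$az_end) / dt
    sac$slope_el <- (nx$el_start - s$el_end) / dt
    sac$az_start <- s$az_end; sac$az_end <- nx$az_start
    sac$el_start <- s$el_end; sac$el_end <- nx$el_start
    sac$mean_speed_deg_s <- jump / dt
    sac$duration_s <- dt
    sac$n <- 2L
    sac$kind <- "saccade"
    # trim the neighbours to their own sample spans so the partition holds
    out[[length(out)]]$t_end <- s$t_last
    out[[length(out)]]$duration_s <- s$t_last -
      out[[length(out)]]$t_start
    nx$t_start <- nx$t_first
    nx$duration_s <- nx$t_end - nx$t_start
    segments[k + 1, ] <- nx
    out[[length(out) + 1]] <- sac
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_segments <- function(segments) {
  run <- cumsum(c(TRUE, segments$kind[-1] != segments$kind[-nrow(segments)] |
                    segments$chunk[-1] != segments$chunk[-nrow(segments)]))
  rows <- lapply(split(seq_len(nrow(segments)), run), function(i) {
    s <- segments[i, , drop = FALSE]
    w <- s$duration_s / sum(s$duration_s)
    m <- nrow(s)
    data.frame(chunk = s$chunk[1], i_start = s$i_start[1],
               i_end = s$i_end[m],
               t_start = s$t_start[1], t_end = s$t_end[m],
               t_first = s$t_first[1], t_last = s$t_last[m],
               slope_az = sum(w * s$slope_az),
               slope_el = sum(w * s$slope_el),
               az_start = s$az_start[1], az_end = s$az_end[m],
               el_start = s$el_start[1], el_end = s$el_end[m],
               mean_speed_deg_s = sum(w * s$mean_speed_deg_s),
               duration_s = s$t_end[m] - s$t_start[1],
               n = sum(s$n), kind = s$kind[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Saccade launch/land headways and tracking durations on the bend
#'
#' Joins classified segments to the headway table by time. For each saccade
#' whose boundaries fall while the vehicle is on the bend, the launch and
#' land headways are taken from the nearest *included* headway samples within
#' `max_boundary_gap_frames` frames of each boundary; events with missing
#' headway at either boundary are dropped. Tracking durations are the lengths
#' of tracking segments between consecutive saccades in the same window.
#'
#' @param segments Classified segments (one trial).
#' @param th Headway table for the same trial.
#' @param bend_window_s Length-2 vector: time-into-trial span during which the
#'   vehicle is on the bend.
#' @param max_boundary_gap_frames Search radius for the boundary headway
#'   samples, frames.
#' @param hz Sampling rate.
#' @return List with `events` (data frame: `launch_th_s`, `land_th_s`,
#'   `forward`, `t_start`, `t_end`) and `tracking` (data frame:
#'   `duration_s`, `t_start`, `t_end`).
#' @export
saccade_th_stats <- function(segments, th, bend_window_s,
                             max_boundary_gap_frames = 2, hz = 60) {
  inc <- th[!th$excluded, , drop = FALSE]
  max_gap <- max_boundary_gap_frames / hz + 1e-9
  # launch headway comes from the last included sample at or before the
  # saccade starts, land headway from the first at or after it ends:
  # samples inside the saccade are neither launch nor land
  th_at <- function(tq, side = c("before", "after")) {
    side <- match.arg(side)
    if (nrow(inc) == 0) return(NA_real_)
    cand <- if (side == "before") which(inc$t <= tq + 1e-9) else
      which(inc$t >= tq - 1e-9)
    if (!length(cand)) return(NA_real_)
    j <- cand[which.min(abs(inc$t[cand] - tq))]
    if (abs(inc$t[j] - tq) <= max_gap) inc$th_s[j] else NA_real_
  }
  # vehicle time-into-trial at a clock time, from the full table
  tit_at <- function(tq) {
    j <- which.min(abs(th$t - tq))
    th$time_into_trial_s[j]
  }
  sac <- segments[segments$kind == "saccade", , drop = FALSE]
  trk <- segments[segments$kind == "tracking", , drop = FALSE]
  ev <- list()
  for (k in seq_len(nrow(sac))) {
    if (nrow(th) == 0) break
    tit0 <- tit_at(sac$t_start[k]); tit1 <- tit_at(sac$t_end[k])
    if (tit0 < bend_window_s[1] || tit1 > bend_window_s[2]) next
    launch <- th_at(sac$t_start[k], "before")
    land <- th_at(sac$t_end[k], "after")
    if (is.na(launch) || is.na(land)) next
    ev[[length(ev) + 1]] <- data.frame(launch_th_s = launch,
                                       land_th_s = land,
                                       forward = land > launch,
                                       t_start = sac$t_start[k],
                                       t_end = sac$t_end[k])
  }
  keep_trk <- logical(nrow(trk))
  for (k in seq_len(nrow(trk))) {
    if (nrow(th) == 0) break
    tit0 <- tit_at(trk$t_start[k]); tit1 <- tit_at(trk$t_end[k])
    keep_trk[k] <- tit0 >= bend_window_s[1] && tit1 <= bend_window_s[2]
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(launch_th_s = numeric(0), land_th_s = numeric(0),
               forward = logical(0), t_start = numeric(0),
               t_end = numeric(0))
  # duration from the sample count: n samples at 1/hz each; unlike the
  # segment's clock span this does not depend on where the inter-sample
  # boundary is drawn
  tracking <- data.frame(duration_s = trk$n[keep_trk] / hz,
                         t_start = trk$t_start[keep_trk],
                         t_end = trk$t_end[keep_trk])
  list(events = events, tracking = tracking)
}

#' Segment and classify every trial's gaze trace
#'
#' Convenience driver: converts each trial's gaze screen trace to visual
#' angles, segments, classifies and extracts bend-restricted saccade events
#' and tracking durations.
#'
#' @param th Headway table covering one or more trials (columns `participant`,
#'   `mode`, `trial`, `t`, `screen_x`, `screen_y`).
#' @param cam A [camera_model()].
#' @param bend_window_s Bend span in time-into-trial coordinates.
#' @param penalty,speed_threshold_deg_s,max_saccade_dur_s Passed to
#'   [segment_trace()] and [classify_segments()].
#' @return List of data frames `segments`, `events`, `tracking`, each
#'   labelled by participant, mode, trial.
#' @export
sequence_all_trials <- function(th, cam, bend_window_s,
                                penalty = default_segment_penalty(),
                                speed_threshold_deg_s = 40,
                                max_saccade_dur_s = 0.12,
                                jump_threshold_deg = 1) {
  groups <- split(th, list(th$participant, th$mode, th$trial), drop = TRUE)
  segs <- list(); evs <- list(); trks <- list()
  for (g in groups) {
    ang <- screen_to_angles(cam, g$screen_x, g$screen_y)
    # excluded samples are gaps for segmentation purposes
    ang[g$excluded, ] <- NA_real_
    s <- segment_trace(g$t, ang$azimuth_deg, ang$elevation_deg,
                       penalty = penalty)
    if (nrow(s) == 0) next
    s <- classify_segments(s, speed_threshold_deg_s, max_saccade_dur_s,
                           jump_threshold_deg)
    st <- saccade_th_stats(s, g, bend_window_s)
    lab <- data.frame(participant = g$participant[1], mode = g$mode[1],
                      trial = g$trial[1])
    segs[[length(segs) + 1]] <- cbind(lab, s, row.names = NULL)
    if (nrow(st$events))
      evs[[length(evs) + 1]] <- cbind(lab, st$events, row.names = NULL)
    if (nrow(st$tracking))
      trks[[length(trks) + 1]] <- cbind(lab, st$tracking, row.names = NULL)
  }
  list(segments = if (length(segs)) do.call(rbind, segs) else NULL,
       events = if (length(evs)) do.call(rbind, evs) else NULL,
       tracking = if (length(trks)) do.call(rbind, trks) else NULL)
}
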