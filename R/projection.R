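#' Default optical-marker screen regions
#'
#' Five square regions bordering the stimulus (four corners plus top centre)
#' standing in for the display's optical tracking markers; gaze landing on a
#' marker is excluded from analysis.
#'
#' @param side Side length of each square, as a fraction of screen height.
#' @return Data frame with columns `cx`, `cy`, `side`.
#' @export
default_marker_regions <- function(side = 0.05) {
  h <- side / 2
  data.frame(cx = c(h, 1 - h, h, 1 - h, 0.5),
             cy = c(h, h, 1 - h, 1 - h, 1 - h),
             side = side)
}

in_marker_region <- function(markers, sx, sy) {
  hit <- rep(FALSE, length(sx))
  for (i in seq_len(nrow(markers))) {
    half <- markers$side[i] / 2
    hit <- hit | (abs(sx - markers$cx[i]) <= half &
                  abs(sy - markers$cy[i]) <= half)
  }
  hit
}

#' Map one gaze sample to its midline reference
#'
#' Projects the midline points within the forward headway window through the
#' camera and returns the candidate minimising Euclidean screen distance to
#' the gaze point (the *gaze midline reference*), with ties broken toward the
#' smaller arc. Candidates behind the camera are dropped.
#'
#' @param cam A [camera_model()].
#' @param pos,yaw Vehicle ground position `(x, z)` and yaw (radians).
#' @param veh_arc_m Vehicle arc position along the midline, metres.
#' @param midline A [build_midline()] result.
#' @param gaze_xy Normalised gaze screen coordinates, length-2 numeric.
#' @param forward_window_s Headway search window `(min, max)` in seconds.
#' @return List with `ref_arc_m`, `angular_error_deg`, `ref_screen_x`,
#'   `ref_screen_y`; `ref_arc_m` is `NA` when no candidate is in front of the
#'   camera.
#' @export
gaze_to_midline_reference <- function(cam, pos, yaw, veh_arc_m, midline,
                                      gaze_xy, forward_window_s = c(0, 8)) {
  speed <- midline$cfg$speed_mps
  arcs <- veh_arc_m + seq(forward_window_s[1] * speed,
                          forward_window_s[2] * speed,
                          by = midline$spacing_m)
  scr <- world_to_screen(cam, pos, yaw, arc_to_world(midline, arcs))
  ok <- !scr$behind
  if (!any(ok))
    return(list(ref_arc_m = NA_real_, angular_error_deg = NA_real_,
                ref_screen_x = NA_real_, ref_screen_y = NA_real_))
  d2 <- (scr$screen_x - gaze_xy[1])^2 + (scr$screen_y - gaze_xy[2])^2
  d2[!ok] <- Inf
  j <- which.min(d2)   # first minimum = smaller arc on ties
  list(ref_arc_m = arcs[j] %% midline$total_arc_m,
       angular_error_deg = screen_angle_between(cam, gaze_xy[1], gaze_xy[2],
                                                scr$screen_x[j],
                                                scr$screen_y[j]),
       ref_screen_x = scr$screen_x[j], ref_screen_y = scr$screen_y[j])
}

#' Gaze time headway from a midline reference
#'
#' Time headway is the distance along the midline from the vehicle's own
#' midline point to the gaze midline reference, wrap-aware, divided by speed.
#' Lane-position offsets are ignored by construction.
#'
#' @param veh_arc_m Vehicle arc position, metres.
#' @param ref_arc_m Gaze midline reference arc position, metres.
#' @param speed_mps Travel speed, m/s.
#' @param total_arc_m Track perimeter, metres (for wrap-around).
#' @return Headway in seconds.
#' @export
compute_time_headway <- function(veh_arc_m, ref_arc_m, speed_mps,
                                 total_arc_m) {
  ((ref_arc_m - veh_arc_m) %% total_arc_m) / speed_mps
}

#' Apply the four gaze exclusion filters
#'
#' A sample is excluded when (1) pupil-detection confidence is below
#' `conf_threshold`, (2) gaze falls outside the display surface, (3) gaze is
#' more than `max_angle_deg` from its midline reference in any direction (or
#' no reference could be found), or (4) gaze falls on an optical marker.
#' Filters are applied in that order and the first matching reason is
#' recorded.
#'
#' @param df Data frame with columns `confidence`, `screen_x`, `screen_y`,
#'   `angular_error_deg`.
#' @param markers Marker regions, see [default_marker_regions()].
#' @param conf_threshold Minimum confidence for inclusion.
#' @param max_angle_deg Maximum allowed gaze-to-reference visual angle.
#' @return `df` with logical `excluded` and character `reason` columns added.
#' @export
apply_exclusions <- function(df, markers = default_marker_regions(),
                             conf_threshold = 0.6, max_angle_deg = 20) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  low <- df$confidence < conf_threshold
  off <- df$screen_x < 0 | df$screen_x > 1 |
         df$screen_y < 0 | df$screen_y > 1
  far <- is.na(df$angular_error_deg) | df$angular_error_deg > max_angle_deg
  mark <- in_marker_region(markers, df$screen_x, df$screen_y)
  reason[mark] <- "on_marker"
  reason[far] <- "far_from_midline"
  reason[off] <- "off_surface"
  reason[low] <- "low_confidence"
  df$excluded <- !is.na(reason)
  df$reason <- reason
  df
}

#' Estimate the gaze time headway signal for one trial
#'
#' Joins the vehicle and gaze streams by nearest timestamp, maps each gaze
#' sample onto the track midline in screen coordinates, converts the
#' along-midline distance to seconds, and applies the exclusion filters.
#'
#' @param vehicle Data frame with columns `t`, `x`, `z`, `yaw` and optionally
#'   `participant`, `mode`, `trial` labels.
#' @param gaze Data frame with columns `t`, `screen_x`, `screen_y`,
#'   `confidence`.
#' @param midline A [build_midline()] result.
#' @param cam A [camera_model()].
#' @param window A [trial_window()] giving the trial's arc extent (time into
#'   trial is measured from its start).
#' @param markers Marker regions for the exclusion filters.
#' @param forward_window_s Headway search window `(min, max)`, seconds.
#' @param max_join_gap_s Maximum vehicle/gaze timestamp mismatch; samples
#'   without a vehicle frame within this gap are dropped.
#' @inheritParams apply_exclusions
#' @return Tidy headway table: one row per gaze sample with `participant`,
#'   `mode`, `trial`, `t`, `time_into_trial_s`, `th_s`, `ref_arc_m`,
#'   `angular_error_deg`, `screen_x`, `screen_y`, `confidence`, `excluded`,
#'   `reason`.
#' @export
estimate_th <- function(vehicle, gaze, midline, cam, window,
                        markers = default_marker_regions(),
                        forward_window_s = c(0, 8),
                        max_join_gap_s = 1 / 120,
                        conf_threshold = 0.6, max_angle_deg = 20) {
  stopifnot(inherits(midline, "midline"), inherits(cam, "camera_model"))
  if (nrow(gaze) == 0 || nrow(vehicle) == 0) return(empty_th_table())
  # nearest-timestamp join of gaze onto vehicle frames
  vi <- findInterval(gaze$t, vehicle$t, all.inside = FALSE)
  lo <- pmax(vi, 1L); hi <- pmin(vi + 1L, nrow(vehicle))
  pick <- ifelse(abs(gaze$t - vehicle$t[lo]) <= abs(gaze$t - vehicle$t[hi]),
                 lo, hi)
  gap <- abs(gaze$t - vehicle$t[pick])
  keep <- gap <= max_join_gap_s + 1e-12
  gaze <- gaze[keep, , drop = FALSE]
  pick <- pick[keep]
  if (nrow(gaze) == 0) return(empty_th_table())

  vx <- vehicle$x[pick]; vz <- vehicle$z[pick]; vyaw <- vehicle$yaw[pick]
  veh_arc <- world_to_arc(midline, vx, vz)
  m <- length(midline$x) - 1L
  veh_idx <- (round(veh_arc / midline$spacing_m) %% m) + 1L
  speed <- midline$cfg$speed_mps
  window_n <- ceiling(diff(forward_window_s) * speed / midline$spacing_m) + 1L

  refs <- cpp_gaze_midline_refs(vx, vz, vyaw, as.integer(veh_idx),
                                gaze$screen_x, gaze$screen_y,
                                midline$x[seq_len(m)], midline$z[seq_len(m)],
                                as.integer(window_n), cam$eye_height_m,
                                cam$tan_h, cam$tan_v)
  base_arc <- (veh_idx - 1L) * midline$spacing_m
  ref_arc <- (base_arc + refs$ref_offset * midline$spacing_m) %%
    midline$total_arc_m
  ref_arc[is.na(refs$ref_offset)] <- NA_real_
  # wrap the along-midline distance into (-total/2, total/2]; the vehicle's
  # own vertex can sit marginally behind the continuous vehicle arc
  delta <- (ref_arc - veh_arc) %% midline$total_arc_m
  delta[!is.na(delta) & delta > midline$total_arc_m / 2] <-
    delta[!is.na(delta) & delta > midline$total_arc_m / 2] -
    midline$total_arc_m
  th <- pmax(0, delta) / speed

  lab <- function(col, default) {
    if (!is.null(vehicle[[col]])) vehicle[[col]][pick] else default
  }
  out <- data.frame(participant = lab("participant", NA_integer_),
                    mode = lab("mode", NA_character_),
                    trial = lab("trial", NA_integer_),
                    t = gaze$t,
                    time_into_trial_s = (veh_arc - window$start_arc_m) / speed,
                    th_s = th,
                    ref_arc_m = ref_arc,
                    angular_error_deg = refs$angular_error_deg,
                    screen_x = gaze$screen_x, screen_y = gaze$screen_y,
                    confidence = gaze$confidence)
  apply_exclusions(out, markers = markers, conf_threshold = conf_threshold,
                   max_angle_deg = max_angle_deg)
}

empty_th_table <- function() {
  data.frame(participant = integer(0), mode = character(0), trial = integer(0),
             t = numeric(0), time_into_trial_s = numeric(0), th_s = numeric(0),
             ref_arc_m = numeric(0), angular_error_deg = numeric(0),
             screen_x = numeric(0), screen_y = numeric(0),
             confidence = numeric(0), excluded = logical(0),
             reason = character(0))
}

#' Read a vehicle-state log
#'
#' Plain-CSV reader with a configurable column mapping so deposited data
#' layouts with different column names can be adapted without rewriting.
#'
#' @param path CSV file path.
#' @param cols Named character vector mapping canonical names (`t`, `x`, `z`,
#'   `yaw`, `mode`, `trial`, `participant`) to the file's column names.
#' @return Data frame with canonical columns.
#' @export
read_vehicle_log <- function(path, cols = c(t = "t", x = "x", z = "z",
                                            yaw = "yaw", mode = "mode",
                                            trial = "trial",
                                            participant = "participant")) {
  raw <- read.csv(path)
  remap_columns(raw, cols)
}

#' Read a gaze-sample log
#'
#' @param path CSV file path.
#' @param cols Named character vector mapping canonical names (`t`,
#'   `screen_x`, `screen_y`, `confidence`) to the file's column names.
#' @return Data frame with canonical columns.
#' @export
read_gaze_log <- function(path, cols = c(t = "t", screen_x = "screen_x",
                                         screen_y = "screen_y",
                                         confidence = "confidence")) {
  raw <- read.csv(path)
  remap_columns(raw, cols)
}

remap_columns <- function(raw, cols) {
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop("missing columns in log file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- raw[, unname(cols), drop = FALSE]
  names(out) <- names(cols)
  out
}

#' Write a tidy headway table
#'
#' @param th Table from [estimate_th()].
#' @param path Output CSV path.
#' @export
write_th_table <- function(th, path) {
  write.csv(th, path, row.names = FALSE)
  invisible(path)
}
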