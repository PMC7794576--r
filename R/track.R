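#' Track configuration
#'
#' Describes the stadium-shaped (oval) test track: two parallel straights
#' joined by two semicircular bends, driven at constant speed. The midline --
#' the path equidistant to either road edge -- is the common reference for all
#' headway computations.
#'
#' @param straight_length_m Length of each straight, metres.
#' @param bend_radius_m Radius of each semicircular bend (measured to the
#'   midline), metres.
#' @param road_width_m Road width, metres (carried for plotting/validation;
#'   the midline itself does not depend on it).
#' @param speed_mps Constant travel speed, m/s. Time along the midline is
#'   arc length divided by this speed.
#' @param resolution_m Midline discretisation step, metres. Must be at most
#'   0.1 m so that the headway discretisation error stays below 0.0125 s at
#'   8 m/s.
#' @return An object of class `track_config`.
#' @export
track_config <- function(straight_length_m = 120, bend_radius_m = 25,
                         road_width_m = 3, speed_mps = 8,
                         resolution_m = 0.05) {
  vals <- c(bend_radius_m = bend_radius_m, road_width_m = road_width_m,
            speed_mps = speed_mps, resolution_m = resolution_m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("track_config: bend_radius_m, road_width_m, speed_mps and ",
         "resolution_m must all be strictly positive", call. = FALSE)
  if (!is.finite(straight_length_m) || straight_length_m < 0)
    stop("track_config: straight_length_m must be non-negative", call. = FALSE)
  if (resolution_m > 0.1)
    stop("track_config: resolution_m must be <= 0.1 m", call. = FALSE)
  structure(list(straight_length_m = straight_length_m,
                 bend_radius_m = bend_radius_m,
                 road_width_m = road_width_m,
                 speed_mps = speed_mps,
                 resolution_m = resolution_m),
            class = "track_config")
}

# Analytic stadium parameterisation. Origin at the start of the first
# straight, travel counter-clockwise in the (x, z) ground plane:
# straight A along +x at z = 0, bend A around (L, R), straight B along -x at
# z = 2R, bend B around (0, R). `s` may be any real; it is wrapped.
stadium_point <- function(s, L, R) {
  P <- 2 * L + 2 * pi * R
  s <- s %% P
  x <- numeric(length(s)); z <- numeric(length(s))
  i1 <- s < L
  x[i1] <- s[i1]; z[i1] <- 0
  i2 <- !i1 & s < L + pi * R
  phi <- (s[i2] - L) / R
  x[i2] <- L + R * sin(phi); z[i2] <- R - R * cos(phi)
  i3 <- !i1 & !i2 & s < 2 * L + pi * R
  x[i3] <- L - (s[i3] - L - pi * R); z[i3] <- 2 * R
  i4 <- !i1 & !i2 & !i3
  phi <- (s[i4] - 2 * L - pi * R) / R
  x[i4] <- -R * sin(phi); z[i4] <- R + R * cos(phi)
  cbind(x = x, z = z)
}

# Heading (yaw, radians, measured from +x toward +z) of the midline tangent
# at arc position s, from the same analytic parameterisation.
stadium_heading <- function(s, L, R) {
  P <- 2 * L + 2 * pi * R
  s <- s %% P
  h <- numeric(length(s))
  i1 <- s < L
  h[i1] <- 0
  i2 <- !i1 & s < L + pi * R
  h[i2] <- (s[i2] - L) / R
  i3 <- !i1 & !i2 & s < 2 * L + pi * R
  h[i3] <- pi
  i4 <- !i1 & !i2 & !i3
  h[i4] <- pi + (s[i4] - 2 * L - pi * R) / R
  h
}

#' Build the discretised track midline
#'
#' Samples the analytic stadium curve at (at most) `resolution_m` spacing into
#' an arc-length parameterised polyline. The vertex list is closed: the last
#' vertex coincides with the first, one full perimeter later.
#'
#' @param cfg A [track_config()].
#' @return An object of class `midline` with fields `x`, `z` (vertex
#'   coordinates), `arc_m` (cumulative arc length, strictly increasing),
#'   `time_s` (`arc_m / speed`), `total_arc_m`, `total_time_s`, `spacing_m`
#'   and the originating `cfg`.
#' @export
build_midline <- function(cfg) {
  stopifnot(inherits(cfg, "track_config"))
  L <- cfg$straight_length_m; R <- cfg$bend_radius_m
  total <- 2 * L + 2 * pi * R
  n <- ceiling(total / cfg$resolution_m)
  arc <- seq(0, total, length.out = n + 1)
  pts <- stadium_point(arc, L, R)
  structure(list(x = pts[, "x"], z = pts[, "z"],
                 arc_m = arc, time_s = arc / cfg$speed_mps,
                 total_arc_m = total, total_time_s = total / cfg$speed_mps,
                 spacing_m = total / n, cfg = cfg),
            class = "midline")
}

#' Map arc position to world coordinates
#'
#' Linear interpolation between bracketing midline vertices; arc positions
#' wrap modulo the total perimeter.
#'
#' @param midline A [build_midline()] result.
#' @param arc_m Numeric vector of arc positions, metres.
#' @return A two-column matrix of `(x, z)` world coordinates.
#' @export
arc_to_world <- function(midline, arc_m) {
  s <- arc_m %% midline$total_arc_m
  cbind(x = approx(midline$arc_m, midline$x, xout = s)$y,
        z = approx(midline$arc_m, midline$z, xout = s)$y)
}

#' Heading of the midline at an arc position
#'
#' @inheritParams arc_to_world
#' @return Yaw angles in radians (0 = +x, increasing toward +z).
#' @export
arc_to_heading <- function(midline, arc_m) {
  stadium_heading(arc_m, midline$cfg$straight_length_m,
                  midline$cfg$bend_radius_m)
}

#' Map world coordinates to arc position
#'
#' Finds the midline vertex nearest in Euclidean distance (ties broken toward
#' the smaller arc value) and refines by orthogonal projection onto the two
#' adjacent polyline segments.
#'
#' @param midline A [build_midline()] result.
#' @param x,z Numeric vectors of world coordinates.
#' @return Arc positions in metres, in `[0, total_arc_m)`.
#' @export
world_to_arc <- function(midline, x, z) {
  # drop the duplicated closing vertex so the nearest search is over the loop
  m <- length(midline$x) - 1L
  idx <- cpp_nearest_vertex(x, z, midline$x[seq_len(m)], midline$z[seq_len(m)])
  out <- numeric(length(x))
  total <- midline$total_arc_m
  for (i in seq_along(x)) {
    j <- idx[i]
    best <- refine_on_segment(midline, j, x[i], z[i])
    jm <- if (j == 1L) m else j - 1L        # segment arriving at vertex j
    prev <- refine_on_segment(midline, jm, x[i], z[i])
    # strict < keeps the smaller-arc candidate on ties
    out[i] <- if (prev$d2 < best$d2) prev$arc %% total else best$arc %% total
  }
  out
}

# Project (px, pz) onto the polyline segment starting at vertex j; returns
# the arc position of the foot point and its squared distance.
refine_on_segment <- function(midline, j, px, pz) {
  ax <- midline$x[j]; az <- midline$z[j]
  bx <- midline$x[j + 1L]; bz <- midline$z[j + 1L]
  vx <- bx - ax; vz <- bz - az
  len2 <- vx * vx + vz * vz
  t <- if (len2 > 0) max(0, min(1, ((px - ax) * vx + (pz - az) * vz) / len2)) else 0
  fx <- ax + t * vx; fz <- az + t * vz
  list(arc = midline$arc_m[j] + t * sqrt(len2),
       d2 = (px - fx)^2 + (pz - fz)^2)
}

#' Analysis trial window
#'
#' Delimits the analysed portion of a lap (an approach straight followed by a
#' bend) by arc position, with participant/trial/mode labels. Windows are
#' constructed inside one lap and never straddle the track origin.
#'
#' @param start_arc_m,end_arc_m Arc positions delimiting the window, metres.
#' @param participant,trial Integer labels.
#' @param mode Driving-mode label, one of `"Manual"`, `"Auto-Replay"`,
#'   `"Auto-Stock"`.
#' @param midline Optional [build_midline()] used to validate containment.
#' @return An object of class `trial_window`.
#' @export
trial_window <- function(start_arc_m, end_arc_m, participant = 1L, trial = 1L,
                         mode = "Manual", midline = NULL) {
  if (!is.finite(start_arc_m) || !is.finite(end_arc_m) ||
      end_arc_m <= start_arc_m)
    stop("trial_window: need end_arc_m > start_arc_m", call. = FALSE)
  if (!is.null(midline) &&
      (start_arc_m < 0 || end_arc_m > midline$total_arc_m))
    stop("trial_window: window must lie within one lap", call. = FALSE)
  if (!mode %in% MODE_LEVELS)
    stop("trial_window: unknown driving mode '", mode, "'", call. = FALSE)
  structure(list(start_arc_m = start_arc_m, end_arc_m = end_arc_m,
                 participant = as.integer(participant),
                 trial = as.integer(trial), mode = mode),
            class = "trial_window")
}

#' Default analysis window: approach straight plus first bend
#'
#' The analysed trial starts `approach_m` before the first bend entry and ends
#' at the bend exit, matching the convention that the straight after the bend
#' is excluded from analysis.
#'
#' @param cfg A [track_config()].
#' @param approach_m Length of the analysed approach straight, metres.
#' @inheritParams trial_window
#' @return A [trial_window()].
#' @export
default_trial_window <- function(cfg, approach_m = 40, participant = 1L,
                                 trial = 1L, mode = "Manual") {
  entry <- cfg$straight_length_m
  trial_window(entry - approach_m, entry + pi * cfg$bend_radius_m,
               participant = participant, trial = trial, mode = mode)
}

#' Arc position and time-into-trial of the bend entry
#'
#' @param cfg A [track_config()].
#' @param window A [trial_window()].
#' @return List with `arc_m` and `time_s` (seconds into the trial at which the
#'   vehicle crosses the bend entry).
#' @export
bend_entry <- function(cfg, window) {
  list(arc_m = cfg$straight_length_m,
       time_s = (cfg$straight_length_m - window$start_arc_m) / cfg$speed_mps)
}

#' Export the midline as a plain-text table
#'
#' @param midline A [build_midline()] result.
#' @param path Output file path (CSV with columns `arc_m`, `x`, `z`).
#' @export
write_midline <- function(midline, path) {
  write.csv(data.frame(arc_m = midline$arc_m, x = midline$x, z = midline$z),
            path, row.names = FALSE)
  invisible(path)
}
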