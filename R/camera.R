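#' Camera / display model
#'
#' Pinhole model of the simulator display. The eye sits `eye_height_m` above
#' the vehicle's ground position, looks horizontally along the vehicle yaw,
#' and the scene is projected onto a plane at `screen_distance_m` whose extent
#' is set by the horizontal and vertical fields of view. Screen coordinates
#' are normalised to `[0, 1] x [0, 1]` with the origin bottom-left.
#'
#' @param eye_height_m Eye height above the ground plane, metres.
#' @param screen_distance_m Eye-to-display distance, metres (the normalised
#'   projection depends only on the fields of view).
#' @param fov_h_deg,fov_v_deg Horizontal and vertical fields of view, degrees.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(eye_height_m = 1.2, screen_distance_m = 1.0,
                         fov_h_deg = 89, fov_v_deg = 58) {
  if (screen_distance_m <= 0)
    stop("camera_model: screen_distance_m must be positive", call. = FALSE)
  if (fov_h_deg <= 0 || fov_h_deg >= 180 || fov_v_deg <= 0 || fov_v_deg >= 180)
    stop("camera_model: fields of view must lie in (0, 180) degrees",
         call. = FALSE)
  structure(list(eye_height_m = eye_height_m,
                 screen_distance_m = screen_distance_m,
                 fov_h_deg = fov_h_deg, fov_v_deg = fov_v_deg,
                 tan_h = tan(fov_h_deg / 2 * pi / 180),
                 tan_v = tan(fov_v_deg / 2 * pi / 180)),
            class = "camera_model")
}

#' Project ground-plane points to screen coordinates
#'
#' Perspective projection of world points (on the ground plane) onto the
#' normalised screen, for a camera above `pos` oriented along `yaw`. Points
#' with non-positive forward depth are flagged `behind` and get `NA`
#' coordinates.
#'
#' @param cam A [camera_model()].
#' @param pos Vehicle ground position, numeric `(x, z)`.
#' @param yaw Vehicle yaw, radians (0 = +x, increasing toward +z).
#' @param points Two-column matrix of ground-plane `(x, z)` points.
#' @return Data frame with `screen_x`, `screen_y`, `behind`.
#' @export
world_to_screen <- function(cam, pos, yaw, points) {
  points <- matrix(points, ncol = 2)
  dx <- points[, 1] - pos[1]
  dz <- points[, 2] - pos[2]
  fwd <- dx * cos(yaw) + dz * sin(yaw)
  lat <- dx * sin(yaw) - dz * cos(yaw)    # rightward positive
  behind <- fwd <= 1e-9
  sx <- 0.5 + (lat / fwd) / (2 * cam$tan_h)
  sy <- 0.5 + (-cam$eye_height_m / fwd) / (2 * cam$tan_v)
  sx[behind] <- NA_real_; sy[behind] <- NA_real_
  data.frame(screen_x = sx, screen_y = sy, behind = behind)
}

#' Convert screen coordinates to gaze angles
#'
#' Maps normalised screen coordinates back onto the unit-distance projection
#' plane and returns the azimuth and elevation of the corresponding ray, in
#' degrees. Used to express gaze traces in visual-angle units for eye-movement
#' segmentation.
#'
#' @param cam A [camera_model()].
#' @param screen_x,screen_y Normalised screen coordinates.
#' @return Data frame with `azimuth_deg`, `elevation_deg`.
#' @export
screen_to_angles <- function(cam, screen_x, screen_y) {
  X <- (screen_x - 0.5) * 2 * cam$tan_h
  Y <- (screen_y - 0.5) * 2 * cam$tan_v
  data.frame(azimuth_deg = atan(X) * 180 / pi,
             elevation_deg = atan(Y) * 180 / pi)
}

#' Visual angle between two screen positions
#'
#' Angle between the rays through two normalised screen points, via the
#' camera model.
#'
#' @param cam A [camera_model()].
#' @param x1,y1,x2,y2 Normalised screen coordinates (vectorised).
#' @return Angles in degrees.
#' @export
screen_angle_between <- function(cam, x1, y1, x2, y2) {
  aX <- (x1 - 0.5) * 2 * cam$tan_h; aY <- (y1 - 0.5) * 2 * cam$tan_v
  bX <- (x2 - 0.5) * 2 * cam$tan_h; bY <- (y2 - 0.5) * 2 * cam$tan_v
  num <- aX * bX + aY * bY + 1
  den <- sqrt(aX^2 + aY^2 + 1) * sqrt(bX^2 + bY^2 + 1)
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}
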