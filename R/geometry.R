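#' Screen model
#'
#' Physical and pixel dimensions of the stimulus display, plus optional
#' prohibited zones: pixel rectangles in which stimuli must never be drawn
#' (e.g. degraded screen corners). Pixel coordinates have their origin at the
#' top-left corner, x rightward, y downward.
#'
#' @param width_cm,height_cm Physical panel size, cm.
#' @param width_px,height_px Panel resolution, pixels.
#' @param prohibited_zones List of rectangles, each
#'   `c(x0, y0, x1, y1)` in pixels with `x0 < x1`, `y0 < y1`. The default is
#'   a rectangle over each bottom corner (where tracking and display quality
#'   degrade); pass `list()` for none.
#' @return An object of class `screen_model`.
#' @export
screen_model <- function(width_cm = 59.7, height_cm = 33.6,
                         width_px = 2560, height_px = 1440,
                         prohibited_zones = NULL) {
  stopifnot(width_cm > 0, height_cm > 0, width_px > 0, height_px > 0)
  if (is.null(prohibited_zones))
    prohibited_zones <- list(
      c(0, 0.8 * height_px, 0.18 * width_px, height_px),
      c(0.82 * width_px, 0.8 * height_px, width_px, height_px))
  sx <- width_px / width_cm
  sy <- height_px / height_cm
  if (abs(sx - sy) / sx > 0.01)
    stop("anisotropic pixel pitch: px/cm must agree within 1% across axes")
  for (z in prohibited_zones) {
    stopifnot(length(z) == 4, z[1] < z[3], z[2] < z[4],
              z[1] >= 0, z[2] >= 0, z[3] <= width_px, z[4] <= height_px)
  }
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 width_px = width_px, height_px = height_px,
                 px_per_cm = c(x = sx, y = sy),
                 prohibited_zones = prohibited_zones),
            class = "screen_model")
}

#' Viewer state
#'
#' The observer's current viewing geometry: viewing distance (time-varying,
#' nominally 60 cm — the tracker focuses at roughly 50 to 70 cm), the current
#' fixation point on screen, and the tracker's trackable angular region
#' (half-extents; targets outside it cannot be classified).
#'
#' @param distance_cm Eye-to-screen distance along the screen normal, cm.
#' @param fixation_px Current gaze point, pixels `c(x, y)`.
#' @param trackbox_deg Half-extents of the trackable region, degrees
#'   `c(horizontal, vertical)`.
#' @param screen The [screen_model()] (used for the default central fixation).
#' @return An object of class `viewer_state`.
#' @export
viewer_state <- function(distance_cm = 60,
                         fixation_px = NULL,
                         trackbox_deg = c(27, 15),
                         screen = screen_model()) {
  stopifnot(distance_cm > 0, all(trackbox_deg > 0))
  if (is.null(fixation_px))
    fixation_px <- c(screen$width_px / 2, screen$height_px / 2)
  structure(list(distance_cm = distance_cm,
                 fixation_px = as.numeric(fixation_px),
                 trackbox_deg = as.numeric(trackbox_deg)),
            class = "viewer_state")
}

#' Angular extent of the screen at a viewing distance
#'
#' @param screen A [screen_model()].
#' @param distance_cm Viewing distance, cm (> 0).
#' @return `c(horizontal, vertical)` full visual angles in degrees,
#'   `2 atan(size / 2d)` per axis.
#' @examples
#' round(screen_angular_extent(screen_model(), 60), 1)  # 52.9 31.3
#' @export
screen_angular_extent <- function(screen = screen_model(), distance_cm = 60) {
  if (distance_cm <= 0) stop("viewing distance must be positive")
  c(horizontal = 2 * atan(screen$width_cm / (2 * distance_cm)),
    vertical   = 2 * atan(screen$height_cm / (2 * distance_cm))) * 180 / pi
}

# Per-axis angular position (deg) of a pixel, eye on the normal through the
# screen centre: theta = atan((p_cm - centre_cm) / d). y angle positive up.
px_to_angle <- function(px, viewer, screen) {
  px <- as.numeric(px)
  dx_cm <- (px[1] - screen$width_px / 2) / screen$px_per_cm["x"]
  dy_cm <- (screen$height_px / 2 - px[2]) / screen$px_per_cm["y"]  # y up
  unname(atan(c(dx_cm, dy_cm) / viewer$distance_cm) * 180 / pi)
}

angle_to_px <- function(angle_deg, viewer, screen) {
  a <- as.numeric(angle_deg) * pi / 180
  dx_cm <- viewer$distance_cm * tan(a[1])
  dy_cm <- viewer$distance_cm * tan(a[2])
  unname(c(screen$width_px / 2 + dx_cm * screen$px_per_cm["x"],
           screen$height_px / 2 - dy_cm * screen$px_per_cm["y"]))
}

#' Place a visual-field offset relative to fixation on the screen
#'
#' Gaze-contingent placement: given a target offset in visual-field degrees
#' relative to the current fixation point, returns the pixel at which the
#' angle between the fixation ray and the target ray equals the requested
#' offset, per axis (tangent-screen construction with the eye on the normal
#' through the screen centre).
#'
#' @param target_deg Offset `c(x, y)` in degrees relative to fixation
#'   (x positive right, y positive up).
#' @param viewer A [viewer_state()].
#' @param screen A [screen_model()].
#' @return List with `px` (pixel position), `valid` (logical) and `reason`
#'   (`"ok"`, or why placement failed — a failure signal, not an error).
#' @export
field_offset_to_px <- function(target_deg, viewer = viewer_state(),
                               screen = screen_model()) {
  fix_angle <- px_to_angle(viewer$fixation_px, viewer, screen)
  tgt_angle <- fix_angle + as.numeric(target_deg)
  px <- angle_to_px(tgt_angle, viewer, screen)
  chk <- placement_valid(target_deg, viewer, screen)
  list(px = px, angle_deg = tgt_angle, valid = chk$valid, reason = chk$reason)
}

#' Recover the visual-field offset of a pixel relative to fixation
#'
#' Inverse of [field_offset_to_px()].
#'
#' @param px Pixel position `c(x, y)`.
#' @inheritParams field_offset_to_px
#' @return Offset in degrees relative to the current fixation.
#' @export
px_to_field_offset <- function(px, viewer = viewer_state(),
                               screen = screen_model()) {
  px_to_angle(px, viewer, screen) - px_to_angle(viewer$fixation_px, viewer, screen)
}

#' Physical footprint of a stimulus of fixed retinal size
#'
#' Size compensation for tangent-screen presentation: a disc that must subtend
#' a constant `diameter_deg` at the eye (Goldmann III: 0.43 degrees) must be
#' drawn physically larger the farther it sits from the screen centre, and
#' larger at greater viewing distance. The per-axis extent at screen angle
#' `theta` is `d (tan(theta + r) - tan(theta - r))` with `r` the angular
#' radius.
#'
#' @param target_px Pixel position of the stimulus centre.
#' @param diameter_deg Retinal angular diameter, degrees.
#' @inheritParams field_offset_to_px
#' @return List with `size_px` (`c(x, y)` extents), `size_cm`, and
#'   `subtended_deg` (the realised angle, for verification).
#' @export
stimulus_footprint <- function(target_px, diameter_deg = 0.43,
                               viewer = viewer_state(),
                               screen = screen_model()) {
  ang <- px_to_angle(target_px, viewer, screen) * pi / 180
  r <- diameter_deg / 2 * pi / 180
  d <- viewer$distance_cm
  size_cm <- c(d * (tan(ang[1] + r) - tan(ang[1] - r)),
               d * (tan(ang[2] + r) - tan(ang[2] - r)))
  size_px <- size_cm * screen$px_per_cm
  # angle actually subtended by the drawn extent, per axis
  sub <- c(atan(tan(ang[1]) + size_cm[1] / (2 * d)) -
             atan(tan(ang[1]) - size_cm[1] / (2 * d)),
           atan(tan(ang[2]) + size_cm[2] / (2 * d)) -
             atan(tan(ang[2]) - size_cm[2] / (2 * d))) * 180 / pi
  list(size_px = unname(size_px), size_cm = unname(size_cm),
       subtended_deg = unname(sub))
}

in_rect <- function(px, rect) {
  px[1] >= rect[1] && px[1] <= rect[3] && px[2] >= rect[2] && px[2] <= rect[4]
}

#' Is a gaze-relative placement valid?
#'
#' A stimulus placement is valid when its full footprint lies on the screen,
#' its centre is outside every prohibited zone, and the target ray falls
#' within the eye-tracker's trackable region (otherwise the saccadic response
#' could not be classified). An invalid placement triggers a refixation trial
#' in the session runner; it is never silently skipped.
#'
#' @inheritParams field_offset_to_px
#' @param diameter_deg Stimulus angular diameter, degrees.
#' @return List `valid` (logical), `reason` (`"ok"`, `"off_screen"`,
#'   `"prohibited_zone"`, or `"outside_trackbox"`).
#' @export
placement_valid <- function(target_deg, viewer = viewer_state(),
                            screen = screen_model(), diameter_deg = 0.43) {
  fix_angle <- px_to_angle(viewer$fixation_px, viewer, screen)
  tgt_angle <- fix_angle + as.numeric(target_deg)
  if (abs(tgt_angle[1]) > viewer$trackbox_deg[1] ||
      abs(tgt_angle[2]) > viewer$trackbox_deg[2])
    return(list(valid = FALSE, reason = "outside_trackbox"))
  half <- screen_angular_extent(screen, viewer$distance_cm) / 2
  if (abs(tgt_angle[1]) >= half[[1]] || abs(tgt_angle[2]) >= half[[2]])
    return(list(valid = FALSE, reason = "off_screen"))
  px <- angle_to_px(tgt_angle, viewer, screen)
  fp <- stimulus_footprint(px, diameter_deg, viewer, screen)
  if (px[1] - fp$size_px[1] / 2 < 0 || px[1] + fp$size_px[1] / 2 > screen$width_px ||
      px[2] - fp$size_px[2] / 2 < 0 || px[2] + fp$size_px[2] / 2 > screen$height_px)
    return(list(valid = FALSE, reason = "off_screen"))
  for (z in screen$prohibited_zones)
    if (in_rect(px, z)) return(list(valid = FALSE, reason = "prohibited_zone"))
  list(valid = TRUE, reason = "ok")
}
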