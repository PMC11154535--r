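# Fixtures are built in code: uniform/blocky color frames for the low-level
# ops, and small synthetic scenes for anything end-to-end.

# uniform frame of a single RGB color (values in [0,1])
uniform_frame <- function(ny, nx, rgb) {
  array(rep(rgb, each = ny * nx), c(ny, nx, 3))
}

# paint an axis-aligned block [x0,x1] x [y0,y1] (0-based, inclusive)
paint_block <- function(frame, x0, y0, x1, y1, rgb) {
  for (ch in 1:3) frame[(y0:y1) + 1, (x0:x1) + 1, ch] <- rgb[ch]
  frame
}

rgb_of_hsv <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

# colors used by the hand-built frames
BODY_HSV <- c(0.08, 0.55, 0.55)
EYE_HSV  <- c(0.10, 0.60, 0.08)
BG_HSV   <- c(0.60, 0.08, 0.85)
BODY_RGB <- rgb_of_hsv(0.08, 0.55, 0.55)
EYE_RGB  <- rgb_of_hsv(0.10, 0.60, 0.08)
BG_RGB   <- rgb_of_hsv(0.60, 0.08, 0.85)

# profile matching the hand-built frames (wide eye range keyed on darkness)
test_profile <- function(alpha_th = 20, fps = 60) {
  calibration_profile(
    body_range = hsv_range(BODY_HSV[1] - 0.06, BODY_HSV[1] + 0.06,
                           BODY_HSV[2] - 0.2, BODY_HSV[2] + 0.2,
                           BODY_HSV[3] - 0.2, BODY_HSV[3] + 0.2),
    eye_range = hsv_range(0, 1, 0, 1, 0, EYE_HSV[3] + 0.1),
    ax = 40, ay = 16, alpha_th = alpha_th, fps = fps)
}

# small fast scene for end-to-end tests; cardiac-capable (60 fps)
small_scene_config <- function(...) {
  defaults <- list(width = 160, height = 120, fps = 60, duration = 5,
                   semi_axes = c(16, 6.5), speed = 1.2, seed = 11)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

# dense parametric ellipse contour (points, not pixels)
ellipse_contour <- function(a, b, angle, n = 200, center = c(0, 0)) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-1]
  x <- a * cos(tt); y <- b * sin(tt)
  cbind(x = center[1] + x * cos(angle) - y * sin(angle),
        y = center[2] + x * sin(angle) + y * cos(angle))
}
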