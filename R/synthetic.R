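#' Synthetic scene configuration
#'
#' Describes a ground-truthed synthetic cage scene: a single elliptical
#' animal of a distinct HSV color with two dark eye spots at the head end,
#' moving over a static background with piecewise-smooth heading, periodic
#' body stretch, and a sinusoidal green-channel pulse on its body pixels.
#' An optional stimulus time switches the motion statistics and the pulse
#' frequency, emulating a startle: faster, more erratic movement with a
#' changed heart rate.
#'
#' Defaults emulate the measurement conditions the pipeline targets: 60 Hz
#' video of a 640x480 analysis region, 30 s long; a pulse at 5.5 Hz (330
#' beats/min, mid-passband for a small rodent) with 4-green-level
#' amplitude; sensor noise of 2 gray levels; a startle that doubles speed,
#' triples turning, and lowers the pulse to 0.8x.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in Hz (default 60).
#' @param duration Scene length in seconds (default 30).
#' @param semi_axes Ellipse semi-axes `c(a, b)` in pixels (a = along the
#'   body axis).
#' @param body_hsv,eye_hsv,background_hsv Colors as `c(h, s, v)` on the
#'   unit scale.
#' @param speed Base speed in px/frame.
#' @param turn_rate Deterministic heading drift in rad/frame (default 0).
#' @param turn_sd Heading innovation sd in rad/frame.
#' @param stretch_amp,stretch_freq Periodic stretch factor amplitude
#'   (dimensionless) and frequency (Hz): the major semi-axis is
#'   `a * (1 + stretch_amp * sin(2 pi stretch_freq t))`.
#' @param pulse_f0 Pulse frequency in Hz (must lie below `fps / 2`).
#' @param pulse_amp Green-channel modulation amplitude in 8-bit levels.
#' @param noise_sd Per-pixel Gaussian noise sd in 8-bit levels.
#' @param stimulus_onset Stimulus time in seconds, or `NA` for none.
#' @param stim_speed_mult,stim_turn_mult,stim_pulse_mult Post-onset
#'   multipliers for speed, turn sd, and pulse frequency.
#' @param seed Integer seed; the whole scene is deterministic given it.
#' @return A `scene_config`.
#' @export
scene_config <- function(width = 640, height = 480, fps = 60, duration = 30,
                         semi_axes = c(42, 16),
                         body_hsv = c(0.08, 0.55, 0.55),
                         eye_hsv = c(0.10, 0.60, 0.08),
                         background_hsv = c(0.60, 0.08, 0.85),
                         speed = 2, turn_rate = 0, turn_sd = 0.05,
                         stretch_amp = 0.15, stretch_freq = 0.5,
                         pulse_f0 = 5.5, pulse_amp = 4, noise_sd = 2,
                         stimulus_onset = NA_real_,
                         stim_speed_mult = 2, stim_turn_mult = 3,
                         stim_pulse_mult = 0.8, seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              fps = fps, duration = duration, semi_axes = semi_axes,
              body_hsv = body_hsv, eye_hsv = eye_hsv,
              background_hsv = background_hsv, speed = speed,
              turn_rate = turn_rate, turn_sd = turn_sd,
              stretch_amp = stretch_amp,
              stretch_freq = stretch_freq, pulse_f0 = pulse_f0,
              pulse_amp = pulse_amp, noise_sd = noise_sd,
              stimulus_onset = stimulus_onset,
              stim_speed_mult = stim_speed_mult,
              stim_turn_mult = stim_turn_mult,
              stim_pulse_mult = stim_pulse_mult, seed = as.integer(seed))
  if (!(pulse_f0 > 0 && pulse_f0 < fps / 2))
    stop("pulse_f0 must lie in (0, fps/2)")
  if (!is.na(stimulus_onset) && stimulus_onset >= duration)
    stop("stimulus onset must precede the scene end")
  if (2 * semi_axes[1] * (1 + stretch_amp) + 6 > min(width, height))
    stop("ellipse does not fit in the frame")
  structure(cfg, class = "scene_config")
}

hsv_to_rgb_vec <- function(hsv) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(hsv[1], hsv[2], hsv[3]))) / 255
}

# Precompute the per-frame trajectory / ground truth for a config.
scene_ground_truth <- function(cfg) {
  n <- round(cfg$fps * cfg$duration)
  a <- cfg$semi_axes[1]; b <- cfg$semi_axes[2]
  max_r <- a * (1 + cfg$stretch_amp) + 2
  margin <- max_r + 2
  if (2 * margin >= cfg$width || 2 * margin >= cfg$height)
    stop("ellipse does not fit in the frame")
  tt <- seq_len(n) - 1L
  time_s <- tt / cfg$fps
  post <- if (is.na(cfg$stimulus_onset)) rep(FALSE, n) else time_s >= cfg$stimulus_onset
  with_local_seed(cfg$seed, {
    cx <- cy <- psi <- numeric(n)
    cx[1] <- cfg$width / 2; cy[1] <- cfg$height / 2
    psi[1] <- stats::runif(1, -pi, pi)
    turns <- stats::rnorm(n, 0, cfg$turn_sd)
    for (i in seq_len(n)[-1]) {
      tm <- if (post[i]) cfg$stim_turn_mult else 1
      sm <- if (post[i]) cfg$stim_speed_mult else 1
      p <- psi[i - 1] + (cfg$turn_rate + turns[i]) * tm
      step <- cfg$speed * sm
      nx <- cx[i - 1] + step * cos(p)
      ny <- cy[i - 1] + step * sin(p)
      if (nx < margin || nx > cfg$width - 1 - margin) p <- pi - p
      if (ny < margin || ny > cfg$height - 1 - margin) p <- -p
      nx <- cx[i - 1] + step * cos(p)
      ny <- cy[i - 1] + step * sin(p)
      cx[i] <- min(max(nx, margin), cfg$width - 1 - margin)
      cy[i] <- min(max(ny, margin), cfg$height - 1 - margin)
      psi[i] <- p
    }
    stretch <- 1 + cfg$stretch_amp * sin(2 * pi * cfg$stretch_freq * time_s)
    f0 <- ifelse(post, cfg$pulse_f0 * cfg$stim_pulse_mult, cfg$pulse_f0)
    phase <- cumsum(2 * pi * f0 / cfg$fps) - 2 * pi * f0[1] / cfg$fps
    d_eye <- 0.65 * a * stretch   # eye patch sits clear of the body outline
    eye_x <- cx + d_eye * cos(psi)
    eye_y <- cy + d_eye * sin(psi)
    bad <- which(cx - a * stretch < 0 | cx + a * stretch > cfg$width - 1 |
                   cy - a * stretch < 0 | cy + a * stretch > cfg$height - 1)
    if (length(bad) > 0L)
      stop(sprintf("ellipse leaves the frame at frame %d", bad[1] - 1L))
    data.frame(t = tt, time_s = time_s, cx = cx, cy = cy,
               orientation = wrap_pi(psi), stretch = stretch,
               r_true = d_eye, eye_x = eye_x, eye_y = eye_y,
               pulse_phase = phase, f0 = f0,
               anomaly = as.integer(post))
  })
}

render_scene_frame <- function(cfg, gt_row, grids) {
  X <- grids$X; Y <- grids$Y
  a <- cfg$semi_axes[1] * gt_row$stretch
  b <- cfg$semi_axes[2]
  phi <- gt_row$orientation
  dx <- X - gt_row$cx; dy <- Y - gt_row$cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  ab <- pmin(pmax((1 - rho) * b + 0.5, 0), 1)     # ~1 px anti-aliased edge

  re <- max(1.5, b / 5)
  px <- -sin(phi) * re * 0.8; py <- cos(phi) * re * 0.8
  d1 <- sqrt((X - (gt_row$eye_x + px))^2 + (Y - (gt_row$eye_y + py))^2)
  d2 <- sqrt((X - (gt_row$eye_x - px))^2 + (Y - (gt_row$eye_y - py))^2)
  ae <- pmax(pmin(pmax(re - d1 + 0.5, 0), 1), pmin(pmax(re - d2 + 0.5, 0), 1))
  ae <- ae * ab                                    # eyes only on the body

  bg <- hsv_to_rgb_vec(cfg$background_hsv)
  bodyc <- hsv_to_rgb_vec(cfg$body_hsv)
  eyec <- hsv_to_rgb_vec(cfg$eye_hsv)
  pulse <- cfg$pulse_amp / 255 * sin(gt_row$pulse_phase)
  frame <- array(0, c(cfg$height, cfg$width, 3))
  for (ch in 1:3) {
    layer <- bg[ch] * (1 - ab) + bodyc[ch] * ab
    if (ch == 2L) layer <- layer + ab * pulse
    layer <- layer * (1 - ae) + eyec[ch] * ae
    frame[, , ch] <- layer
  }
  if (cfg$noise_sd > 0) {
    with_local_seed(frame_seed(cfg$seed, gt_row$t), {
      frame <- frame + stats::rnorm(length(frame), 0, cfg$noise_sd / 255)
    })
  }
  pmin(pmax(frame, 0), 1)
}

#' Generate a ground-truthed synthetic scene
#'
#' Builds the trajectory and per-frame ground truth, and returns a lazy
#' scene whose frames are rendered on demand (byte-identical for the same
#' seed). If `stimulus_onset` is set in the config, post-onset frames use
#' the stimulus multipliers.
#'
#' @param config A [scene_config()].
#' @return A `scene`: list with `config`, `ground_truth` (`data.frame`, one
#'   row per frame: `t`, `time_s`, `cx`, `cy`, `orientation`, `stretch`,
#'   `r_true`, `eye_x`, `eye_y`, `pulse_phase`, `f0`, `anomaly`), `frame`
#'   (function of 1-based index), `n_frames`, `fps`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  gt <- scene_ground_truth(config)
  grids <- list(
    X = matrix(rep(0:(config$width - 1), each = config$height),
               config$height, config$width),
    Y = matrix(rep(0:(config$height - 1), times = config$width),
               config$height, config$width))
  force(gt)
  structure(list(config = config, ground_truth = gt,
                 frame = function(i) render_scene_frame(config, gt[i, ], grids),
                 n_frames = nrow(gt), fps = config$fps),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene: %dx%d, %d frames @ %g fps, pulse %g Hz%s>\n",
              x$config$width, x$config$height, x$n_frames, x$fps,
              x$config$pulse_f0,
              if (!is.na(x$config$stimulus_onset))
                sprintf(", stimulus @ %gs", x$config$stimulus_onset) else ""))
  invisible(x)
}

#' Generate a stimulus scenario
#'
#' Convenience wrapper over [generate_scene()] for a scene with a stimulus:
#' validates that the onset and post-onset multipliers are set. Pre-onset
#' dynamics follow the base config; after onset the speed and turn rate are
#' multiplied and the pulse frequency is scaled (default 0.8, a decrease).
#'
#' @param config A [scene_config()] with `stimulus_onset` set.
#' @return A `scene`.
#' @export
stimulus_scenario <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (is.na(config$stimulus_onset))
    stop("stimulus_onset must be set in the config")
  generate_scene(config)
}

#' Write a scene to disk
#'
#' Frames as numbered PNGs plus `ground_truth.csv` and `scene_config.json`.
#'
#' @param scene A `scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(scene$n_frames))
    write_frame(scene$frame(i), file.path(dir, sprintf("frame_%05d.png", i)))
  utils::write.csv(scene$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- scene$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "scene_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' A calibration profile matched to a synthetic scene
#'
#' Derives HSV ranges analytically from the scene's configured colors (with
#' a pad wide enough to absorb the pulse modulation and pixel noise) and
#' body metrics from the ellipse geometry — the synthetic analogue of
#' clicking calibration rectangles on a real frame.
#'
#' @param config A [scene_config()].
#' @param pad Extra HSV pad on each channel (unit scale). Default 0.08.
#' @param area_fraction Fraction for the minimum valid area. Default 0.1.
#' @return A [calibration_profile()].
#' @export
scene_profile <- function(config, pad = 0.08, area_fraction = 0.1) {
  mk <- function(hsv) {
    clip <- function(x) pmin(pmax(x, 0), 1)
    hsv_range(clip(hsv[1] - pad), clip(hsv[1] + pad),
              clip(hsv[2] - pad), clip(hsv[2] + pad),
              clip(hsv[3] - pad), clip(hsv[3] + pad))
  }
  a <- config$semi_axes[1] * (1 + config$stretch_amp)
  b <- config$semi_axes[2]
  calibration_profile(mk(config$body_hsv), mk(config$eye_hsv),
                      ax = 2 * a, ay = 2 * b,
                      alpha_th = area_fraction * 4 * a * b,
                      fps = config$fps)
}
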