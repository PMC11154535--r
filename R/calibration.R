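#' Rectangle specified by two diagonal corners
#'
#' Coordinates are 0-based pixel positions, x rightward and y downward,
#' matching the click-two-corners calibration workflow. Corners are
#' normalized so `pa` is the top-left and `pb` the bottom-right corner.
#'
#' @param pa,pb Numeric length-2 vectors `c(x, y)`.
#' @return A `rect_spec` with fields `pa`, `pb`.
#' @export
rect_spec <- function(pa, pb) {
  stopifnot(length(pa) == 2L, length(pb) == 2L,
            is.numeric(pa), is.numeric(pb), all(is.finite(c(pa, pb))))
  structure(list(pa = c(min(pa[1], pb[1]), min(pa[2], pb[2])),
                 pb = c(max(pa[1], pb[1]), max(pa[2], pb[2]))),
            class = "rect_spec")
}

rect_width  <- function(rect) rect$pb[1] - rect$pa[1]
rect_height <- function(rect) rect$pb[2] - rect$pa[2]

check_rect_in_image <- function(rect, frame) {
  d <- dim(frame)
  if (rect$pa[1] < 0 || rect$pa[2] < 0 ||
      rect$pb[1] > d[2] - 1 || rect$pb[2] > d[1] - 1)
    stop("rectangle lies outside the image")
  invisible(rect)
}

#' HSV channel bounds
#'
#' All channels are on the unit scale: hue as a fraction of the full circle
#' and saturation/value in `[0, 1]` (the scale used by [grDevices::rgb2hsv()]).
#' Profiles read from disk may declare other scales; see [read_profile()].
#'
#' @param h_min,h_max,s_min,s_max,v_min,v_max Channel bounds, each pair with
#'   min not exceeding max.
#' @return An `hsv_range`.
#' @export
hsv_range <- function(h_min, h_max, s_min, s_max, v_min, v_max) {
  v <- c(h_min = h_min, h_max = h_max, s_min = s_min, s_max = s_max,
         v_min = v_min, v_max = v_max)
  stopifnot(all(is.finite(v)), all(v >= 0), all(v <= 1))
  if (h_min > h_max || s_min > s_max || v_min > v_max)
    stop("hsv_range: each channel min must not exceed its max")
  structure(as.list(v), class = "hsv_range")
}

#' Derive an HSV range from a calibration rectangle
#'
#' Takes the channel-wise minimum and maximum over the rectangle's pixels
#' after HSV conversion, widened by a symmetric per-channel pad and clipped
#' to `[0, 1]`. This is the exact-envelope rule: every pixel inside the
#' rectangle lies within the returned range at `pad = 0`.
#'
#' Hue wraparound is not representable by a min/max pair; rectangles whose
#' hue values span more than half the hue circle are rejected so that a
#' red-ish patch straddling hue 0 cannot silently produce a near-full-circle
#' range.
#'
#' @param image RGB frame array.
#' @param rect A [rect_spec()] inside the image.
#' @param pad Per-channel symmetric widening; a scalar or length-3 vector
#'   `(h, s, v)` on the unit scale. Default 0.
#' @return An [hsv_range()].
#' @export
derive_hsv_range <- function(image, rect, pad = 0) {
  check_rect_in_image(rect, image)
  if (length(pad) == 1L) pad <- rep(pad, 3L)
  stopifnot(length(pad) == 3L, all(pad >= 0))
  rows <- (rect$pa[2]:rect$pb[2]) + 1
  cols <- (rect$pa[1]:rect$pb[1]) + 1
  patch <- image[rows, cols, , drop = FALSE]
  if (length(patch) == 0L) stop("empty calibration rectangle")
  hsv <- to_hsv(patch)
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  if (max(h) - min(h) > 0.5)
    stop("hue spread exceeds half the hue circle (wraparound not supported); ",
         "choose a more uniform calibration patch")
  clip <- function(x) min(max(x, 0), 1)
  hsv_range(clip(min(h) - pad[1]), clip(max(h) + pad[1]),
            clip(min(s) - pad[2]), clip(max(s) + pad[2]),
            clip(min(v) - pad[3]), clip(max(v) + pad[3]))
}

#' Body-length constants and minimum valid area
#'
#' The body-length rectangle encloses the fully stretched animal; its width
#' and height give the body lengths `ax`, `ay` along the image axes, and the
#' minimum valid mask area is a declared fraction of the `ax * ay` box.
#' Frames whose mask is smaller than `alpha_th` are treated as unreliable by
#' the cardiac stage.
#'
#' @param rect_l A non-degenerate [rect_spec()] enclosing the animal.
#' @param area_fraction Fraction of `ax * ay` used as the minimum valid
#'   area; in `(0, 1]`. Default 0.1, tolerant of partial occlusion.
#' @return List with `ax`, `ay` (pixels) and `alpha_th` (pixels^2).
#' @export
derive_body_metrics <- function(rect_l, area_fraction = 0.1) {
  stopifnot(inherits(rect_l, "rect_spec"),
            is_scalar_num(area_fraction), area_fraction > 0, area_fraction <= 1)
  ax <- rect_width(rect_l)
  ay <- rect_height(rect_l)
  if (ax <= 0 || ay <= 0) stop("degenerate body-length rectangle")
  list(ax = ax, ay = ay, alpha_th = area_fraction * ax * ay)
}

#' Analysis crop window (region A)
#'
#' @param mx,my Margins in pixels from the frame's top-left corner.
#' @param rx,ry Width and height of the analysis region in pixels.
#' @return A `crop_spec`.
#' @export
crop_spec <- function(mx, my, rx, ry) {
  stopifnot(mx >= 0, my >= 0, rx >= 1, ry >= 1)
  structure(list(mx = as.integer(mx), my = as.integer(my),
                 rx = as.integer(rx), ry = as.integer(ry)),
            class = "crop_spec")
}

#' Crop the analysis region A out of a full frame
#'
#' Pixel intervals are half-open: columns `[mx, mx + rx)` and rows
#' `[my, my + ry)`, so composing the crop with a coordinate shift of
#' `(+mx, +my)` maps cropped coordinates back to source coordinates exactly.
#'
#' @param frame RGB frame array.
#' @param crop A [crop_spec()] that fits inside the frame.
#' @return The `ry x rx x 3` sub-array.
#' @export
crop_region_a <- function(frame, crop) {
  d <- dim(frame)
  if (crop$mx + crop$rx > d[2] || crop$my + crop$ry > d[1])
    stop(sprintf("crop %dx%d at (%d,%d) exceeds frame %dx%d",
                 crop$rx, crop$ry, crop$mx, crop$my, d[2], d[1]))
  frame[(crop$my + 1):(crop$my + crop$ry),
        (crop$mx + 1):(crop$mx + crop$rx), , drop = FALSE]
}

#' Calibration profile
#'
#' Bundles everything the segmentation and cardiac stages need: HSV ranges
#' for body and eye color, body lengths, the minimum valid area, the
#' analysis crop, and the frame rate.
#'
#' @param body_range,eye_range [hsv_range()] objects.
#' @param ax,ay Body lengths in pixels (positive).
#' @param alpha_th Minimum valid mask area in pixels^2; in `(0, ax * ay]`.
#' @param crop A [crop_spec()] or `NULL` for no cropping.
#' @param fps Frame rate in Hz.
#' @return A `calibration_profile`.
#' @export
calibration_profile <- function(body_range, eye_range, ax, ay, alpha_th,
                                crop = NULL, fps = 60) {
  stopifnot(inherits(body_range, "hsv_range"), inherits(eye_range, "hsv_range"),
            is_scalar_num(ax), ax > 0, is_scalar_num(ay), ay > 0,
            is_scalar_num(alpha_th), alpha_th > 0,
            is_scalar_num(fps), fps > 0)
  if (alpha_th > ax * ay) stop("alpha_th must not exceed ax * ay")
  if (!is.null(crop)) stopifnot(inherits(crop, "crop_spec"))
  structure(list(body_range = body_range, eye_range = eye_range,
                 ax = ax, ay = ay, alpha_th = alpha_th, crop = crop,
                 fps = fps),
            class = "calibration_profile")
}

#' Calibrate from an image and three user rectangles
#'
#' Convenience wrapper running [derive_hsv_range()] for the body and eye
#' rectangles and [derive_body_metrics()] for the body-length rectangle.
#'
#' @param image Calibration frame (RGB array), typically the first video
#'   frame with the animal lying stretched.
#' @param body_rect,eye_rect,length_rect [rect_spec()] objects.
#' @param crop Optional [crop_spec()].
#' @param pad Per-channel pad for both HSV ranges (see [derive_hsv_range()]).
#' @param area_fraction Passed to [derive_body_metrics()].
#' @param fps Frame rate in Hz.
#' @return A [calibration_profile()].
#' @export
calibrate <- function(image, body_rect, eye_rect, length_rect, crop = NULL,
                      pad = 0, area_fraction = 0.1, fps = 60) {
  bm <- derive_body_metrics(length_rect, area_fraction)
  calibration_profile(
    body_range = derive_hsv_range(image, body_rect, pad),
    eye_range  = derive_hsv_range(image, eye_rect, pad),
    ax = bm$ax, ay = bm$ay, alpha_th = bm$alpha_th, crop = crop, fps = fps)
}

# ---- profile (de)serialization ---------------------------------------------

# Supported hsv scales for profiles on disk. Internally everything is "unit".
.hsv_scales <- list(
  unit   = c(h = 1, s = 1, v = 1),
  opencv = c(h = 180, s = 255, v = 255),   # OpenCV 8-bit convention
  degrees = c(h = 360, s = 100, v = 100)
)

#' Write a calibration profile as a flat YAML config
#'
#' Keys: `hsv_scale`, `body.h_min` ... `body.v_max`, `eye.h_min` ...
#' `eye.v_max`, `ax`, `ay`, `alpha_th`, `crop.mx`, `crop.my`, `crop.rx`,
#' `crop.ry`, `fps`. Values are written on the declared scale.
#'
#' @param profile A [calibration_profile()].
#' @param path Output file path.
#' @param hsv_scale One of `"unit"`, `"opencv"`, `"degrees"`.
#' @export
write_profile <- function(profile, path, hsv_scale = "unit") {
  sc <- .hsv_scales[[match.arg(hsv_scale, names(.hsv_scales))]]
  enc <- function(r, prefix) {
    v <- unlist(r)
    v <- v * sc[c("h", "h", "s", "s", "v", "v")]
    stats::setNames(as.list(unname(v)), paste0(prefix, ".", names(r)))
  }
  out <- c(list(hsv_scale = hsv_scale),
           enc(profile$body_range, "body"), enc(profile$eye_range, "eye"),
           list(ax = profile$ax, ay = profile$ay, alpha_th = profile$alpha_th,
                fps = profile$fps))
  if (!is.null(profile$crop))
    out <- c(out, list(crop.mx = profile$crop$mx, crop.my = profile$crop$my,
                       crop.rx = profile$crop$rx, crop.ry = profile$crop$ry))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a calibration profile from a flat YAML config
#'
#' The config declares its HSV scale explicitly (`hsv_scale: unit | opencv |
#' degrees`); values are converted to the unit scale on load. Printed
#' threshold listings sometimes swap a channel's min and max; each pair is
#' sorted on load so the range invariant always holds.
#'
#' @param path Path to a YAML profile written by [write_profile()] or by hand.
#' @return A [calibration_profile()].
#' @export
read_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  scale_name <- cfg$hsv_scale %||% "unit"
  if (!scale_name %in% names(.hsv_scales))
    stop("unknown hsv_scale '", scale_name, "'")
  sc <- .hsv_scales[[scale_name]]
  dec <- function(prefix) {
    get2 <- function(ch) {
      lo <- cfg[[paste0(prefix, ".", ch, "_min")]]
      hi <- cfg[[paste0(prefix, ".", ch, "_max")]]
      if (is.null(lo) || is.null(hi))
        stop("profile missing ", prefix, ".", ch, " bounds")
      sort(c(lo, hi)) / sc[[ch]]     # tolerate swapped printed pairs
    }
    h <- get2("h"); s <- get2("s"); v <- get2("v")
    hsv_range(h[1], h[2], s[1], s[2], v[1], v[2])
  }
  crop <- NULL
  if (!is.null(cfg$crop.rx))
    crop <- crop_spec(cfg$crop.mx, cfg$crop.my, cfg$crop.rx, cfg$crop.ry)
  calibration_profile(dec("body"), dec("eye"),
                      ax = cfg$ax, ay = cfg$ay, alpha_th = cfg$alpha_th,
                      crop = crop, fps = cfg$fps %||% 60)
}
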