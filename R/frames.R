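#' Frame sources
#'
#' A frame source is a uniform, lazily-evaluated view over a sequence of
#' color frames: a directory of numbered PNG files, an in-memory list of
#' arrays, or a synthetic scene (see [generate_scene()]). Frames are numeric
#' arrays of dimension `c(height, width, 3)` with RGB values in `[0, 1]`;
#' pixel `(x, y)` (0-based, x rightward, y downward) is `frame[y + 1, x + 1, ]`.
#'
#' @param x A directory path containing `.png` frames (sorted by name), a
#'   list of frame arrays, a single frame array, or a `scene` object.
#' @param fps Frame rate in Hz; taken from the scene when given one, `NA`
#'   when unknown (operations that need timing then require it explicitly).
#' @return An object of class `frame_source` with elements `get` (function
#'   of a 1-based frame index returning an array), `n` (frame count) and
#'   `fps`.
#' @export
as_frame_source <- function(x, fps = NULL) {
  if (inherits(x, "frame_source")) return(x)
  if (inherits(x, "scene")) {
    return(new_frame_source(x$frame, x$n_frames, x$fps))
  }
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) stop("frame directory not found: ", x)
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no .png frames in ", x)
    return(new_frame_source(function(i) read_frame(files[i]), length(files),
                            fps %||% NA_real_))
  }
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty frame list")
    return(new_frame_source(function(i) x[[i]], length(x), fps %||% NA_real_))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a frame source")
}

new_frame_source <- function(get, n, fps) {
  stopifnot(is.function(get), n >= 1L, is.na(fps) || fps > 0)
  structure(list(get = get, n = as.integer(n), fps = fps),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source: %d frames @ %g fps>\n", x$n, x$fps))
  invisible(x)
}

#' Read a single PNG frame as an RGB array in `[0, 1]`
#'
#' Grayscale images are expanded to three channels and an alpha channel,
#' if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return Numeric array `c(height, width, 3)`.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a frame to PNG
#'
#' @param frame RGB array in `[0, 1]`.
#' @param path Output path.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 1), path)
  invisible(path)
}

# RGB array -> HSV array of the same dimension, all channels on [0, 1]
# (hue as a fraction of the full circle).
to_hsv <- function(frame) {
  d <- dim(frame)
  px <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
              as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), d)
}
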