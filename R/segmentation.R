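#' Segmentation backends
#'
#' Per-frame animal detection is delegated to a named backend that proposes
#' candidate binary masks; the largest candidate (by pixel count) becomes
#' the animal region B. The default `color_threshold` backend thresholds the
#' frame in HSV space with the profile's body range and proposes each
#' 8-connected component as a candidate. An `instance_segmentation` adapter
#' accepts any external detector exposing per-instance masks and class
#' labels (e.g. a pretrained network); masks whose label falls in a
#' configurable animal-like label set count as candidates. The adapter is
#' inert until a detector function is supplied via
#' `options(cagemon.instance_detector = ...)`, keeping the default pipeline
#' self-contained.
#'
#' @name segmentation-backends
NULL

.backends <- new.env(parent = emptyenv())

#' Register a segmentation backend
#'
#' @param name Backend name.
#' @param fun Function `(frame, hsv, profile) -> list of logical matrices`
#'   (candidate masks, possibly empty). `hsv` is the frame converted to HSV.
#' @export
register_segmentation_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .backends)
  invisible(name)
}

#' List registered segmentation backends
#' @return Character vector of backend names.
#' @export
segmentation_backends <- function() sort(ls(.backends))

get_backend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE))
    stop("unknown segmentation backend '", name, "'; registered: ",
         paste(segmentation_backends(), collapse = ", "))
  get(name, envir = .backends, inherits = FALSE)
}

# logical mask of pixels inside an hsv_range
hsv_in_range <- function(hsv, range) {
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  h >= range$h_min & h <= range$h_max &
    s >= range$s_min & s <= range$s_max &
    v >= range$v_min & v <= range$v_max
}

backend_color_threshold <- function(frame, hsv, profile) {
  mask <- hsv_in_range(hsv, profile$body_range)
  if (!any(mask)) return(list())
  # fill interior holes (e.g. differently-colored eyes) so the candidate is
  # the simply-connected animal region
  lab <- EBImage::fillHull(EBImage::bwlabel(mask))
  n <- max(lab)
  lapply(seq_len(n), function(k) lab == k)
}

backend_instance_segmentation <- function(frame, hsv, profile) {
  detector <- getOption("cagemon.instance_detector", NULL)
  if (is.null(detector))
    stop("instance_segmentation backend: no detector configured; set ",
         "options(cagemon.instance_detector = function(frame) ",
         "list(masks = <list>, labels = <chr>))")
  labels_ok <- getOption("cagemon.animal_labels",
                         c("cat", "dog", "bird", "horse", "sheep", "cow",
                           "elephant", "bear", "zebra", "giraffe", "mouse"))
  det <- detector(frame)
  keep <- det$labels %in% labels_ok
  det$masks[keep]
}

# populated at load time
register_default_backends <- function() {
  register_segmentation_backend("color_threshold", backend_color_threshold)
  register_segmentation_backend("instance_segmentation",
                                backend_instance_segmentation)
}

#' Extract the outer contour of the largest connected component
#'
#' Border following (8-connectivity) around the largest component's outer
#' boundary; interior holes are ignored. Points revisited by the border
#' walk on thin structures are deduplicated, preserving first-visit order,
#' so the contour point count never exceeds the mask pixel count. Every
#' returned point is a foreground pixel with at least one background
#' 8-neighbor.
#'
#' @param mask Logical or 0/1 matrix (rows = y, columns = x).
#' @return Integer matrix with columns `x`, `y` (0-based), ordered along
#'   the boundary, or `NULL` when the mask is empty (no detection).
#' @export
extract_contour <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  largest <- which.max(sizes)
  oc <- EBImage::ocontour(lab == largest)[[1]]
  # ocontour indexes along matrix dims: col 1 = dim1 (y), col 2 = dim2 (x)
  pts <- cbind(x = oc[, 2], y = oc[, 1])
  pts[!duplicated(pts), , drop = FALSE]
}

#' Centroid of a contour point set
#'
#' Arithmetic mean of the contour point coordinates (not of all mask
#' pixels): the animal's position proxy G(t). Computing the mean over the
#' boundary rather than the filled mask weights the estimate toward regions
#' of high boundary curvature; for near-elliptical bodies the two coincide.
#'
#' @param contour Matrix with columns `x`, `y`; at least one row.
#' @return Numeric `c(Gx, Gy)`, or `NULL` for an empty/`NULL` contour.
#' @export
centroid_of <- function(contour) {
  if (is.null(contour) || nrow(contour) == 0L) return(NULL)
  c(mean(contour[, 1]), mean(contour[, 2]))
}

#' Locate the eye inside a bounding box by color
#'
#' Thresholds the box interior with the eye HSV range and returns the pixel
#' centroid of the largest eye-colored 8-connected component. When both
#' eyes appear as separate components the larger one wins (a tie-break the
#' upstream literature leaves unstated).
#'
#' @param hsv HSV frame array (unit scale).
#' @param bbox [rect_spec()] inside the frame (bounding box of region B,
#'   typically inflated by a couple of pixels).
#' @param eye_range [hsv_range()] of the eye color.
#' @return Numeric `c(Fx, Fy)` or `NULL` when no eye-colored pixels exist.
#' @export
detect_eye <- function(hsv, bbox, eye_range) {
  d <- dim(hsv)
  x0 <- max(0, floor(bbox$pa[1])); y0 <- max(0, floor(bbox$pa[2]))
  x1 <- min(d[2] - 1, ceiling(bbox$pb[1])); y1 <- min(d[1] - 1, ceiling(bbox$pb[2]))
  if (x1 < x0 || y1 < y0) return(NULL)
  sub <- hsv[(y0:y1) + 1, (x0:x1) + 1, , drop = FALSE]
  mask <- hsv_in_range(sub, eye_range)
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  c(x0 + mean(idx[, 2]) - 1, y0 + mean(idx[, 1]) - 1)
}

#' Segment one frame into the animal region B
#'
#' Runs the chosen backend, keeps the largest candidate mask as region B,
#' and derives the contour, centroid G(t), area, and eye position F(t)
#' (searched in region B's bounding box inflated by 2 px). When no
#' candidate exists the frame is reported as a no-detection record
#' (`valid_mask = FALSE`); nothing is interpolated. Area-based gating
#' against `alpha_th` is applied downstream (the area is always reported).
#'
#' @param frame Region-A-sized RGB frame array.
#' @param profile A [calibration_profile()].
#' @param backend Backend name; see [segmentation_backends()].
#' @param centroid_from `"contour"` (default; mean of contour points) or
#'   `"mask"` (mean of all mask pixels).
#' @param frame_index Optional frame index stored in the result.
#' @return A `segmentation_result`: list with `mask`, `contour`, `centroid`,
#'   `eye`, `area`, `valid_mask`, `valid_eye`, `frame_index`.
#' @export
segment_frame <- function(frame, profile, backend = "color_threshold",
                          centroid_from = c("contour", "mask"),
                          frame_index = NA_integer_) {
  centroid_from <- match.arg(centroid_from)
  if (is.null(dim(frame)) || length(dim(frame)) != 3L || any(dim(frame) == 0L))
    stop("empty or non-RGB frame")
  fun <- get_backend(backend)
  hsv <- to_hsv(frame)
  cands <- fun(frame, hsv, profile)
  empty <- structure(list(mask = NULL, contour = NULL, centroid = NULL,
                          eye = NULL, area = 0L, valid_mask = FALSE,
                          valid_eye = FALSE, frame_index = frame_index),
                     class = "segmentation_result")
  if (length(cands) == 0L) return(empty)
  areas <- vapply(cands, sum, numeric(1))
  b <- cands[[which.max(areas)]]
  contour <- extract_contour(b)
  if (is.null(contour)) return(empty)
  centroid <- if (centroid_from == "contour") centroid_of(contour) else {
    idx <- which(b, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  }
  # eye search box: bbox of B inflated by 2 px to survive mask erosion
  bbox <- rect_spec(c(min(contour[, 1]) - 2, min(contour[, 2]) - 2),
                    c(max(contour[, 1]) + 2, max(contour[, 2]) + 2))
  eye <- detect_eye(hsv, bbox, profile$eye_range)
  structure(list(mask = b, contour = contour, centroid = centroid,
                 eye = eye, area = as.integer(sum(b)),
                 valid_mask = TRUE, valid_eye = !is.null(eye),
                 frame_index = frame_index),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result t=%s: %s, area=%d%s>\n",
              x$frame_index,
              if (x$valid_mask) sprintf("G=(%.1f, %.1f)", x$centroid[1],
                                        x$centroid[2]) else "no detection",
              x$area,
              if (x$valid_eye) sprintf(", F=(%.1f, %.1f)", x$eye[1], x$eye[2])
              else ""))
  invisible(x)
}
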