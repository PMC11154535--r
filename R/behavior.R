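#' Behavioral features
#'
#' Per-frame behavioral descriptors of a tracked animal: the amount of
#' movement m(t) (frame-to-frame displacement of the centroid), the body
#' extent r(t) (centroid-to-eye distance) and its change r'(t), and the
#' heading theta(t) combining a PCA body-axis estimate with the
#' centroid-to-eye direction, differenced into the direction change
#' theta'(t). Angles are in radians in image coordinates (x-positive = 0,
#' y pointing down), wrapped to (-pi, pi].
#'
#' @name behavior-features
NULL

#' Movement per frame
#'
#' Euclidean displacement of the centroid between consecutive frames.
#'
#' @param g_t,g_prev Centroids `c(Gx, Gy)`; `NULL`/`NA` marks a missing
#'   detection and yields `NA`.
#' @return Non-negative scalar, or `NA_real_` when either centroid is missing.
#' @export
movement <- function(g_t, g_prev) {
  if (is.null(g_t) || is.null(g_prev) || anyNA(g_t) || anyNA(g_prev))
    return(NA_real_)
  sqrt(sum((g_t - g_prev)^2))
}

#' Body extent: centroid-to-eye distance
#'
#' Large values indicate a stretched body, small values a curled-up one.
#'
#' @param g Centroid `c(Gx, Gy)`.
#' @param f Eye position `c(Fx, Fy)`.
#' @return Non-negative scalar, `NA_real_` when either point is missing.
#' @export
body_extent <- function(g, f) {
  if (is.null(g) || is.null(f) || anyNA(g) || anyNA(f)) return(NA_real_)
  sqrt(sum((g - f)^2))
}

#' Change in body extent between consecutive frames
#'
#' Positive when the body is stretching, negative when shrinking.
#'
#' @param r_t,r_prev Body extents; `NA` propagates.
#' @return `r_t - r_prev`.
#' @export
extent_change <- function(r_t, r_prev) {
  if (is.na(r_t) || is.na(r_prev)) return(NA_real_)
  r_t - r_prev
}

#' Body-axis direction from contour PCA
#'
#' Centers the contour coordinates, forms their 2x2 covariance matrix, and
#' returns the angle of the leading eigenvector as an axis angle in
#' (-pi/2, pi/2] (an axis is defined only modulo pi). When the leading
#' eigenvalue does not dominate the second by at least `min_eigen_ratio`
#' the contour is effectively isotropic — a curled-up animal has no body
#' axis — and `NA` is returned.
#'
#' @param contour Matrix with columns `x`, `y`; at least 2 distinct points.
#' @param min_eigen_ratio Minimum `lambda1 / lambda2`; default 1.2.
#' @return Axis angle in radians, or `NA_real_` when undefined.
#' @export
pca_direction <- function(contour, min_eigen_ratio = 1.2) {
  if (is.null(contour) || nrow(contour) < 2L) return(NA_real_)
  pts <- unique(contour[, 1:2, drop = FALSE])
  if (nrow(pts) < 2L) return(NA_real_)
  ctr <- sweep(pts, 2, colMeans(pts))
  sigma <- crossprod(ctr) / nrow(ctr)
  e <- eigen(sigma, symmetric = TRUE)
  if (e$values[2] > 0 && e$values[1] / e$values[2] < min_eigen_ratio)
    return(NA_real_)
  w1 <- e$vectors[, 1]
  wrap_half_pi(atan2(w1[2], w1[1]))
}

#' Centroid-to-eye direction
#'
#' Quadrant-aware angle of the vector from the centroid G toward the eye
#' position F, so the direction points from body center toward the head.
#' `strict = TRUE` reproduces the quadrant-blind single-argument
#' arctangent form `atan((Gy - Fy) / (Gx - Fx))` (an axis in
#' (-pi/2, pi/2]), which cannot distinguish head-left from head-right.
#'
#' @param g Centroid `c(Gx, Gy)`.
#' @param f Eye position `c(Fx, Fy)`.
#' @param strict Use the quadrant-blind form. Default `FALSE`.
#' @return Angle in radians in (-pi, pi], or `NA_real_` when a point is
#'   missing or G equals F.
#' @export
eye_direction <- function(g, f, strict = FALSE) {
  if (is.null(g) || is.null(f) || anyNA(g) || anyNA(f)) return(NA_real_)
  if (all(g == f)) return(NA_real_)
  if (strict) {
    dx <- g[1] - f[1]
    if (dx == 0) return(pi / 2)
    return(atan((g[2] - f[2]) / dx))
  }
  atan2(f[2] - g[2], f[1] - g[1])
}

#' Combine PCA axis and eye direction into the heading
#'
#' The PCA estimate is an axis (modulo pi) while the eye direction is a
#' full direction (modulo 2 pi); the axis is flipped by pi when that
#' reduces its angular distance to the eye direction, and the two are then
#' averaged circularly (the arithmetic mean after mapping both to within pi
#' of each other). When the PCA axis is missing the eye direction is used
#' alone.
#'
#' @param theta_m PCA axis angle (may be `NA`).
#' @param theta_c Eye direction (may be `NA`).
#' @return Heading in (-pi, pi], or `NA_real_` when both inputs are missing
#'   or `theta_c` is missing.
#' @export
combined_direction <- function(theta_m, theta_c) {
  if (is.na(theta_c)) return(NA_real_)
  if (is.na(theta_m)) return(wrap_pi(theta_c))
  d0 <- wrap_pi(theta_m - theta_c)
  d1 <- wrap_pi(theta_m + pi - theta_c)
  d <- if (abs(d1) < abs(d0)) d1 else d0
  wrap_pi(theta_c + d / 2)
}

#' Direction change between consecutive frames
#'
#' Wrapped angular difference in (-pi, pi]; a constant-rate rotation yields
#' its angular velocity at every step with no 2 pi jumps.
#'
#' @param theta_t,theta_prev Headings in radians; `NA` propagates.
#' @return Wrapped difference, or `NA_real_`.
#' @export
direction_change <- function(theta_t, theta_prev) {
  if (is.na(theta_t) || is.na(theta_prev)) return(NA_real_)
  wrap_pi(theta_t - theta_prev)
}

#' Per-frame behavioral feature table from segmentation results
#'
#' Applies the feature operations over a sequence of per-frame segmentation
#' results. Features needing frame t-1 are missing at the start of the
#' sequence and after any no-detection frame; missing values propagate to
#' sample assembly rather than being imputed.
#'
#' @param segs List of `segmentation_result` objects in frame order.
#' @param min_eigen_ratio Passed to [pca_direction()].
#' @param strict_eye_angle Passed to [eye_direction()].
#' @return `data.frame` with columns `t`, `Gx`, `Gy`, `Fx`, `Fy`, `area`,
#'   `valid_mask`, `valid_eye`, `m`, `r`, `r_prime`, `theta`, `theta_prime`.
#' @export
behavior_features <- function(segs, min_eigen_ratio = 1.2,
                              strict_eye_angle = FALSE) {
  n <- length(segs)
  na2 <- c(NA_real_, NA_real_)
  g <- t(vapply(segs, function(s) s$centroid %||% na2, numeric(2)))
  f <- t(vapply(segs, function(s) s$eye %||% na2, numeric(2)))
  valid_mask <- vapply(segs, `[[`, logical(1), "valid_mask")
  valid_eye <- vapply(segs, `[[`, logical(1), "valid_eye")
  area <- vapply(segs, `[[`, numeric(1), "area")
  tt <- vapply(seq_len(n), function(i) {
    ti <- segs[[i]]$frame_index
    if (is.na(ti)) i - 1L else as.integer(ti)
  }, integer(1))

  m <- r <- r_prime <- theta <- theta_prime <- rep(NA_real_, n)
  theta_raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!valid_mask[i]) next
    r[i] <- body_extent(g[i, ], f[i, ])
    th_m <- pca_direction(segs[[i]]$contour, min_eigen_ratio)
    th_c <- eye_direction(g[i, ], f[i, ], strict = strict_eye_angle)
    theta_raw[i] <- combined_direction(th_m, th_c)
    theta[i] <- theta_raw[i]
    if (i > 1L && valid_mask[i - 1L]) {
      m[i] <- movement(g[i, ], g[i - 1L, ])
      r_prime[i] <- extent_change(r[i], r[i - 1L])
      theta_prime[i] <- direction_change(theta_raw[i], theta_raw[i - 1L])
    }
  }
  data.frame(t = tt, Gx = g[, 1], Gy = g[, 2], Fx = f[, 1], Fy = f[, 2],
             area = area, valid_mask = valid_mask, valid_eye = valid_eye,
             m = m, r = r, r_prime = r_prime, theta = theta,
             theta_prime = theta_prime)
}
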