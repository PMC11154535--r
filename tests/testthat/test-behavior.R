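test_that("movement is the Euclidean centroid displacement", {
  expect_equal(movement(c(3, 4), c(0, 0)), 5)
  expect_equal(movement(c(2, 2), c(2, 2)), 0)
  expect_true(is.na(movement(NULL, c(0, 0))))
  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(2, sd = 50); b <- rnorm(2, sd = 50)
    expect_equal(movement(a, b), sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2),
                 tolerance = 1e-12)
  }
})

test_that("body extent and its change follow the stretch/shrink semantics", {
  expect_equal(body_extent(c(0, 0), c(0, 5)), 5)
  expect_equal(extent_change(10, 7), 3)     # stretching
  expect_equal(extent_change(7, 10), -3)    # shrinking
  expect_true(is.na(body_extent(c(0, 0), c(NA, 1))))
  # rigid translation leaves r unchanged
  g <- c(3, 4); f <- c(10, -2); d <- c(8.5, -3.25)
  expect_equal(extent_change(body_extent(g + d, f + d), body_extent(g, f)), 0)
})

test_that("pca_direction recovers ellipse axes and rejects isotropy", {
  ct0 <- ellipse_contour(8, 2, 0)
  expect_equal(pca_direction(ct0), 0, tolerance = 1e-9)
  ct30 <- ellipse_contour(8, 2, pi / 6)
  expect_equal(pca_direction(ct30), pi / 6, tolerance = 1e-6)
  # circle: eigenvalue ratio below the gate -> missing
  expect_true(is.na(pca_direction(ellipse_contour(5, 5, 0.3))))
})

test_that("pca_direction agrees with a brute-force eigen-solve", {
  set.seed(9)
  for (i in 1:100) {
    pts <- cbind(x = rnorm(60, sd = runif(1, 2, 10)),
                 y = rnorm(60, sd = runif(1, 2, 10)))
    ang <- runif(1, -pi, pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    pts <- pts %*% t(R)
    # oracle: explicit 2x2 covariance eigenvector
    ctr <- sweep(pts, 2, colMeans(pts))
    S <- crossprod(ctr) / nrow(ctr)
    ev <- eigen(S, symmetric = TRUE)
    if (ev$values[1] / ev$values[2] < 1.2) {
      expect_true(is.na(pca_direction(pts)))
    } else {
      expected <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
      got <- pca_direction(pts)
      diff <- abs(got - expected) %% pi
      expect_lt(min(diff, pi - diff), pi / 180)
    }
  }
})

test_that("eye_direction is quadrant-aware from centroid toward the eye", {
  expect_equal(eye_direction(c(0, 0), c(1, 0)), 0)
  expect_equal(eye_direction(c(0, 0), c(0, 1)), pi / 2)   # image y points down
  expect_equal(eye_direction(c(0, 0), c(-1, 0)), pi)
  expect_true(is.na(eye_direction(c(2, 2), c(2, 2))))
  # strict mode reproduces the quadrant-blind single-argument arctangent
  expect_equal(eye_direction(c(0, 0), c(-1, 0), strict = TRUE), 0)
  expect_equal(eye_direction(c(0, 0), c(1, 1), strict = TRUE),
               atan((0 - 1) / (0 - 1)))
})

test_that("combined_direction resolves the axis flip before averaging", {
  expect_equal(combined_direction(0.1, 0.3), 0.2)
  # axis near 0, eye direction near pi: flip the axis by pi first
  got <- combined_direction(0.05, 3.10)
  # oracle: brute force over both flip choices, minimizing |wrapped diff|
  flips <- c(0.05, 0.05 + pi)
  d <- abs(atan2(sin(flips - 3.10), cos(flips - 3.10)))
  best <- flips[which.min(d)]
  expected <- atan2(sin(3.10) + sin(best), cos(3.10) + cos(best))
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(combined_direction(NA_real_, 1.5), 1.5)
  expect_true(is.na(combined_direction(0.3, NA_real_)))
})

test_that("direction_change wraps to (-pi, pi] with no 2*pi jumps", {
  expect_equal(direction_change(0.4, 0.4), 0)
  expect_equal(direction_change(-3.1, 3.1), 2 * pi - 6.2, tolerance = 1e-12)
  omega <- 0.25
  theta <- wrap_pi_seq <- vapply(0:100, function(k) {
    a <- (k * omega) %% (2 * pi); if (a > pi) a - 2 * pi else a
  }, numeric(1))
  dd <- mapply(direction_change, theta[-1], theta[-length(theta)])
  expect_true(all(abs(dd - omega) < 1e-9))
})

test_that("features are translation-invariant and rotation-equivariant", {
  ct <- ellipse_contour(9, 3, 0.7, center = c(20, 30))
  g <- centroid_of(ct); f <- c(20 + 7 * cos(0.7), 30 + 7 * sin(0.7))
  d <- c(-12.5, 8)
  ct2 <- ct; ct2[, 1] <- ct2[, 1] + d[1]; ct2[, 2] <- ct2[, 2] + d[2]
  expect_equal(pca_direction(ct2), pca_direction(ct), tolerance = 1e-9)
  expect_equal(body_extent(g + d, f + d), body_extent(g, f), tolerance = 1e-9)
  expect_equal(eye_direction(g + d, f + d), eye_direction(g, f),
               tolerance = 1e-9)
  # rotating the contour rotates the recovered axis by the same amount
  for (rot in c(0.3, -0.9)) {
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    ctr <- sweep(ct, 2, c(20, 30))
    rotated <- sweep(ctr %*% t(R), 2, c(20, 30), `+`)
    diff <- (pca_direction(rotated) - pca_direction(ct) - rot) %% pi
    expect_lt(min(diff, pi - diff), 1e-6)
  }
})

test_that("behavior_features propagates missingness across gaps", {
  # three valid frames, then a no-detection, then two valid frames
  mk <- function(cx, cy, valid = TRUE) {
    structure(list(mask = NULL,
                   contour = if (valid) ellipse_contour(8, 3, 0, center = c(cx, cy)),
                   centroid = if (valid) c(cx, cy),
                   eye = if (valid) c(cx + 6, cy), area = if (valid) 80L else 0L,
                   valid_mask = valid, valid_eye = valid,
                   frame_index = NA_integer_),
              class = "segmentation_result")
  }
  segs <- list(mk(10, 10), mk(13, 14), mk(16, 18), mk(0, 0, valid = FALSE),
               mk(20, 20), mk(21, 20))
  bf <- behavior_features(segs)
  expect_equal(bf$m[2], 5)
  expect_true(is.na(bf$m[1]))          # no previous frame
  expect_true(all(is.na(bf[4, c("m", "r", "r_prime", "theta", "theta_prime")])))
  expect_true(is.na(bf$m[5]))          # previous frame was a no-detection
  expect_equal(bf$m[6], 1)
  expect_equal(bf$r[6], 6)
})
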