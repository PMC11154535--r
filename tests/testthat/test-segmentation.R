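test_that("extract_contour returns the outer boundary points", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  ct <- extract_contour(m)
  expect_equal(nrow(ct), 8L)                 # all of the 3x3 block but center
  expect_false(any(ct[, 1] == 2 & ct[, 2] == 2))

  single <- matrix(0L, 4, 4); single[3, 2] <- 1L
  expect_equal(extract_contour(single), cbind(x = 1L, y = 2L))

  line <- matrix(0L, 3, 7); line[2, 2:6] <- 1L
  lc <- extract_contour(line)
  expect_equal(nrow(lc), 5L)                 # deduplicated walk
  expect_setequal(lc[, 1], 1:5)
  expect_true(all(lc[, 2] == 1))

  expect_null(extract_contour(matrix(0L, 4, 4)))
})

test_that("contour points are foreground pixels with a background 8-neighbor", {
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(15 * 15) > 0.6, 15, 15)
    if (!any(m)) next
    ct <- extract_contour(m)
    for (i in seq_len(nrow(ct))) {
      x <- ct[i, 1]; y <- ct[i, 2]
      expect_true(m[y + 1, x + 1])
      nb <- expand.grid(dx = -1:1, dy = -1:1)
      nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
      has_bg <- any(vapply(seq_len(nrow(nb)), function(k) {
        xx <- x + nb$dx[k]; yy <- y + nb$dy[k]
        xx < 0 || yy < 0 || xx > 14 || yy > 14 || !m[yy + 1, xx + 1]
      }, logical(1)))
      expect_true(has_bg)
    }
    # contour never exceeds the component it came from
    expect_lte(nrow(ct), sum(m))
  }
})

test_that("centroid_of is the exact mean of the contour points", {
  sq <- cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  expect_equal(centroid_of(sq), c(1, 1))
  expect_equal(centroid_of(cbind(x = 5, y = 5)), c(5, 5))
  set.seed(3)
  pts <- cbind(x = rnorm(40), y = rnorm(40))
  expect_equal(centroid_of(pts), c(mean(pts[, 1]), mean(pts[, 2])))
  shift <- pts; shift[, 1] <- shift[, 1] + 3.5; shift[, 2] <- shift[, 2] - 1.25
  expect_equal(centroid_of(shift), centroid_of(pts) + c(3.5, -1.25))
})

test_that("segment_frame finds the animal and reports no-detections", {
  prof <- test_profile()
  cfg <- small_scene_config(speed = 0, turn_sd = 0, noise_sd = 0)
  sc <- generate_scene(cfg)
  seg <- segment_frame(sc$frame(1), scene_profile(cfg), frame_index = 0L)
  expect_true(seg$valid_mask)
  gt <- sc$ground_truth[1, ]
  expect_lt(max(abs(seg$centroid - c(gt$cx, gt$cy))), 1)
  expect_gte(seg$area, nrow(seg$contour))

  # pure background
  bg <- uniform_frame(40, 40, BG_RGB)
  seg0 <- segment_frame(bg, prof)
  expect_false(seg0$valid_mask)
  expect_equal(seg0$area, 0L)

  # two body-colored blobs: the larger becomes region B
  fr <- paint_block(bg, 2, 2, 26, 21, BODY_RGB)    # 25 x 20 = 500 px
  fr <- paint_block(fr, 30, 28, 39, 37, BODY_RGB)  # 10 x 10 = 100 px
  seg2 <- segment_frame(fr, prof)
  expect_equal(seg2$area, 500L)
  expect_equal(seg2$centroid, c(14, 11.5))
})

test_that("segment_frame is deterministic and translation-equivariant", {
  prof <- test_profile()
  bg <- uniform_frame(60, 80, BG_RGB)
  fr1 <- paint_block(bg, 10, 12, 29, 23, BODY_RGB)
  fr1 <- paint_block(fr1, 24, 16, 26, 18, EYE_RGB)
  s1 <- segment_frame(fr1, prof)
  s1b <- segment_frame(fr1, prof)
  expect_identical(s1[c("centroid", "eye", "area", "contour")],
                   s1b[c("centroid", "eye", "area", "contour")])

  dx <- 17; dy <- 9
  fr2 <- paint_block(bg, 10 + dx, 12 + dy, 29 + dx, 23 + dy, BODY_RGB)
  fr2 <- paint_block(fr2, 24 + dx, 16 + dy, 26 + dx, 18 + dy, EYE_RGB)
  s2 <- segment_frame(fr2, prof)
  expect_equal(s2$centroid, s1$centroid + c(dx, dy), tolerance = 1e-9)
  expect_equal(s2$eye, s1$eye + c(dx, dy), tolerance = 1e-9)
})

test_that("detect_eye returns the largest dark component's centroid", {
  prof <- test_profile()
  bg <- uniform_frame(50, 50, BG_RGB)
  fr <- paint_block(bg, 5, 5, 44, 40, BODY_RGB)
  fr <- paint_block(fr, 20, 18, 22, 20, EYE_RGB)   # 3x3 spot centered (21, 19)
  hsv <- cagemon:::to_hsv(fr)
  f <- detect_eye(hsv, rect_spec(c(5, 5), c(44, 40)), prof$eye_range)
  expect_lt(max(abs(f - c(21, 19))), 1)

  # no eye-colored pixels -> absent
  fr0 <- paint_block(bg, 5, 5, 44, 40, BODY_RGB)
  expect_null(detect_eye(cagemon:::to_hsv(fr0), rect_spec(c(5, 5), c(44, 40)),
                         prof$eye_range))

  # two spots: larger one wins
  fr2 <- paint_block(fr, 30, 30, 34, 34, EYE_RGB)  # 5x5 spot centered (32, 32)
  f2 <- detect_eye(cagemon:::to_hsv(fr2), rect_spec(c(5, 5), c(44, 40)),
                   prof$eye_range)
  expect_lt(max(abs(f2 - c(32, 32))), 1)
})

test_that("color backend recovers the synthetic body with high overlap", {
  cfg <- small_scene_config(width = 256, height = 192, semi_axes = c(30, 12),
                            duration = 5)
  sc <- generate_scene(cfg)
  prof <- scene_profile(cfg)
  gt <- sc$ground_truth
  ious <- vapply(c(1, 100, 250), function(i) {
    seg <- segment_frame(sc$frame(i), prof)
    g <- gt[i, ]
    a <- cfg$semi_axes[1] * g$stretch; b <- cfg$semi_axes[2]
    X <- matrix(rep(0:(cfg$width - 1), each = cfg$height), cfg$height)
    Y <- matrix(rep(0:(cfg$height - 1), cfg$width), cfg$height)
    u <- (X - g$cx) * cos(g$orientation) + (Y - g$cy) * sin(g$orientation)
    v <- -(X - g$cx) * sin(g$orientation) + (Y - g$cy) * cos(g$orientation)
    truth <- (u / a)^2 + (v / b)^2 <= 1
    sum(truth & seg$mask) / sum(truth | seg$mask)
  }, numeric(1))
  expect_true(all(ious >= 0.9))
})

test_that("unknown backends and malformed frames are rejected", {
  prof <- test_profile()
  expect_error(segment_frame(uniform_frame(5, 5, BG_RGB), prof,
                             backend = "nope"), "unknown segmentation backend")
  expect_error(segment_frame(array(0, c(0, 5, 3)), prof), "empty")
  expect_true(all(c("color_threshold", "instance_segmentation") %in%
                    segmentation_backends()))
  # adapter is inert without a configured detector
  expect_error(segment_frame(uniform_frame(5, 5, BG_RGB), prof,
                             backend = "instance_segmentation"),
               "no detector configured")
})
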