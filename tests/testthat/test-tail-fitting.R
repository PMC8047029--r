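test_that("rasterized circles are tight, ordered, and include the r=1 ring", {
  c1 <- precomputeCirclePoints(1)
  expect_equal(nrow(c1), 8)   # 8-neighborhood: diagonals round to radius 1
  for (r in c(1, 5, 8, 12)) {
    cp <- precomputeCirclePoints(r)
    expect_true(all(abs(sqrt(cp$x^2 + cp$y^2) - r) <= 0.5))
    expect_true(all(diff(cp$angle) > 0))
  }
  expect_error(precomputeCirclePoints(0.4), ">= 1")
})

test_that("a straight synthetic tail is fitted collinearly at the right spacing", {
  pose <- fishPose(c(100, 60), heading = pi, segmentAngles = numeric(7))
  r <- renderFishFrame(pose, c(160, 120))
  cfg <- tailFitConfig(numTailSegments = 7, pixelPolarity = "darkest",
                       headingDirection = pi)
  pts <- calculateTailPoints(r$frame, pose@centroid, cfg)
  err <- sqrt(rowSums((pts - r$truth$points)^2))
  expect_true(all(err <= 1.5))
  spacing <- sqrt(rowSums(diff(pts)^2))[-1]
  expect_true(all(abs(spacing - 6) <= 1))
})

test_that("the output length contract holds for every configuration", {
  pose <- fishPose(c(80, 80), heading = 0, segmentAngles = numeric(10))
  r <- renderFishFrame(pose, c(160, 160))
  for (n in c(1, 3, 7, 10)) {
    for (m in c("pixel_search", "weighted_median", "center_of_mass")) {
      cfg <- tailFitConfig(numTailSegments = n, method = m,
                           pixelPolarity = "darkest", headingDirection = 0)
      expect_equal(nrow(calculateTailPoints(r$frame, pose@centroid, cfg)),
                   n + 2)
    }
  }
})

test_that("a uniform image yields a deterministic (documented) tie-break", {
  f <- matrix(128, 80, 80)
  cfg <- tailFitConfig(numTailSegments = 4, pixelPolarity = "darkest",
                       headingDirection = 0)
  p1 <- calculateTailPoints(f, c(40, 40), cfg)
  p2 <- calculateTailPoints(f, c(40, 40), cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 6)
})

test_that("all three methods recover curved tails within 2 px RMS", {
  for (s in c(3, 14, 27)) {
    r <- renderAt(s)
    for (m in c("pixel_search", "weighted_median", "center_of_mass")) {
      fit <- fitPose(r, method = m)
      expect_lt(rmsError(fit$points, r$truth$points), 2)
    }
  }
})

test_that("fitting is 90-degree rotation equivariant", {
  r <- renderAt(5)
  f <- r$frame
  h <- nrow(f); w <- ncol(f)
  # rotate frame 90 deg: pixel (x, y) -> (x' = h - 1 - y, y' = x)
  f2 <- matrix(0, w, h)
  for (y in seq_len(h)) f2[, h - y + 1] <- f[y, ]
  cen <- r$pose@centroid
  cen2 <- c(h - 1 - cen[2], cen[1])
  # the reported heading rotates by -pi/2 (x->-y is a clockwise turn in
  # reporting convention)
  cfg <- tailFitConfig(numTailSegments = 7, pixelPolarity = "darkest",
                       headingDirection = (r$pose@heading - pi / 2) %% (2 * pi))
  cfg0 <- tailFitConfig(numTailSegments = 7, pixelPolarity = "darkest",
                        headingDirection = r$pose@heading %% (2 * pi))
  p0 <- calculateTailPoints(f, cen, cfg0)
  p2 <- calculateTailPoints(f2, cen2, cfg)
  mapped <- cbind(h - 1 - p0[, 2], p0[, 1])
  expect_lt(max(sqrt(rowSums((p2 - mapped)^2))), 1.5)
})

test_that("the fitted polyline never doubles back", {
  for (s in 1:10) {
    r <- renderAt(s)
    fit <- fitPose(r)
    d <- diff(fit$points)
    ang <- atan2(d[, 2], d[, 1])
    turn <- abs(wrapAngle(diff(ang)))
    expect_true(all(turn <= 2 * pi / 3 / 2 + 0.2))
  }
})

test_that("a no-detection centroid propagates and offsets are applied last", {
  f <- matrix(200, 60, 60)
  none <- calculateCentroid(f, 250)
  cfg <- tailFitConfig(numTailSegments = 3)
  expect_null(calculateTailPoints(f, none, cfg))

  pose <- fishPose(c(80, 80), heading = 0, segmentAngles = numeric(5))
  r <- renderFishFrame(pose, c(160, 160))
  base <- calculateTailPoints(r$frame, pose@centroid,
                              tailFitConfig(numTailSegments = 5,
                                            pixelPolarity = "darkest",
                                            headingDirection = 0))
  off <- calculateTailPoints(r$frame, pose@centroid,
                             tailFitConfig(numTailSegments = 5,
                                           pixelPolarity = "darkest",
                                           headingDirection = 0,
                                           offsetX = 3, offsetY = -2))
  expect_equal(off[, 1], base[, 1] + 3)
  expect_equal(off[, 2], base[, 2] - 2)
})

test_that("search arcs leaving the frame clamp with a warning", {
  pose <- fishPose(c(60, 60), heading = 0, segmentAngles = numeric(3))
  r <- renderFishFrame(pose, c(120, 120))
  cfg <- tailFitConfig(numTailSegments = 3, pixelPolarity = "darkest",
                       headingDirection = -1, distTailBase = 25)
  # seeding near the corner pushes part of the base circle out of frame
  w <- capture_warnings(pts <- calculateTailPoints(r$frame, c(5, 5), cfg))
  expect_true(any(grepl("clamped", w)))
  expect_equal(nrow(pts), 5)   # the contract survives the clamp
})
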