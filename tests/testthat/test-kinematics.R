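test_that("the rotation-normalized curvature matches the hand-derived example", {
  P <- rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 3))
  th <- calculateTailCurvature(P)
  expect_equal(attr(th, "thetaH"), -pi / 2, tolerance = 1e-9)
  expect_equal(as.numeric(th), c(0, 0, -pi / 4), tolerance = 1e-9)
})

test_that("collinear points give zero curvature and theta1 is always 0", {
  P <- cbind(seq(0, 30, by = 5), seq(0, 60, by = 10))
  expect_equal(as.numeric(calculateTailCurvature(P)), rep(0, 6),
               tolerance = 1e-9)
  set.seed(9)
  for (i in 1:10) {
    P <- cbind(cumsum(runif(6, 1, 4)), cumsum(runif(6, -2, 2)))
    expect_equal(as.numeric(calculateTailCurvature(P))[1], 0,
                 tolerance = 1e-12)
  }
})

test_that("curvature is invariant to global rotation and translation", {
  set.seed(21)
  P <- cbind(cumsum(runif(8, 2, 5)), cumsum(runif(8, -3, 3)))
  th0 <- as.numeric(calculateTailCurvature(P))
  for (i in 1:5) {
    a <- runif(1, -pi, pi); shift <- runif(2, -50, 50)
    R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    P2 <- sweep(P %*% t(R), 2, -shift)
    expect_equal(as.numeric(calculateTailCurvature(P2)), th0,
                 tolerance = 1e-9)
  }
})

test_that("degenerate tail point inputs are rejected", {
  expect_error(calculateTailCurvature(rbind(c(0, 0), c(1, 1))), "3")
  expect_error(calculateTailCurvature(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident")
})

test_that("unwrapping follows the 2*pi offset rule and is idempotent", {
  expect_equal(unwrapCurvature(c(0, 3.04, -3.04)),
               c(0, 3.04, -3.04 + 2 * pi), tolerance = 1e-9)
  smooth <- c(0, 0.3, 0.5, 0.2)
  expect_identical(unwrapCurvature(smooth), smooth)
  x <- c(0, 2.9, -3.0, -2.8, 3.1)
  expect_identical(unwrapCurvature(unwrapCurvature(x)), unwrapCurvature(x))
  u <- unwrapCurvature(x)
  expect_true(all(abs(diff(u)) <= pi))
  expect_error(unwrapCurvature(numeric(0)), "empty")
})

test_that("the tail angle is the mean of the last three segments", {
  expect_equal(tailAngle(c(0, 0, 0, 0)), 0)
  expect_equal(tailAngle(c(0, 0.1, 0.2, 0.3)), 0.2)
  expect_error(tailAngle(c(0, 0.1)), "3")
})

test_that("eye angles match the printed-equation substitution and invariances", {
  e <- data.frame(major = 10, thetaM = pi / 4)
  expect_equal(calculateEyeAngles(e, 0), pi / 4, tolerance = 1e-9)
  # aligned with the rotation frame: angle 0
  expect_equal(calculateEyeAngles(data.frame(major = 3, thetaM = 0), 0), 0)
  # the pi disambiguation keeps results within (-pi/2, pi/2]
  set.seed(4)
  for (i in 1:20) {
    e <- data.frame(major = runif(1, 1, 20), thetaM = runif(1, 0, pi))
    a <- calculateEyeAngles(e, runif(1, -pi, pi))
    expect_true(a > -pi / 2 && a <= pi / 2)
  }
  # homogeneity: the angle of a ray ignores its length
  e2 <- data.frame(major = c(10, 43), thetaM = c(1.1, 1.1))
  expect_equal(diff(calculateEyeAngles(e2, 0.7)), 0)
  expect_error(calculateEyeAngles(data.frame(major = 0, thetaM = 1), 0),
               "positive")
})

test_that("cumulative heading accumulates without wrapping", {
  # eyes symmetric about +x from the centroid: heading 0
  hs <- headingState()
  eyes <- data.frame(x = c(10, 10), y = c(4, 6))
  r <- calculateHeading(hs, centroid = c(5, 5), eyes = eyes)
  expect_equal(r$heading, 0, tolerance = 1e-12)
  # fish rotating 10 deg/frame for 72 frames: cumulative 720 deg
  hs <- headingState(initializeToZero = TRUE)
  total <- NA
  for (k in 0:72) {
    a <- k * 10 * pi / 180
    eyes <- data.frame(x = 5 + 4 * cos(a) + c(0, 0),
                       y = 5 - 4 * sin(a) + c(0, 0))
    r <- calculateHeading(hs, centroid = c(5, 5), eyes = eyes)
    hs <- r$state
    if (k == 0) expect_identical(r$heading, 0)
    total <- r$heading
  }
  expect_equal(total, 720 * pi / 180, tolerance = 1e-9)
})

test_that("heading from tail points matches the curvature theta_h", {
  P <- rbind(c(0, 0), c(0, 1), c(0, 2))
  r <- calculateHeading(headingState(), tailPoints = P)
  expect_equal(r$heading, -pi / 2, tolerance = 1e-12)
})

test_that("heading-trace cleanup excises >180 deg jumps and re-joins the trace", {
  fps <- 332
  t <- seq(0, 1, by = 1 / fps)
  smooth <- 20 * sin(2 * pi * 0.5 * t)
  expect_identical(cleanHeadingTrace(smooth, fps), structure(
    smooth, shifts = data.frame(index = integer(0), shift = numeric(0))))
  # inject a 360 deg single-frame artifact
  x <- smooth
  k <- 150
  x[k:length(x)] <- x[k:length(x)] + 360
  cleaned <- cleanHeadingTrace(x, fps)
  ok <- !is.na(cleaned)
  expect_true(sum(!ok) >= 1)
  expect_lt(max(abs(diff(cleaned[ok]))), 180)
  # continuity across the gap: post-gap start rejoins the pre-gap level
  gap <- which(!ok)
  expect_lt(abs(cleaned[max(gap) + 1] - cleaned[min(gap) - 1]), 5)
  # oracle: re-adding the recorded shifts reproduces the input
  sh <- attr(cleaned, "shifts")
  rec <- cleaned
  rec[(sh$index[1] + 1):length(rec)] <-
    rec[(sh$index[1] + 1):length(rec)] - sh$shift[1]
  expect_equal(rec[ok], x[ok], tolerance = 1e-9)
})

test_that("two consecutive artifacts compose", {
  fps <- 332
  x <- rep(0, 400)
  x[100:length(x)] <- x[100:length(x)] + 360
  x[250:length(x)] <- x[250:length(x)] - 360
  cleaned <- cleanHeadingTrace(x, fps)
  ok <- !is.na(cleaned)
  expect_equal(nrow(attr(cleaned, "shifts")), 2)
  expect_true(all(abs(cleaned[ok]) < 1e-9))
})

test_that("bout segmentation pads by 15 ms, merges overlaps, clips to record", {
  expect_equal(nrow(segmentBouts(rep(FALSE, 100), 332)), 0)
  f <- rep(FALSE, 300); f[101:200] <- TRUE   # frames 100..199, 0-based
  s <- segmentBouts(f, 332)
  expect_equal(s$start, 95)                  # round(0.015*332) = 5
  expect_equal(s$end, 204)
  # two runs 2 frames apart merge after padding
  f2 <- rep(FALSE, 120); f2[11:30] <- TRUE; f2[33:50] <- TRUE
  s2 <- segmentBouts(f2, 332)
  expect_equal(nrow(s2), 1)
  # clipping at the record edges
  f3 <- rep(TRUE, 50)
  s3 <- segmentBouts(f3, 332)
  expect_equal(c(s3$start, s3$end), c(0, 49))
})

test_that("bout features integrate, spread, and keep signs as specified", {
  z <- computeBoutFeatures(rep(0, 100), rep(0, 100),
                           list(start = 10, end = 60), 332)
  expect_equal(c(z$integral, z$sdTail, z$maxAmplitude, z$meanTbf),
               c(0, 0, 0, 0))
  # constant 0.2 rad over a full second at 332 fps: integral 0.2 rad s
  a <- rep(0.2, 332)
  f <- computeBoutFeatures(a, rep(15, 332), list(start = 0, end = 331), 332)
  expect_equal(f$integral, 0.2, tolerance = 1e-9)
  expect_equal(f$meanTbf, 15)
  # symmetric sine: integral ~ 0 but sd and signed max amplitude nonzero
  t <- (0:331) / 332
  sine <- 0.5 * sin(2 * pi * 10 * t)
  fs <- computeBoutFeatures(sine, rep(10, 332), list(start = 0, end = 331),
                            332)
  expect_lt(abs(fs$integral), 1e-3)
  expect_gt(fs$sdTail, 0.3)
  expect_equal(abs(fs$maxAmplitude), 0.5, tolerance = 0.01)
  expect_error(computeBoutFeatures(a, a, list(start = 100, end = 400), 332),
               "inside")
})
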