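test_that("straight-tail poses render a dark stroke through collinear truth points", {
  pose <- fishPose(c(60, 60), heading = 0, segmentAngles = numeric(5))
  r <- renderFishFrame(pose, c(120, 120))
  pts <- r$truth$points
  expect_equal(nrow(pts), 7)
  # heading 0: tail extends along -x at constant y
  expect_true(all(abs(pts[, 2] - 60) < 1e-9))
  expect_true(all(diff(pts[, 1]) < 0))
  # stroke pixels are darker than the background along the polyline
  vals <- r$frame[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)]
  expect_true(all(vals < pose@backgroundIntensity - 50))
})

test_that("all-zero segment angles give a straight ray opposite the heading", {
  pose <- fishPose(c(80, 80), heading = pi / 3, segmentAngles = numeric(6))
  pts <- poseTailPoints(pose)
  dirs <- atan2(-diff(pts[, 2]), diff(pts[, 1]))  # reporting convention
  expect_true(all(abs(wrapAngle(dirs - (pi / 3 + pi))) < 1e-9))
})

test_that("rendering is deterministic for a fixed seed", {
  r1 <- renderAt(7)
  r2 <- renderAt(7)
  expect_identical(r1$frame, r2$frame)
  expect_identical(r1$truth$points, r2$truth$points)
})

test_that("a tail leaving the frame raises an error naming the segment", {
  pose <- fishPose(c(10, 60), heading = pi, segmentAngles = numeric(7))
  # heading pi: tail extends along +x from x=10; fits. Move near right edge:
  pose2 <- fishPose(c(115, 60), heading = pi, segmentAngles = numeric(7))
  expect_error(renderFishFrame(pose2, c(120, 120)), "segment")
  expect_silent(renderFishFrame(pose, c(120, 120)))
})

test_that("swim traces follow the bout model and partition frames exactly", {
  tr <- generateSwimTrace(332, 1, list(), noiseSd = 0)
  expect_true(all(tr$angle == 0))
  expect_true(!any(tr$bout))

  tr <- generateSwimTrace(332, 2, list(
    list(onset = 0.3, duration = 0.8, freq = 20, amplitude = 0.5),
    list(onset = 1.4, duration = 0.4, freq = 10, amplitude = 0.3)))
  # ground-truth flags exactly match the bout windows
  inBout <- (tr$t >= 0.3 & tr$t < 1.1) | (tr$t >= 1.4 & tr$t < 1.8)
  expect_identical(tr$bout, inBout)
  expect_true(all(tr$angle[!tr$bout] == 0))
  # same-direction peak spacing ~ one period = fps/f frames
  pk <- attr(tr, "peakTimes")[[1]]
  expect_true(all(abs(diff(pk) - 1 / (2 * 20)) < 1e-9))
  expect_equal((pk[3] - pk[1]) * 332, 332 / 20, tolerance = 1e-9)
})

test_that("aliasing beat frequencies and overlapping bouts are rejected", {
  expect_error(generateSwimTrace(100, 1, list(
    list(onset = 0, duration = 1, freq = 50, amplitude = 1))), "alias")
  expect_error(generateSwimTrace(100, 2, list(
    list(onset = 0, duration = 1, freq = 5, amplitude = 1),
    list(onset = 0.5, duration = 1, freq = 5, amplitude = 1))), "overlap")
})

test_that("swim traces are reproducible under a fixed seed", {
  b <- list(list(onset = 0.1, duration = 0.5, freq = 15, amplitude = 0.4))
  t1 <- generateSwimTrace(332, 1, b, noiseSd = 0.02, seed = 11)
  t2 <- generateSwimTrace(332, 1, b, noiseSd = 0.02, seed = 11)
  t3 <- generateSwimTrace(332, 1, b, noiseSd = 0.02, seed = 12)
  expect_identical(t1$angle, t2$angle)
  expect_false(identical(t1$angle, t3$angle))
})

test_that("prey paths stay in the arena and alternate run/pause/turn", {
  pp <- generatePreyPaths(6, arena = c(60, 60), duration = 10, fps = 30,
                          seed = 3)
  expect_equal(length(unique(pp$prey)), 6)
  expect_true(all(pp$x >= 0 & pp$x <= 60 & pp$y >= 0 & pp$y <= 60))
  expect_setequal(unique(pp$state), c("run", "pause", "turn"))
  # reproducible
  pp2 <- generatePreyPaths(6, arena = c(60, 60), duration = 10, fps = 30,
                           seed = 3)
  expect_identical(pp, pp2)
})

test_that("zero angular velocity and zero pause give a straight prey path", {
  pp <- generatePreyPaths(1, arena = c(200, 200), duration = 5, fps = 30,
                          seed = 5, pauseRange = c(0, 0),
                          turnRange = c(0, 0))
  # collinearity: cross product of consecutive displacement vectors ~ 0
  dx <- diff(pp$x); dy <- diff(pp$y)
  cross <- head(dx, -1) * tail(dy, -1) - head(dy, -1) * tail(dx, -1)
  expect_true(all(abs(cross) < 1e-9))
})

test_that("bout-feature mixtures validate inputs and reproduce under a seed", {
  cp <- list(list(mean = c(20, 1, 0.3, 0.8), sd = rep(0.1, 4)),
             list(mean = c(5, 4, 1.0, 2.0), sd = rep(0.1, 4)))
  expect_error(generateBoutFeatureClusters(10, cp[1]), "2 classes")
  bad <- cp; bad[[1]]$sd <- c(0.1, 0, 0.1, 0.1)
  expect_error(generateBoutFeatureClusters(10, bad), "positive")
  f1 <- generateBoutFeatureClusters(25, cp, seed = 2)
  f2 <- generateBoutFeatureClusters(25, cp, seed = 2)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 50)
  expect_equal(unname(table(f1$label)), c(25L, 25L), ignore_attr = TRUE)
})

test_that("frame sequences written to disk round-trip through readFrames", {
  dir <- withr::local_tempdir()
  frames <- lapply(1:3, function(i) {
    renderFishFrame(fishPose(c(70, 70), heading = i), c(140, 140))
  })
  saveFrameSequence(frames, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- readFrames(dir)
  expect_length(back, 3)
  # 8-bit PNG quantization only
  expect_lt(max(abs(back[[1]] - frames[[1]]$frame)), 0.51)
  expect_identical(back, readFrames(dir))
})
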