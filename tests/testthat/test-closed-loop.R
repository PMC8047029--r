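cfg332 <- function(gain = 1) {
  calibrateVigorScale(feedbackConfig1D(baselineVelocity = 10, gain = gain,
                                       frameRate = 332))
}

steadyVs <- function(cfg) {
  tr <- generateSwimTrace(332, 3, list(list(onset = 0.5, duration = 2,
                                            freq = 20, amplitude = 1)))
  flags <- detectTailBeats(boutDetector(0.1, 0.05, 332), tr$angle)$bout
  vs <- stimulusVelocity1D(swimVigor(tr$angle, flags, cfg), cfg)
  mean(vs[tr$t >= 1 & tr$t < 2])
}

test_that("vigor is zero for constant angles and outside bouts", {
  cfg <- feedbackConfig1D(frameRate = 332)
  expect_true(all(swimVigor(rep(0.4, 100), rep(TRUE, 100), cfg) == 0))
  t <- (0:331) / 332
  osc <- 0.5 * sin(2 * pi * 20 * t)
  expect_true(all(swimVigor(osc, rep(FALSE, 332), cfg) == 0))
  expect_gt(mean(swimVigor(osc, rep(TRUE, 332), cfg)), 0)
  expect_error(swimVigor(osc[1:2], rep(TRUE, 2),
                         feedbackConfig1D(frameRate = 332)), "window")
})

test_that("the calibrated 20 Hz bout reproduces the three worked gain examples", {
  expect_equal(steadyVs(cfg332(1.0)), -10, tolerance = 0.02 * 10 / 10)
  expect_equal(steadyVs(cfg332(0.5)), 0, tolerance = 0.4)
  expect_equal(steadyVs(cfg332(1.5)), -20, tolerance = 0.02)
})

test_that("baseline-minus-stimulus velocity is exactly linear in gain", {
  vig <- c(0, 0.5, 2, 7)
  base <- calibrateVigorScale(feedbackConfig1D(frameRate = 332))
  drops <- sapply(c(0.5, 1, 1.5, 2), function(g) {
    cfg <- base; cfg@gain <- g
    base@baselineVelocity - stimulusVelocity1D(vig, cfg)
  })
  for (i in seq_along(vig)) {
    expect_equal(drops[i, ] / c(0.5, 1, 1.5, 2),
                 rep(drops[i, 2], 4), tolerance = 1e-12)
  }
  expect_error(stimulusVelocity1D(1, feedbackConfig1D()), "calibrated")
})

test_that("the 2-D velocity law follows the printed orientation factor", {
  cfg <- feedbackConfig2D(baselineVelocity = 10, gain = 1, frameRate = 332)
  tbf <- rep(20, 100)
  # |theta| = 90: the factor is zero regardless of swimming
  expect_true(all(stimulusVelocity2D(tbf, 90, cfg)[-(1:5)] == 10))
  expect_true(all(stimulusVelocity2D(tbf, -90, cfg)[-(1:5)] == 10))
  # theta = 0, boxcar(F) = 20: V_S = 10 - 20 = -10
  v0 <- stimulusVelocity2D(tbf, 0, cfg)
  expect_equal(tail(v0, 1), -10, tolerance = 1e-9)
  # |theta| = 180: factor -1, stimulus speeds up
  v180 <- stimulusVelocity2D(tbf, 180, cfg)
  expect_equal(tail(v180, 1), 10 + 20, tolerance = 1e-9)
  # wrap: theta is taken on [-180, 180)
  expect_equal(tail(stimulusVelocity2D(tbf, 270, cfg), 1),
               tail(stimulusVelocity2D(tbf, -90, cfg), 1))
})

test_that("stimulus angular velocity decays with time since bout onset", {
  expect_equal(stimulusAngularVelocity(0, 1, 0.5), 0)
  expect_equal(stimulusAngularVelocity(0.5, 0.1, 0), 5)
  expect_equal(stimulusAngularVelocity(0.5, 0.5, 0), 1)
  ts <- seq(0.05, 1, by = 0.05)
  vth <- stimulusAngularVelocity(0.5, ts, 0)
  expect_true(all(diff(vth) < 0))
  expect_error(stimulusAngularVelocity(0.5, 0.5, 0.5), "greater")
})

test_that("the gain schedule cycles medium/low/high then medium/high/low", {
  expect_equal(gainSchedule(0), 1.0)
  expect_equal(gainSchedule(3), 0.5)
  expect_equal(gainSchedule(12), 1.5)
  all54 <- gainSchedule(0:53)
  expect_equal(unname(table(all54)), rep(18L, 3), ignore_attr = TRUE)
  # block structure repeats every 18 trials
  expect_equal(all54[1:18], all54[19:36])
  expect_equal(all54[1:18],
               rep(c(1, 0.5, 1.5, 1, 1.5, 0.5), each = 3))
  expect_error(gainSchedule(54), "53")
})

test_that("a 1-D trial log holds V_B without bouts and dips during one", {
  cfg <- cfg332(1)
  n <- 332 * 3
  quiet <- runTrial1D(rep(0, n), cfg, motionStart = 0.5, motionDuration = 2)
  expect_equal(nrow(quiet), n)
  motion <- quiet$t >= 0.5 & quiet$t < 2.5
  expect_true(all(quiet$Vs[motion] == 10))
  expect_true(all(quiet$Vs[!motion] == 0))

  tr <- generateSwimTrace(332, 3, list(list(onset = 1.2, duration = 0.8,
                                            freq = 20, amplitude = 1)))
  log <- runTrial1D(tr$angle, cfg, motionStart = 0.5, motionDuration = 2)
  during <- log$t >= 1.4 & log$t < 1.9
  after <- log$t >= 2.2 & log$t < 2.5
  expect_equal(mean(log$Vs[during]), -10, tolerance = 0.5)
  expect_true(all(abs(log$Vs[after] - 10) < 1e-6))
})
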