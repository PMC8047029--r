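wellSeparated <- function(seed, nPerClass = 20) {
  generateBoutFeatureClusters(nPerClass, list(
    list(mean = c(22, 0.5, 0.25, 0.6), sd = rep(0.08, 4)),   # forward swims
    list(mean = c(12, 3.5, 0.9, 2.2), sd = rep(0.08, 4)),    # routine turns
    list(mean = c(16, 1.6, 0.35, 1.1), sd = rep(0.08, 4))),  # J-turns
    seed = seed)
}

labelAgreement <- function(labels, truth) {
  tab <- table(labels, truth)
  k <- max(nrow(tab), ncol(tab))
  cost <- matrix(0, k, k)
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- -tab
  a <- solveAssignment(cost)
  matched <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (a[i] <= ncol(tab)) tab[i, a[i]] else 0L
  }, numeric(1)))
  matched / length(labels)
}

test_that("planted three-class mixtures select k = 3 with high agreement", {
  f <- wellSeparated(1)
  res <- clusterBouts(f)
  expect_equal(res$chosenK, 3)
  expect_gte(labelAgreement(res$labels, f$label), 0.95)
  expect_equal(res$silhouette$k, 2:10)
  expect_equal(res$chosenK,
               res$silhouette$k[which.max(res$silhouette$score)])
})

test_that("identical bouts give an explicit degenerate result, not a crash", {
  f <- data.frame(meanTbf = rep(10, 20), integral = rep(1, 20),
                  sdTail = rep(0.5, 20), maxAmplitude = rep(1, 20))
  res <- clusterBouts(f)
  expect_true(res$degenerate)
  expect_true(is.na(res$chosenK))
  expect_equal(res$labels, rep(1L, 20))
})

test_that("duplicating every bout leaves the chosen k unchanged", {
  f <- wellSeparated(2)
  r1 <- clusterBouts(f)
  r2 <- clusterBouts(rbind(f, f))
  expect_equal(r1$chosenK, r2$chosenK)
})

test_that("too few bouts shrink the k range with a warning", {
  f <- wellSeparated(3, nPerClass = 3)   # 9 bouts < kmax 10
  expect_warning(res <- clusterBouts(f), "shrinking")
  expect_true(max(res$silhouette$k) <= 8)
  expect_error(clusterBouts(f[1:2, ]), "3 bouts")
})

test_that("cluster mean traces are integral-normalized", {
  f <- wellSeparated(4, nPerClass = 8)
  traces <- lapply(seq_len(nrow(f)), function(i) {
    sgn <- sign(f$integral[i])
    sgn * abs(sin(seq(0, 3 * pi, length.out = 40))) * f$maxAmplitude[i]
  })
  res <- clusterBouts(f, traces = traces)
  expect_length(res$meanTraces, res$chosenK)
  for (m in res$meanTraces) expect_gt(sum(m), 0)
})

test_that("direction splitting follows the integral sign with a tie rule", {
  allPos <- splitJturnDirection(c(0.2, 0.5, 1.1))
  expect_true(all(allPos$direction == "left"))
  # synthetic biased bouts: the split matches the injected bias sign exactly
  tr <- generateSwimTrace(332, 4, list(
    list(onset = 0.3, duration = 0.5, freq = 20, amplitude = 0.3, bias = 0.3),
    list(onset = 1.2, duration = 0.5, freq = 20, amplitude = 0.3, bias = -0.3),
    list(onset = 2.1, duration = 0.5, freq = 20, amplitude = 0.3, bias = 0.3),
    list(onset = 3.0, duration = 0.5, freq = 20, amplitude = 0.3, bias = -0.3)))
  iv <- segmentBouts(tr$bout, 332)
  feats <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i)
    computeBoutFeatures(tr$angle, tr$frequency, iv[i, ], 332)))
  split <- splitJturnDirection(feats$integral, yawAtStart = c(50, -45, 60, -70))
  expect_equal(split$direction, c("left", "right", "left", "right"))
  expect_equal(split$yawAtStart[split$direction == "left"], c(50, 60))
  # antisymmetry: negating every trace swaps the partition
  neg <- splitJturnDirection(-feats$integral)
  expect_true(all(neg$direction != split$direction))
  # zero integral: documented tie rule (right) plus a flag
  tie <- splitJturnDirection(0)
  expect_equal(tie$direction, "right")
  expect_true(tie$tied)
})

test_that("per-fish normalization divides by the fish mean", {
  f <- data.frame(meanTbf = c(2, 4, 10), integral = c(1, 1, 3))
  fish <- c("a", "a", "b")
  norm <- normalizeBoutKinematics(f, fish)
  expect_equal(norm$meanTbf, c(2 / 3, 4 / 3, 1))
  expect_equal(norm$integral, c(1, 1, 1))
  # per-fish means of normalized features are exactly 1
  expect_equal(unname(tapply(norm$meanTbf, fish, mean)), c(1, 1),
               ignore_attr = TRUE)
})

test_that("heuristic cluster naming separates the three canonical types", {
  f <- wellSeparated(6)
  res <- clusterBouts(f)
  nm <- nameBoutClusters(res, f)
  expect_setequal(nm, c("forward swim", "routine turn", "J-turn"))
  # the routine-turn cluster holds the truth class with the largest |integral|
  turnCluster <- which(nm == "routine turn")
  turnTruth <- names(which.max(tapply(abs(f$integral), f$label, mean)))
  agree <- mean(f$label[res$labels == turnCluster] == as.integer(turnTruth))
  expect_gte(agree, 0.95)
})
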