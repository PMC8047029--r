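## Shared fixtures: thresholds matched to the renderer's contrast levels,
## multi-fish composition, and independent brute-force oracles.

# foreground (255 - frame) thresholds for the default render contrasts:
# body weight 0.8 -> fg ~152, tail 0.55 -> ~105, eyes 1.0 -> ~190
BODY_THRESHOLD <- 165
EYE_THRESHOLD <- 215

renderAt <- function(seed, frameSize = c(160, 160), ...) {
  pose <- randomFishPose(seed, frameSize = frameSize, ...)
  c(renderFishFrame(pose, frameSize), list(pose = pose))
}

## dark fish on light background: compose multiple renders by darkest pixel
renderMulti <- function(poses, size) {
  frames <- lapply(poses, function(p) renderFishFrame(p, size)$frame)
  Reduce(pmin, frames)
}

fitPose <- function(render, method = "pixel_search", heading = NULL) {
  pose <- render$pose
  cen <- calculateCentroid(255 - render$frame, BODY_THRESHOLD,
                           minArea = 20, maxArea = 500)
  cfg <- tailFitConfig(numTailSegments = length(pose@segmentAngles),
                       pixelPolarity = "darkest", method = method,
                       headingDirection = heading %||% pose@heading)
  list(centroid = cen,
       points = calculateTailPoints(render$frame, c(cen$x, cen$y), cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmsError <- function(fitted, truth) sqrt(mean(rowSums((fitted - truth)^2)))

## independent exhaustive-permutation assignment oracle
permutationsOf <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(permutationsOf(v[-i]), function(p) c(v[i], p))
  }))
}

bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  best <- NULL; bestCost <- Inf
  for (p in permutationsOf(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestCost) { bestCost <- cc; best <- p }
  }
  list(assignment = best, cost = bestCost)
}

## independent BFS connected-component labeling oracle (4-connectivity is
## deliberately NOT used: EBImage and OpenCV label with 8-connectivity)
ccLabelBFS <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- q[1] + di; jj <- q[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}
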