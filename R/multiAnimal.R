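## Post-hoc multi-animal identity assignment, contact handling, accuracy.

#' Minimum-cost linear sum assignment
#'
#' Solves the square assignment problem (shortest augmenting path / Hungarian
#' method, O(n^3)). Used to match centroids between successive frames by
#' minimizing total Euclidean distance.
#'
#' @param cost numeric square matrix; \code{cost[i, j]} is the cost of
#'   assigning row i to column j.
#' @return integer vector \code{a} with \code{a[i]} the column assigned to
#'   row i.
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square")
  if (n == 0) return(integer(0))
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)           # p[j]: row assigned to column j (1 = virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

#' Assign identities across one frame step
#'
#' Builds the Euclidean cost matrix between the previous frame's identity
#' positions and the current centroids and solves the minimum-total-distance
#' assignment. When fewer centroids than identities are present (fish in
#' contact merge into one blob), each unassigned identity is mapped to its
#' nearest current centroid and every identity sharing a centroid is flagged
#' as a contact.
#'
#' @param prev data.frame with columns \code{id}, \code{x}, \code{y} (one row
#'   per identity; the previous frame's assignment).
#' @param centroids data.frame or matrix of current centroids (columns x, y);
#'   may have fewer rows than \code{prev} (merges) or zero rows (all lost).
#' @return data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{centroidIndex} (row of \code{centroids}, NA when lost),
#'   \code{contact} (logical), \code{lost} (logical).
#' @export
assignIdentities <- function(prev, centroids) {
  k <- nrow(prev)
  cen <- as.matrix(centroids)
  m <- if (length(cen)) nrow(cen) else 0L
  if (m == 0) {
    return(data.frame(id = prev$id, x = NA_real_, y = NA_real_,
                      centroidIndex = NA_integer_, contact = FALSE,
                      lost = TRUE))
  }
  n <- max(k, m)
  cost <- matrix(0, n, n)
  d <- outer(seq_len(k), seq_len(m), function(i, j)
    sqrt((prev$x[i] - cen[j, 1])^2 + (prev$y[i] - cen[j, 2])^2))
  cost[seq_len(k), seq_len(m)] <- d
  a <- solveAssignment(cost)
  ci <- integer(k)
  for (i in seq_len(k)) ci[i] <- if (a[i] <= m) a[i] else NA_integer_
  ## merged centroids: unassigned identities go to their nearest centroid
  for (i in which(is.na(ci))) ci[i] <- which.min(d[i, ])
  contact <- ave(ci, ci, FUN = length) > 1
  data.frame(id = prev$id, x = cen[ci, 1], y = cen[ci, 2],
             centroidIndex = ci, contact = as.logical(contact), lost = FALSE)
}

#' Track identities across a whole recording
#'
#' Chains \code{\link{assignIdentities}} over per-frame centroid sets,
#' starting identities 1..k from the first frame's centroids.
#'
#' @param centroidsByFrame list of per-frame centroid data.frames/matrices
#'   (columns x, y).
#' @return data.frame: \code{frame} (0-based), \code{id}, \code{x}, \code{y},
#'   \code{contact}, \code{lost}. The per-frame contact flags form the
#'   discard mask used for accuracy reporting.
#' @export
trackIdentities <- function(centroidsByFrame) {
  first <- as.matrix(centroidsByFrame[[1]])
  prev <- data.frame(id = seq_len(nrow(first)), x = first[, 1], y = first[, 2])
  out <- vector("list", length(centroidsByFrame))
  out[[1]] <- cbind(frame = 0L, prev, centroidIndex = seq_len(nrow(first)),
                    contact = FALSE, lost = FALSE)
  for (f in seq_along(centroidsByFrame)[-1]) {
    cur <- assignIdentities(prev, centroidsByFrame[[f]])
    out[[f]] <- cbind(frame = f - 1L, cur)
    ok <- !cur$lost
    if (any(ok)) prev <- cur[, c("id", "x", "y")]
  }
  do.call(rbind, out)
}

#' Tracking accuracy report
#'
#' Percent accuracy is the fraction of tracked data points free of
#' fish-to-fish contacts:
#' \code{(total - contacts) / total * 100}.
#'
#' @param totalTrackedDataPoints total tracked data points (> 0).
#' @param numberOfContacts number of contact-flagged data points.
#' @return list with \code{totalTrackedDataPoints}, \code{numberOfContacts},
#'   \code{percentAccuracy}.
#' @examples
#' percentAccuracy(1000, 50)$percentAccuracy  # 95
#' @export
percentAccuracy <- function(totalTrackedDataPoints, numberOfContacts) {
  if (totalTrackedDataPoints <= 0) stop("total must be positive")
  if (numberOfContacts < 0 || numberOfContacts > totalTrackedDataPoints)
    stop("contacts must lie in [0, total]")
  list(totalTrackedDataPoints = totalTrackedDataPoints,
       numberOfContacts = numberOfContacts,
       percentAccuracy = (totalTrackedDataPoints - numberOfContacts) /
         totalTrackedDataPoints * 100)
}

#' Group-level optomotor direction from the center of mass
#'
#' The group's center of mass is the mean of the centroids. The stimulus
#' direction switches to \code{"rightward"} when the center of mass enters
#' the leftmost quarter of the arena and to \code{"leftward"} in the
#' rightmost quarter; anywhere else the previous direction persists
#' (hysteresis).
#'
#' @param centroids matrix/data.frame of centroids (columns x, y), >= 1 row.
#' @param arenaWidth arena extent along x, same units as the centroids.
#' @param previous previous direction, \code{"leftward"} or
#'   \code{"rightward"}.
#' @return the new direction.
#' @export
groupOmrDirection <- function(centroids, arenaWidth,
                              previous = c("rightward", "leftward")) {
  previous <- match.arg(previous)
  cen <- as.matrix(centroids)
  if (nrow(cen) < 1) stop("at least one centroid is required")
  comx <- mean(cen[, 1])
  if (comx < arenaWidth / 4) "rightward"
  else if (comx > 3 * arenaWidth / 4) "leftward"
  else previous
}

#' Expand contact flags into a discard mask
#'
#' Optionally extends each contact event by a configurable number of frames
#' on both sides before discarding, mirroring the removal of contact regions
#' from multi-animal kinematic data.
#'
#' @param identities output of \code{\link{trackIdentities}}.
#' @param padFrames frames discarded around each contact event (default 0).
#' @return logical vector over frames: \code{TRUE} where any identity is in
#'   contact (padded).
#' @export
contactDiscardMask <- function(identities, padFrames = 0) {
  frames <- sort(unique(identities$frame))
  perFrame <- tapply(identities$contact, identities$frame, any)
  mask <- as.logical(perFrame[as.character(frames)])
  if (padFrames > 0 && any(mask)) {
    hits <- which(mask)
    for (h in hits) {
      lo <- max(1, h - padFrames); hi <- min(length(mask), h + padFrames)
      mask[lo:hi] <- TRUE
    }
  }
  mask
}
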