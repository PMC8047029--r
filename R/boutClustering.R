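## Hierarchical clustering of bout features with silhouette model selection.

#' Cluster swim bouts by kinematic features
#'
#' Transforms the four bout features to (mean TBF, |integral|, SD, |max
#' amplitude|) — the left/right direction is deliberately ignored — optionally
#' z-scores them, fits agglomerative hierarchical clustering (Ward linkage on
#' Euclidean distance by default) and cuts the tree at every k in
#' \code{kRange}, choosing the k that maximizes the mean silhouette width.
#'
#' @param features data.frame with columns \code{meanTbf}, \code{integral},
#'   \code{sdTail}, \code{maxAmplitude} (signed values; absolute values are
#'   taken here), one row per bout. At least 12 bouts are expected for a
#'   meaningful model scan.
#' @param kRange candidate cluster counts (default 2:10); shrunk with a
#'   warning when there are fewer bouts than \code{max(kRange)}.
#' @param standardize z-score features before clustering (default
#'   \code{TRUE}; prevents the Hz-scaled feature from dominating the
#'   Euclidean metric).
#' @param linkage \code{stats::hclust} method (default \code{"ward.D2"}).
#' @param traces optional list of per-bout tail-angle traces; per-cluster
#'   mean traces are computed after normalizing each bout so its integral is
#'   positive, resampled to the median trace length.
#' @return object of class \code{"ClusteringResult"}: list with
#'   \code{labels}, \code{chosenK}, \code{silhouette} (data.frame k, score),
#'   \code{degenerate} flag, and \code{meanTraces} (NULL or list by
#'   cluster).
#' @export
clusterBouts <- function(features, kRange = 2:10, standardize = TRUE,
                         linkage = "ward.D2", traces = NULL) {
  X <- cbind(meanTbf = features$meanTbf,
             integral = abs(features$integral),
             sdTail = features$sdTail,
             maxAmplitude = abs(features$maxAmplitude))
  n <- nrow(X)
  if (n < 3) stop("at least 3 bouts are required")
  if (max(kRange) > n - 1) {
    warning("fewer bouts than the maximum cluster count; shrinking k range")
    kRange <- kRange[kRange <= n - 1]
  }
  if (standardize) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- scale(X, center = TRUE, scale = sds)
  }
  D <- dist(X)
  if (max(D) == 0) {
    return(structure(list(labels = rep(1L, n), chosenK = NA_integer_,
                          silhouette = data.frame(k = integer(0),
                                                  score = numeric(0)),
                          degenerate = TRUE, meanTraces = NULL),
                     class = "ClusteringResult"))
  }
  hc <- hclust(D, method = linkage)
  scores <- vapply(kRange, function(k) {
    lab <- cutree(hc, k = k)
    mean(cluster::silhouette(lab, D)[, "sil_width"])
  }, numeric(1))
  chosen <- kRange[which.max(scores)]
  labels <- cutree(hc, k = chosen)
  meanTraces <- NULL
  if (!is.null(traces)) {
    L <- as.integer(median(lengths(traces)))
    norm <- lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      if (features$integral[i] < 0) tr <- -tr
      approx(seq_along(tr), tr, n = L)$y
    })
    meanTraces <- lapply(sort(unique(labels)), function(cl) {
      Reduce(`+`, norm[labels == cl]) / sum(labels == cl)
    })
  }
  structure(list(labels = labels, chosenK = chosen,
                 silhouette = data.frame(k = kRange, score = scores),
                 degenerate = FALSE, meanTraces = meanTraces),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  if (x$degenerate) {
    cat("ClusteringResult: degenerate (all bouts identical)\n")
  } else {
    cat("ClusteringResult: k =", x$chosenK, "over", length(x$labels),
        "bouts; silhouette",
        round(max(x$silhouette$score), 3), "\n")
  }
  invisible(x)
}

#' Split a cluster into left- and right-biased bouts
#'
#' Uses the sign of the unnormalized bout integral: positive integrals
#' (counterclockwise-positive tail angle, the fish's left) are labeled
#' \code{"left"}, negative \code{"right"}. A bout with an exactly zero
#' integral is assigned \code{"right"} by the documented tie rule and
#' flagged.
#'
#' @param integrals unnormalized signed bout integrals, rad s.
#' @param yawAtStart optional per-bout prey yaw (deg) at the bout start
#'   frame, carried through to the output.
#' @return data.frame: \code{direction} ("left"/"right"), \code{tied}
#'   (logical), and \code{yawAtStart} when given.
#' @export
splitJturnDirection <- function(integrals, yawAtStart = NULL) {
  dir <- ifelse(integrals > 0, "left", "right")
  out <- data.frame(direction = dir, tied = integrals == 0,
                    stringsAsFactors = FALSE)
  if (!is.null(yawAtStart)) out$yawAtStart <- yawAtStart
  out
}

#' Normalize bout kinematics per fish
#'
#' Divides every feature by the across-trial mean of that feature for the
#' same fish, so the per-fish mean of each normalized feature is 1.
#'
#' @param features data.frame of numeric bout features.
#' @param fish per-bout fish identifier (same length as rows).
#' @return data.frame of normalized features (columns as input).
#' @export
normalizeBoutKinematics <- function(features, fish) {
  out <- features
  for (col in names(features)) {
    if (!is.numeric(features[[col]])) next
    mu <- ave(features[[col]], fish, FUN = mean)
    out[[col]] <- ifelse(mu == 0, 0, features[[col]] / mu)
  }
  out
}

#' Heuristic cluster naming
#'
#' A reporting convenience, not an algorithmic output: matches clusters to
#' the canonical bout types by comparing cluster-mean kinematics. The
#' cluster with the largest mean |integral| (strong lateral bias) is called
#' the routine turn; among the rest, the one with higher mean TBF is the
#' forward swim and the low-amplitude lateralized remainder the J-turn.
#' With other than three clusters, names are \code{"cluster 1"}, ... .
#'
#' @param result a \code{\link{clusterBouts}} result.
#' @param features the feature frame the result was fit on.
#' @return character vector naming each cluster.
#' @export
nameBoutClusters <- function(result, features) {
  k <- result$chosenK
  if (is.na(k) || k != 3) return(paste("cluster", seq_len(max(1, k, na.rm = TRUE))))
  agg <- function(v) tapply(v, result$labels, mean)
  absint <- agg(abs(features$integral))
  tbf <- agg(features$meanTbf)
  names <- character(3)
  turn <- which.max(absint)
  names[turn] <- "routine turn"
  rest <- setdiff(1:3, turn)
  fwd <- rest[which.max(tbf[rest])]
  names[fwd] <- "forward swim"
  names[setdiff(rest, fwd)] <- "J-turn"
  names
}
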