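#' @include AllClasses.R AllGenerics.R utils-geometry.R
NULL

# k-means++ initial centres (seeded caller-side); falls back to uniform
# resampling when all remaining squared distances are zero.
kmeansppCenters <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums(sweep(pts, 2, centers[1, ])^2)
    for (j in 2:k) {
      idx <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
             else sample.int(n, 1L)
      centers[j, ] <- pts[idx, ]
      d2 <- pmin(d2, rowSums(sweep(pts, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Seeded multi-restart K-means partition
#'
#' Partitions observation points into `k` clusters with Lloyd's algorithm
#' (via [stats::kmeans()], `algorithm = "Lloyd"`, at most 300 iterations),
#' restarted `nRestarts` times from k-means++ initial centres drawn from a
#' seeded RNG; the restart with the lowest total within-cluster sum of
#' squares is kept. Deterministic for a fixed seed. Distances are Euclidean
#' on the coordinates as given (raw lon/lat degrees by default in this
#' package's pipeline).
#'
#' @param points points as accepted by [pointDistances()] (n x 2 matrix,
#'   data.frame with lon/lat, or [OccurrenceRecords-class]).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @param nRestarts number of k-means++ restarts (default 20).
#' @param silhouette if `TRUE` (default) per-point Silhouette widths are
#'   computed for `k >= 2` and stored on the result.
#' @return a [ClusterPartition-class].
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' kmeansPartition(pts, k = 2, seed = 1)
#' @export
kmeansPartition <- function(points, k, seed = 1L, nRestarts = 20L,
                            silhouette = TRUE) {
  pts <- asPointMatrix(points)
  n <- nrow(pts)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n (n = ", n, ")")
  nDistinct <- nrow(unique(pts))
  if (k > nDistinct)
    stop("k exceeds the number of distinct points (", nDistinct, ")")

  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(nRestarts)) {
    fit <- NULL
    for (attempt in 1:10) {   # redraw on degenerate (empty-cluster) starts
      centers <- kmeansppCenters(pts, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(pts, centers = centers,
                                       iter.max = 300L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to find a non-degenerate start")
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  labels <- as.integer(best$cluster)
  sil <- numeric(0)
  msil <- NA_real_
  if (silhouette && k >= 2L) {
    sil <- silhouetteWidths(pts, labels)
    msil <- mean(sil)
  } else if (silhouette && k == 1L) {
    sil <- rep(0, n)   # undefined for a single cluster; stored as 0
    msil <- 0
  }
  new("ClusterPartition", k = k, labels = labels,
      centroids = unname(best$centers), silWidths = sil,
      meanSilhouette = msil, wcss = best$tot.withinss,
      seed = as.integer(seed), nRestarts = as.integer(nRestarts))
}

#' Per-point Silhouette widths
#'
#' For point i with mean distance `a(i)` to the other members of its own
#' cluster and `b(i)` the smallest mean distance to the points of any other
#' cluster, the Silhouette width is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`.
#' Members of singleton clusters get `s(i) = 0` by convention. The mean
#' Silhouette width over all points is the model-selection statistic used by
#' [selectK()].
#'
#' @param points points as accepted by [pointDistances()].
#' @param labels integer cluster label per point; at least two distinct
#'   clusters must be present.
#' @param metric distance metric, see [pointDistances()].
#' @return numeric vector of per-point widths in `[-1, 1]`.
#' @export
silhouetteWidths <- function(points, labels,
                             metric = c("euclidean_degrees",
                                        "haversine_km")) {
  pts <- asPointMatrix(points)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(pts))
  ids <- sort(unique(labels))
  if (length(ids) < 2L)
    stop("silhouette requires at least two clusters")
  D <- pointDistances(pts, pts, metric = match.arg(metric))
  n <- nrow(pts)
  sizes <- as.numeric(table(factor(labels, levels = ids)))
  # n x k matrix of summed distances from each point to each cluster
  member <- outer(labels, ids, "==") * 1
  sums <- D %*% member
  own <- match(labels, ids)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[own[i]]
    if (ni <= 1) { s[i] <- 0; next }             # singleton convention
    a <- sums[i, own[i]] / (ni - 1)              # excludes self (d = 0)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Select the number of clusters by the Silhouette criterion
#'
#' Runs [kmeansPartition()] for each k in `kMin:kMax` and retains the k whose
#' partition maximizes the mean Silhouette width; ties are broken in favour
#' of the smaller k (parsimony). The full profile over k is returned so it
#' can be plotted and inspected, mirroring the usual Silhouette-scan figure.
#'
#' @param points points as accepted by [pointDistances()].
#' @param kMin,kMax scan range; defaults 2 and `min(8, n - 1)`.
#' @param seed integer seed; restart RNG for k is derived as `seed + k` so
#'   the scan is deterministic and each k is independent.
#' @param nRestarts restarts per k (default 20).
#' @param metric distance metric for the Silhouette widths (clustering itself
#'   is Euclidean on the given coordinates).
#' @return list with `k` (selected), `profile` (data.frame `k`,
#'   `meanSilhouette`), and `partition` (the [ClusterPartition-class] for the
#'   selected k).
#' @export
selectK <- function(points, kMin = 2L, kMax = NULL, seed = 1L,
                    nRestarts = 20L,
                    metric = c("euclidean_degrees", "haversine_km")) {
  metric <- match.arg(metric)
  pts <- asPointMatrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to scan cluster numbers")
  kMin <- as.integer(kMin)
  if (is.null(kMax)) kMax <- min(8L, n - 1L)
  kMax <- as.integer(min(kMax, nrow(unique(pts)) - 1L))
  if (kMin < 2L) stop("kMin must be >= 2")
  if (kMax < kMin) stop("kMax must be >= kMin")

  parts <- vector("list", kMax - kMin + 1L)
  msil <- numeric(length(parts))
  for (i in seq_along(parts)) {
    k <- kMin + i - 1L
    p <- kmeansPartition(pts, k, seed = as.integer(seed) + k,
                         nRestarts = nRestarts, silhouette = FALSE)
    sw <- silhouetteWidths(pts, p@labels, metric = metric)
    p@silWidths <- sw
    p@meanSilhouette <- mean(sw)
    parts[[i]] <- p
    msil[i] <- p@meanSilhouette
  }
  bestIdx <- which.max(msil)   # first max -> smallest k on ties
  list(k = kMin + bestIdx - 1L,
       profile = data.frame(k = kMin:kMax, meanSilhouette = msil),
       partition = parts[[bestIdx]])
}

#' Nearest-site (Voronoi) assignment
#'
#' Assigns each query point to the nearest site under the chosen metric;
#' distance ties are broken deterministically in favour of the lowest site
#' index. With cluster centroids as sites this partitions the territory into
#' the clusters' Voronoi cells.
#'
#' @param sites m x 2 matrix of (lon, lat) sites (m >= 1).
#' @param queries query points as accepted by [pointDistances()].
#' @param metric distance metric, see [pointDistances()].
#' @return integer vector of 1-based site indices, one per query.
#' @export
voronoiAssign <- function(sites, queries,
                          metric = c("euclidean_degrees", "haversine_km")) {
  sites <- asPointMatrix(sites)
  if (nrow(sites) < 1L) stop("at least one site required")
  D <- pointDistances(queries, sites, metric = match.arg(metric))
  # max.col on -D picks the per-row minimum; "first" = lowest site index
  max.col(-D, ties.method = "first")
}
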