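#' @include AllClasses.R AllGenerics.R utils-geometry.R
NULL

#' Parameters of a Rossmo geographic-profiling surface
#'
#' The criminal-geographic-targeting score of grid cell j given observations
#' i at distances `d_ij` is
#' `sum_i [ d_ij^(-f)  if d_ij > B;  B^(g-f) * (2B - d_ij)^(-g)  otherwise ]`,
#' i.e. distance decay outside a buffer of radius B around each observation
#' and an increasing term inside it, so that (with `f = g`) each observation
#' contributes a ring-shaped maximum at distance B — events are assumed to
#' occur near, but not at, the anchor point. Distances are clamped below at
#' `epsilonD` so the surface stays finite at the observations themselves.
#'
#' @param bufferKm buffer radius B, in the units of `metric` (km for
#'   haversine); `"auto"` (default) resolves to half the mean
#'   nearest-neighbour distance among the observations, making the buffer
#'   data-adaptive.
#' @param f,g decay exponents (> 0); default 1.2 for both.
#' @param gridNx,gridNy grid resolution (default 200 x 200).
#' @param paddingFraction fraction of the observation bounding-box span added
#'   on each side (default 0.1).
#' @param metric `"haversine_km"` (default) or `"euclidean_degrees"`; with
#'   the latter, B and epsilonD are in degrees.
#' @param epsilonD singularity clamp; `NULL` (default) resolves to half the
#'   grid-cell diagonal at the grid centre.
#' @return a named list of class `"geoprofileParams"`.
#' @export
geoprofileParams <- function(bufferKm = "auto", f = 1.2, g = 1.2,
                             gridNx = 200L, gridNy = 200L,
                             paddingFraction = 0.1,
                             metric = c("haversine_km", "euclidean_degrees"),
                             epsilonD = NULL) {
  metric <- match.arg(metric)
  if (!identical(bufferKm, "auto")) {
    bufferKm <- as.numeric(bufferKm)
    if (!is.finite(bufferKm) || bufferKm <= 0)
      stop("bufferKm must be positive (or \"auto\")")
  }
  stopifnot(f > 0, g > 0, gridNx >= 2, gridNy >= 2, paddingFraction >= 0)
  structure(list(bufferKm = bufferKm, f = f, g = g,
                 gridNx = as.integer(gridNx), gridNy = as.integer(gridNy),
                 paddingFraction = paddingFraction, metric = metric,
                 epsilonD = epsilonD),
            class = "geoprofileParams")
}

# Grid geometry: cell-centre vectors and extent from observation bbox plus
# padding; degenerate spans (single point or collinear set) are widened to a
# minimum span so the grid is always two-dimensional.
profileExtent <- function(pts, paddingFraction, minSpan = 2) {
  bbox <- c(range(pts[, 1]), range(pts[, 2]))
  spanLon <- max(bbox[2] - bbox[1], minSpan)
  spanLat <- max(bbox[4] - bbox[3], minSpan)
  c(lonMin = mean(bbox[1:2]) - spanLon / 2 - paddingFraction * spanLon,
    lonMax = mean(bbox[1:2]) + spanLon / 2 + paddingFraction * spanLon,
    latMin = mean(bbox[3:4]) - spanLat / 2 - paddingFraction * spanLat,
    latMax = mean(bbox[3:4]) + spanLat / 2 + paddingFraction * spanLat)
}

cellCentres <- function(extent, nx, ny) {
  dx <- (extent[2] - extent[1]) / nx
  dy <- (extent[4] - extent[3]) / ny
  list(lon = extent[1] + dx * (seq_len(nx) - 0.5),
       lat = extent[3] + dy * (seq_len(ny) - 0.5), dx = dx, dy = dy)
}

#' Compute a Rossmo geographic profile for a set of observations
#'
#' Evaluates the buffered distance-decay score (see [geoprofileParams()]) of
#' every cell of a regular lon/lat grid spanning the observations plus
#' padding, and normalizes the surface to unit total mass.
#'
#' @param points observations as accepted by [pointDistances()] (>= 1 point).
#' @param params a [geoprofileParams()] list.
#' @param clusterId identifier stored on the result.
#' @param extent optional explicit grid extent
#'   `c(lonMin, lonMax, latMin, latMax)` overriding the padded bounding box.
#' @return a [Geoprofile-class]; `profileParams()` of the result records the
#'   resolved buffer and clamp values.
#' @export
rossmoSurface <- function(points, params = geoprofileParams(),
                          clusterId = "1", extent = NULL) {
  pts <- asPointMatrix(points)
  if (nrow(pts) < 1) stop("at least one observation required")
  if (!inherits(params, "geoprofileParams"))
    stop("params must come from geoprofileParams()")
  nx <- params$gridNx
  ny <- params$gridNy
  if (is.null(extent))
    extent <- unname(profileExtent(pts, params$paddingFraction))
  grid <- cellCentres(extent, nx, ny)

  # resolve buffer: half the mean nearest-neighbour distance
  B <- params$bufferKm
  if (identical(B, "auto")) {
    if (nrow(pts) >= 2) {
      D <- pointDistances(pts, pts, metric = params$metric)
      diag(D) <- Inf
      B <- mean(apply(D, 1, min)) / 2
    } else B <- 0
    if (!is.finite(B) || B <= 0) {
      # duplicate-only or single observation: fall back to extent scale
      corners <- rbind(c(extent[1], extent[3]), c(extent[2], extent[4]))
      B <- pointDistances(corners[1, , drop = FALSE],
                          corners[2, , drop = FALSE],
                          metric = params$metric)[1, 1] / 20
    }
  }

  eps <- params$epsilonD
  if (is.null(eps)) {
    ctr <- c(mean(grid$lon), mean(grid$lat))
    eps <- pointDistances(rbind(ctr), rbind(ctr + c(grid$dx, grid$dy)),
                          metric = params$metric)[1, 1] / 2
  }
  eps <- min(eps, 0.99 * B)   # clamp must stay inside the buffer

  # row-major cell order: lat (row) slow, lon (col) fast
  cells <- cbind(lon = rep(grid$lon, times = ny),
                 lat = rep(grid$lat, each = nx))
  D <- pointDistances(cells, pts, metric = params$metric)
  D <- pmax(D, eps)
  S <- ifelse(D > B, D^(-params$f),
              B^(params$g - params$f) * (2 * B - D)^(-params$g))
  score <- rowSums(S)
  scores <- matrix(score, nrow = ny, ncol = nx, byrow = TRUE)
  scores <- scores / sum(scores)

  resolved <- params
  resolved$bufferKm <- B
  resolved$epsilonD <- eps
  new("Geoprofile", scores = scores, lon = as.numeric(grid$lon),
      lat = as.numeric(grid$lat), extent = as.numeric(extent),
      params = unclass(resolved), clusterId = as.character(clusterId))
}

# Row-major flattening of the score matrix (lat rows slow, lon cols fast),
# matching the deterministic tie-break order used throughout.
flattenScores <- function(gp) as.vector(t(gp@scores))

#' Extract the peak and the top-q probability region of a geoprofile
#'
#' The peak is the maximum-score cell (ties resolved to the lowest row-major
#' cell index); the top region is the smallest set of highest-score cells
#' whose cumulative mass reaches `q` — the analogue of the red
#' highest-probability area on a geoprofiling map.
#'
#' @param gp a [Geoprofile-class].
#' @param q probability mass in (0, 1]; default 0.05.
#' @return an [OriginEstimate-class].
#' @export
estimateOrigin <- function(gp, q = 0.05) {
  stopifnot(is(gp, "Geoprofile"))
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  v <- flattenScores(gp)
  ord <- order(-v)                       # stable: ties keep row-major order
  nTop <- which(cumsum(v[ord]) >= q - 1e-12)[1]
  if (is.na(nTop)) nTop <- length(v)
  topIdx <- ord[seq_len(nTop)]
  nx <- length(gp@lon)
  mask <- matrix(FALSE, nrow = length(gp@lat), ncol = nx)
  mask[cbind((topIdx - 1L) %/% nx + 1L, (topIdx - 1L) %% nx + 1L)] <- TRUE
  peakIdx <- ord[1]
  peak <- c(gp@lon[(peakIdx - 1L) %% nx + 1L],
            gp@lat[(peakIdx - 1L) %/% nx + 1L])
  new("OriginEstimate", peak = peak, topRegion = mask, q = q,
      mass = sum(v[topIdx]))
}

# Grid cell (row, col) containing a coordinate; errors outside the extent.
cellOf <- function(gp, lonlat) {
  e <- gp@extent
  if (lonlat[1] < e[1] || lonlat[1] > e[2] ||
      lonlat[2] < e[3] || lonlat[2] > e[4])
    stop("coordinate (", lonlat[1], ", ", lonlat[2],
         ") lies outside the geoprofile extent")
  nx <- length(gp@lon)
  ny <- length(gp@lat)
  col <- min(nx, max(1L, ceiling((lonlat[1] - e[1]) / ((e[2] - e[1]) / nx))))
  row <- min(ny, max(1L, ceiling((lonlat[2] - e[3]) / ((e[4] - e[3]) / ny))))
  c(row = row, col = col)
}

#' Hit score of a geoprofile against a known origin
#'
#' Fraction of grid cells scored at least as high as the cell containing the
#' true origin. 1/(nx*ny) is a perfect hit (origin in the single top cell);
#' 1 means the surface carries no localization information. Lower is better.
#'
#' @param gp a [Geoprofile-class].
#' @param trueOrigin c(lon, lat); must lie inside the grid extent.
#' @return fraction in (0, 1].
#' @export
hitScore <- function(gp, trueOrigin) {
  stopifnot(is(gp, "Geoprofile"), length(trueOrigin) == 2)
  rc <- cellOf(gp, trueOrigin)
  mean(gp@scores >= gp@scores[rc[1], rc[2]])
}

#' Full per-cluster geoprofiling of an occurrence record set
#'
#' Composes the analysis chain applied at each year cutoff: inclusive year
#' filter, earliest-record extraction per territorial unit and status,
#' Silhouette-based selection of the number of clusters, K-means partition,
#' and one Rossmo surface with origin estimate per cluster.
#'
#' @param rs an [OccurrenceRecords-class] object.
#' @param cutoff inclusive year cutoff (default `Inf`: all records).
#' @param kMin,kMax,seed,nRestarts passed to [selectK()].
#' @param params a [geoprofileParams()] list applied to every cluster.
#' @param q top-region probability mass for [estimateOrigin()].
#' @param status which record stream to profile: `"wild"` (default — the
#'   invasion itself; cultivation localities can then be compared against
#'   the resulting origin areas without circularity), `"cultivated"`, or
#'   `"all"`.
#' @param clusterMetric distance metric for the Silhouette widths.
#' @return list with elements `cutoff`, `records` (the filtered first
#'   records), `selection` (the [selectK()] result), and `clusters` — one
#'   entry per cluster index holding `points`, `geoprofile`
#'   ([Geoprofile-class]) and `origin` ([OriginEstimate-class]).
#' @export
clusterGeoprofiles <- function(rs, cutoff = Inf, kMin = 2L, kMax = NULL,
                               seed = 1L, nRestarts = 20L,
                               params = geoprofileParams(), q = 0.05,
                               status = c("wild", "all", "cultivated"),
                               clusterMetric = "euclidean_degrees") {
  stopifnot(is(rs, "OccurrenceRecords"))
  status <- match.arg(status)
  fr <- firstRecords(filterUntil(rs, cutoff))
  if (status != "all")
    fr <- OccurrenceRecords(recordData(fr)[recordData(fr)$status == status, ,
                                           drop = FALSE],
                            provenance = fr@provenance)
  if (length(fr) == 0) stop("no records remain at cutoff ", cutoff)
  sel <- selectK(fr, kMin = kMin, kMax = kMax, seed = seed,
                 nRestarts = nRestarts, metric = clusterMetric)
  part <- sel$partition
  pts <- asPointMatrix(fr)
  clusters <- lapply(seq_len(part@k), function(i) {
    cpts <- pts[part@labels == i, , drop = FALSE]
    gp <- rossmoSurface(cpts, params = params, clusterId = as.character(i))
    list(cluster = i, n = nrow(cpts), points = cpts, geoprofile = gp,
         origin = estimateOrigin(gp, q = q))
  })
  list(cutoff = cutoff, records = fr, selection = sel, clusters = clusters)
}

#' Export a geoprofile as an ESRI ASCII grid
#'
#' Writes the score matrix in ArcInfo ASCII raster format; when the lon and
#' lat cell sizes differ the GDAL `DX`/`DY` header extension is used instead
#' of `CELLSIZE`.
#'
#' @param gp a [Geoprofile-class].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(gp, path) {
  stopifnot(is(gp, "Geoprofile"))
  e <- gp@extent
  nx <- length(gp@lon)
  ny <- length(gp@lat)
  dx <- (e[2] - e[1]) / nx
  dy <- (e[4] - e[3]) / ny
  hdr <- c(paste("NCOLS", nx), paste("NROWS", ny),
           paste("XLLCORNER", format(e[1], digits = 12)),
           paste("YLLCORNER", format(e[3], digits = 12)))
  hdr <- c(hdr,
           if (abs(dx - dy) < 1e-12) paste("CELLSIZE", format(dx, digits = 12))
           else c(paste("DX", format(dx, digits = 12)),
                  paste("DY", format(dy, digits = 12))),
           "NODATA_VALUE -9999")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # ASCII grids store the northernmost row first
  for (r in rev(seq_len(ny)))
    writeLines(paste(format(gp@scores[r, ], digits = 10), collapse = " "),
               con)
  invisible(path)
}

#' Export a geoprofile as long-format CSV
#'
#' One row per grid cell: `lon,lat,score`.
#'
#' @param gp a [Geoprofile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSurfaceCSV <- function(gp, path) {
  stopifnot(is(gp, "Geoprofile"))
  df <- data.frame(lon = rep(gp@lon, times = length(gp@lat)),
                   lat = rep(gp@lat, each = length(gp@lon)),
                   score = as.vector(t(gp@scores)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an origin estimate as GeoJSON
#'
#' The peak becomes a Point feature; the top-q region a MultiPolygon of the
#' flagged grid-cell rectangles.
#'
#' @param est an [OriginEstimate-class].
#' @param gp the [Geoprofile-class] the estimate was derived from.
#' @param path output path; `NULL` returns the GeoJSON string.
#' @return `path` (invisibly) or the GeoJSON string.
#' @export
originToGeoJSON <- function(est, gp, path = NULL) {
  stopifnot(is(est, "OriginEstimate"), is(gp, "Geoprofile"))
  e <- gp@extent
  nx <- length(gp@lon)
  ny <- length(gp@lat)
  dx <- (e[2] - e[1]) / nx
  dy <- (e[4] - e[3]) / ny
  idx <- which(est@topRegion, arr.ind = TRUE)
  polys <- lapply(seq_len(nrow(idx)), function(i) {
    x0 <- e[1] + (idx[i, 2] - 1) * dx
    y0 <- e[3] + (idx[i, 1] - 1) * dy
    list(list(c(x0, y0), c(x0 + dx, y0), c(x0 + dx, y0 + dy),
              c(x0, y0 + dy), c(x0, y0)))
  })
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = est@peak),
         properties = list(role = "peak")),
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = polys),
         properties = list(role = "top_region", q = est@q,
                           mass = est@mass))))
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
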