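#' @import methods
NULL

REQUIRED_RECORD_COLS <- c("record_id", "tu_id", "tu_name", "lon", "lat",
                          "year", "status", "source")
RECORD_STATUS_LEVELS <- c("cultivated", "wild")

#' Historical occurrence records
#'
#' An ordered collection of dated, georeferenced reports of the species, one
#' row per report. Each record carries the territorial unit (TU; NUTS-3 or
#' GADM unit) it refers to, a representative point in WGS84 decimal degrees,
#' the year of the report (a terminus ante quem: the species was present no
#' later than that year), and whether the report concerns a cultivated or a
#' wild plant. Cultivated and wild records are analysed as separate streams.
#'
#' @slot records data.frame with columns `record_id`, `tu_id`, `tu_name`,
#'   `lon`, `lat`, `year`, `status`, `source`.
#' @slot provenance free-text description of where the records came from.
#'
#' @seealso [OccurrenceRecords()], [readRecords()], [firstRecords()],
#'   [filterUntil()]
#' @export
setClass("OccurrenceRecords",
         representation(records = "data.frame", provenance = "character"))

setValidity("OccurrenceRecords", function(object) {
  df <- object@records
  missing <- setdiff(REQUIRED_RECORD_COLS, names(df))
  if (length(missing) > 0)
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  msgs <- character(0)
  if (anyDuplicated(df$record_id))
    msgs <- c(msgs, "record_id values must be unique")
  bad <- which(!is.finite(df$lon) | df$lon < -180 | df$lon > 180)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("lon out of [-180, 180] in row(s) ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(df$lat) | df$lat < -90 | df$lat > 90)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("lat out of [-90, 90] in row(s) ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(df$year) | df$year < 1500 | df$year > 2100 |
                 df$year != floor(df$year))
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("year must be an integer in [1500, 2100]; row(s) ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!df$status %in% RECORD_STATUS_LEVELS)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("status must be 'cultivated' or 'wild'; row(s) ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
})

#' Partition of observation points into k clusters
#'
#' Result of seeded, multi-restart Lloyd K-means together with the per-point
#' Silhouette widths used for model selection. Labels are 1-based cluster
#' indices; every cluster has at least one member.
#'
#' @slot k number of clusters.
#' @slot labels integer cluster index (1..k) per point.
#' @slot centroids k x 2 matrix of cluster centroids (lon, lat).
#' @slot silWidths per-point Silhouette width in [-1, 1] (singletons get 0).
#' @slot meanSilhouette arithmetic mean of `silWidths`.
#' @slot wcss total within-cluster sum of squares of the retained restart.
#' @slot seed,nRestarts RNG seed and number of restarts used.
#' @export
setClass("ClusterPartition",
         representation(k = "integer", labels = "integer",
                        centroids = "matrix", silWidths = "numeric",
                        meanSilhouette = "numeric", wcss = "numeric",
                        seed = "integer", nRestarts = "integer"))

setValidity("ClusterPartition", function(object) {
  msgs <- character(0)
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (!all(object@labels %in% seq_len(object@k)))
    msgs <- c(msgs, "labels must lie in 1..k")
  if (length(unique(object@labels)) != object@k)
    msgs <- c(msgs, "every cluster must have at least one member")
  if (nrow(object@centroids) != object@k)
    msgs <- c(msgs, "centroids must have k rows")
  if (length(object@silWidths) > 0) {
    if (length(object@silWidths) != length(object@labels))
      msgs <- c(msgs, "silWidths length must equal labels length")
    if (any(object@silWidths < -1 - 1e-12 | object@silWidths > 1 + 1e-12))
      msgs <- c(msgs, "silhouette widths must lie in [-1, 1]")
    if (abs(object@meanSilhouette - mean(object@silWidths)) > 1e-9)
      msgs <- c(msgs, "meanSilhouette must equal mean(silWidths)")
  }
  if (length(msgs) > 0) msgs else TRUE
})

#' Geographic profile (Rossmo probability surface)
#'
#' A regular lon/lat grid of non-negative origin-probability scores for one
#' cluster of observations, normalized to sum to one. High-scoring cells mark
#' the most probable anchor (introduction) area of the events in the cluster.
#'
#' @slot scores ny x nx matrix of cell scores; rows index latitude (south to
#'   north), columns longitude (west to east); sums to 1.
#' @slot lon,lat cell-centre coordinates (length nx resp. ny).
#' @slot extent numeric c(lonMin, lonMax, latMin, latMax) of the grid edges.
#' @slot params the [geoprofileParams()] list the surface was computed with
#'   (including the resolved buffer radius).
#' @slot clusterId identifier of the cluster the surface belongs to.
#' @export
setClass("Geoprofile",
         representation(scores = "matrix", lon = "numeric", lat = "numeric",
                        extent = "numeric", params = "list",
                        clusterId = "character"))

setValidity("Geoprofile", function(object) {
  msgs <- character(0)
  if (nrow(object@scores) != length(object@lat) ||
      ncol(object@scores) != length(object@lon))
    msgs <- c(msgs, "scores must be length(lat) x length(lon)")
  if (any(object@scores < 0))
    msgs <- c(msgs, "scores must be non-negative")
  if (abs(sum(object@scores) - 1) > 1e-9)
    msgs <- c(msgs, "scores must sum to 1 (within 1e-9)")
  if (length(object@extent) != 4)
    msgs <- c(msgs, "extent must be c(lonMin, lonMax, latMin, latMax)")
  if (length(msgs) > 0) msgs else TRUE
})

#' Estimated introduction area extracted from a geoprofile
#'
#' The peak cell and the smallest set of highest-score cells holding at least
#' a fraction `q` of the total probability mass (the map's "red area").
#'
#' @slot peak c(lon, lat) of the maximum-score cell (ties: lowest row-major
#'   index).
#' @slot topRegion logical matrix (same shape as the geoprofile scores)
#'   flagging the top-q cells.
#' @slot q requested probability mass in (0, 1].
#' @slot mass probability mass actually contained in `topRegion` (>= q).
#' @export
setClass("OriginEstimate",
         representation(peak = "numeric", topRegion = "matrix", q = "numeric",
                        mass = "numeric"))

setValidity("OriginEstimate", function(object) {
  msgs <- character(0)
  if (length(object@peak) != 2) msgs <- c(msgs, "peak must be c(lon, lat)")
  if (object@q <= 0 || object@q > 1) msgs <- c(msgs, "q must be in (0, 1]")
  if (object@mass < object@q - 1e-12)
    msgs <- c(msgs, "topRegion mass must be >= q")
  if (length(msgs) > 0) msgs else TRUE
})

#' Per-population haplotype frequency table
#'
#' Populations x haplotypes matrix of percentages (each row sums to 100 up to
#' printed-rounding tolerance), with per-population sample sizes (NA when
#' unknown) and a native/invaded region label per population. Haplotype labels
#' are hyphen-joined allele sizes in locus order, e.g. "122-121".
#'
#' @slot freq numeric matrix, populations x haplotypes, percentages in
#'   [0, 100].
#' @slot n per-population number of called individuals (NA allowed).
#' @slot region per-population region label, "native" or "invaded".
#' @export
setClass("HaplotypeFrequencyTable",
         representation(freq = "matrix", n = "numeric", region = "character"))

setValidity("HaplotypeFrequencyTable", function(object) {
  msgs <- character(0)
  f <- object@freq
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msgs <- c(msgs, "freq must have population rownames and haplotype colnames")
  if (any(f < 0 | f > 100))
    msgs <- c(msgs, "frequencies must lie in [0, 100]")
  rs <- rowSums(f)
  if (any(abs(rs - 100) > 0.05))
    msgs <- c(msgs, paste0("row sums must be 100 +/- 0.05; offending: ",
                           paste(utils::head(rownames(f)[abs(rs - 100) > 0.05], 5),
                                 collapse = ", ")))
  if (length(object@n) != nrow(f) || length(object@region) != nrow(f))
    msgs <- c(msgs, "n and region must have one entry per population")
  if (!all(object@region %in% c("native", "invaded")))
    msgs <- c(msgs, "region must be 'native' or 'invaded'")
  if (length(msgs) > 0) msgs else TRUE
})

#' Ground-truth parameters of a simulated multi-origin invasion
#'
#' Defines origins (introduction points with start years), a distance-decay
#' displacement kernel on the sphere, a constant-rate spread clock that turns
#' displacement distance into year of first record, and a
#' cultivated-near-origin status model. Used by [simulateInvasion()].
#'
#' @slot origins m x 2 matrix of (lon, lat) introduction points.
#' @slot startYears year of introduction per origin.
#' @slot nPoints number of records drawn per origin.
#' @slot scaleKm scale (km) of the displacement kernel.
#' @slot gammaShape shape of a Gamma displacement kernel; NA_real_ selects the
#'   default Exponential(scaleKm) kernel.
#' @slot spreadRateKmYr apparent spread rate (km/year) converting distance to
#'   record-year delay.
#' @slot sigmaYear s.d. (years) of Gaussian noise on the record year.
#' @slot pCultivated probability that a record within `cultivatedBufferKm` of
#'   its origin is a cultivated (garden) record rather than a wild one.
#' @slot cultivatedBufferKm radius (km) of the near-origin cultivated zone.
#' @slot tuTileDeg size (degrees) of the regular tiling used to assign
#'   territorial-unit codes to simulated points.
#' @export
setClass("InvasionScenario",
         representation(origins = "matrix", startYears = "numeric",
                        nPoints = "integer", scaleKm = "numeric",
                        gammaShape = "numeric", spreadRateKmYr = "numeric",
                        sigmaYear = "numeric", pCultivated = "numeric",
                        cultivatedBufferKm = "numeric", tuTileDeg = "numeric"))

setValidity("InvasionScenario", function(object) {
  msgs <- character(0)
  m <- nrow(object@origins)
  if (m < 1) msgs <- c(msgs, "at least one origin required")
  if (ncol(object@origins) != 2) msgs <- c(msgs, "origins must be m x 2")
  if (any(abs(object@origins[, 2]) > 85))
    msgs <- c(msgs, "origin latitude must lie within +/- 85 degrees")
  if (length(object@startYears) != m || length(object@nPoints) != m)
    msgs <- c(msgs, "startYears and nPoints must have one entry per origin")
  if (any(object@nPoints < 1L)) msgs <- c(msgs, "nPoints must be >= 1")
  if (object@scaleKm <= 0) msgs <- c(msgs, "scaleKm must be > 0")
  if (object@spreadRateKmYr <= 0) msgs <- c(msgs, "spreadRateKmYr must be > 0")
  if (object@sigmaYear < 0) msgs <- c(msgs, "sigmaYear must be >= 0")
  if (object@pCultivated < 0 || object@pCultivated > 1)
    msgs <- c(msgs, "pCultivated must be in [0, 1]")
  if (length(msgs) > 0) msgs else TRUE
})
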