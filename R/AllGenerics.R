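#' @include AllClasses.R
NULL

#' Extract the earliest record per territorial unit and status
#'
#' @param x an [OccurrenceRecords-class] object.
#' @param ... passed to methods.
#' @return an object of the same class as `x`.
#' @export
setGeneric("firstRecords", function(x, ...) standardGeneric("firstRecords"))

#' Keep records up to (and including) a cutoff year
#'
#' @param x an [OccurrenceRecords-class] object.
#' @param cutoff integer calendar year; records with `year <= cutoff` are
#'   retained, input order preserved.
#' @param ... passed to methods.
#' @export
setGeneric("filterUntil",
           function(x, cutoff, ...) standardGeneric("filterUntil"))

#' Summary counts for a record set
#'
#' @param x an [OccurrenceRecords-class] object.
#' @param ... passed to methods.
#' @export
setGeneric("summarizeRecords",
           function(x, ...) standardGeneric("summarizeRecords"))

#' Per-haplotype summary of a frequency table
#'
#' @param x a [HaplotypeFrequencyTable-class].
#' @param ... passed to methods.
#' @export
setGeneric("haplotypeSummary",
           function(x, ...) standardGeneric("haplotypeSummary"))

#' Native-vs-invaded contrast of haplotype occurrence
#'
#' @param x a [HaplotypeFrequencyTable-class].
#' @param ... passed to methods.
#' @export
setGeneric("regionContrast",
           function(x, ...) standardGeneric("regionContrast"))

# --- simple accessors ------------------------------------------------------

#' Access the record table of an OccurrenceRecords object
#' @param x an [OccurrenceRecords-class] object.
#' @return data.frame, one row per record.
#' @export
recordData <- function(x) {
  stopifnot(is(x, "OccurrenceRecords"))
  x@records
}

#' @describeIn recordData free-text provenance of the set.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "OccurrenceRecords"))
  x@provenance
}

#' Accessors for ClusterPartition objects
#' @param x a [ClusterPartition-class].
#' @return `clusterLabels`: integer vector of 1-based labels;
#'   `clusterCentroids`: k x 2 matrix; `meanSilhouette`: scalar.
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusterPartition"))
  x@labels
}

#' @describeIn clusterLabels cluster centroids.
#' @export
clusterCentroids <- function(x) {
  stopifnot(is(x, "ClusterPartition"))
  x@centroids
}

#' @describeIn clusterLabels mean Silhouette width of the partition.
#' @export
meanSilhouette <- function(x) {
  stopifnot(is(x, "ClusterPartition"))
  x@meanSilhouette
}

#' Accessors for Geoprofile objects
#' @param x a [Geoprofile-class].
#' @return `profileScores`: ny x nx score matrix; `profileGrid`: list with
#'   `lon`, `lat` cell-centre vectors and `extent`; `profileParams`: the
#'   parameter list used.
#' @export
profileScores <- function(x) {
  stopifnot(is(x, "Geoprofile"))
  x@scores
}

#' @describeIn profileScores grid geometry.
#' @export
profileGrid <- function(x) {
  stopifnot(is(x, "Geoprofile"))
  list(lon = x@lon, lat = x@lat, extent = x@extent)
}

#' @describeIn profileScores parameters (including resolved buffer).
#' @export
profileParams <- function(x) {
  stopifnot(is(x, "Geoprofile"))
  x@params
}

#' Accessors for OriginEstimate objects
#' @param x an [OriginEstimate-class].
#' @return `originPeak`: c(lon, lat); `topRegionMask`: logical matrix.
#' @export
originPeak <- function(x) {
  stopifnot(is(x, "OriginEstimate"))
  x@peak
}

#' @describeIn originPeak logical mask of the top-q region.
#' @export
topRegionMask <- function(x) {
  stopifnot(is(x, "OriginEstimate"))
  x@topRegion
}

#' Accessors for HaplotypeFrequencyTable objects
#' @param x a [HaplotypeFrequencyTable-class].
#' @return `haplotypeFreq`: populations x haplotypes percentage matrix;
#'   `populationRegions`: named region vector; `populationSizes`: named n
#'   vector.
#' @export
haplotypeFreq <- function(x) {
  stopifnot(is(x, "HaplotypeFrequencyTable"))
  x@freq
}

#' @describeIn haplotypeFreq region label per population.
#' @export
populationRegions <- function(x) {
  stopifnot(is(x, "HaplotypeFrequencyTable"))
  stats::setNames(x@region, rownames(x@freq))
}

#' @describeIn haplotypeFreq called sample size per population.
#' @export
populationSizes <- function(x) {
  stopifnot(is(x, "HaplotypeFrequencyTable"))
  stats::setNames(x@n, rownames(x@freq))
}

# --- show methods ----------------------------------------------------------

setMethod("show", "OccurrenceRecords", function(object) {
  df <- object@records
  cat("OccurrenceRecords with", nrow(df), "record(s)\n")
  if (nrow(df) > 0) {
    cat("  years:", min(df$year), "-", max(df$year), "\n")
    cat("  status:", sum(df$status == "cultivated"), "cultivated,",
        sum(df$status == "wild"), "wild\n")
    cat("  territorial units:", length(unique(df$tu_id)), "\n")
  }
  if (length(object@provenance) && nzchar(object@provenance[1]))
    cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition: k =", object@k, "over", length(object@labels),
      "points\n")
  cat("  mean silhouette:", format(object@meanSilhouette, digits = 4),
      " WCSS:", format(object@wcss, digits = 6), "\n")
  cat("  sizes:", paste(tabulate(object@labels, object@k), collapse = ", "),
      "\n")
})

setMethod("show", "Geoprofile", function(object) {
  cat("Geoprofile [cluster ", object@clusterId, "]: ",
      length(object@lat), " x ", length(object@lon), " grid\n", sep = "")
  cat("  extent: lon [", object@extent[1], ", ", object@extent[2],
      "], lat [", object@extent[3], ", ", object@extent[4], "]\n", sep = "")
  pk <- which(object@scores == max(object@scores), arr.ind = TRUE)[1, ]
  cat("  peak at (", format(object@lon[pk[2]], digits = 5), ", ",
      format(object@lat[pk[1]], digits = 5), ")\n", sep = "")
})

setMethod("show", "OriginEstimate", function(object) {
  cat("OriginEstimate: peak (", format(object@peak[1], digits = 5), ", ",
      format(object@peak[2], digits = 5), "); top region q = ", object@q,
      " covers ", sum(object@topRegion), " cell(s), mass ",
      format(object@mass, digits = 4), "\n", sep = "")
})

setMethod("show", "HaplotypeFrequencyTable", function(object) {
  cat("HaplotypeFrequencyTable:", nrow(object@freq), "populations x",
      ncol(object@freq), "haplotypes\n")
  cat("  haplotypes:", paste(colnames(object@freq), collapse = ", "), "\n")
  cat("  regions:", sum(object@region == "native"), "native,",
      sum(object@region == "invaded"), "invaded\n")
})

setMethod("show", "InvasionScenario", function(object) {
  cat("InvasionScenario:", nrow(object@origins), "origin(s),",
      sum(object@nPoints), "points total\n")
  for (i in seq_len(nrow(object@origins)))
    cat(sprintf("  origin %d: (%.2f, %.2f), start %d, n = %d\n", i,
                object@origins[i, 1], object@origins[i, 2],
                as.integer(object@startYears[i]), object@nPoints[i]))
  kern <- if (is.na(object@gammaShape)) sprintf("Exponential(%g km)",
                                                object@scaleKm)
          else sprintf("Gamma(%g, %g km)", object@gammaShape, object@scaleKm)
  cat("  displacement:", kern, " spread:", object@spreadRateKmYr, "km/yr\n")
})

setMethod("length", "OccurrenceRecords", function(x) nrow(x@records))
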