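#' @include AllClasses.R
NULL

# Coerce points input (OccurrenceRecords, data.frame with lon/lat, or
# 2-column matrix) to an n x 2 numeric matrix of (lon, lat).
asPointMatrix <- function(x) {
  if (is(x, "OccurrenceRecords"))
    return(cbind(lon = x@records$lon, lat = x@records$lat))
  if (is.data.frame(x)) {
    if (all(c("lon", "lat") %in% names(x)))
      return(cbind(lon = x$lon, lat = x$lat))
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || ncol(x) != 2 || !is.numeric(x))
    stop("points must be an n x 2 numeric matrix (lon, lat)")
  colnames(x) <- c("lon", "lat")
  x
}

#' Pairwise distance matrix between two point sets
#'
#' @param a,b n x 2 and m x 2 matrices of (lon, lat).
#' @param metric `"euclidean_degrees"` (plain Euclidean distance on raw
#'   decimal degrees) or `"haversine_km"` (great-circle distance in km).
#' @return n x m matrix of distances.
#' @export
pointDistances <- function(a, b,
                           metric = c("euclidean_degrees", "haversine_km")) {
  metric <- match.arg(metric)
  a <- asPointMatrix(a)
  b <- asPointMatrix(b)
  if (metric == "haversine_km") {
    # distHaversine is vectorized over its second argument; iterate over the
    # smaller point set so grid-sized inputs stay fast
    out <- matrix(NA_real_, nrow(a), nrow(b))
    if (nrow(a) <= nrow(b)) {
      for (i in seq_len(nrow(a)))
        out[i, ] <- geosphere::distHaversine(a[i, ], b)
    } else {
      for (j in seq_len(nrow(b)))
        out[, j] <- geosphere::distHaversine(b[j, ], a)
    }
    return(out / 1000)
  }
  # direct coordinate differences (the crossprod expansion loses precision
  # when coordinates are large relative to their separations)
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}
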