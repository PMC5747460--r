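# Independent brute-force oracles used to check the vectorized
# implementations, plus small fixture builders. Kept deliberately naive.

# Per-cell double-loop evaluation of the buffered distance-decay score.
naiveRossmo <- function(pts, lon, lat, B, f, g, eps,
                        metric = "euclidean_degrees") {
  S <- matrix(0, length(lat), length(lon))
  for (r in seq_along(lat)) {
    for (c in seq_along(lon)) {
      s <- 0
      for (i in seq_len(nrow(pts))) {
        d <- if (metric == "haversine_km")
          geosphere::distHaversine(c(lon[c], lat[r]), pts[i, ]) / 1000
        else
          sqrt((lon[c] - pts[i, 1])^2 + (lat[r] - pts[i, 2])^2)
        d <- max(d, eps)
        s <- s + if (d > B) d^(-f) else B^(g - f) * (2 * B - d)^(-g)
      }
      S[r, c] <- s
    }
  }
  S / sum(S)
}

# Group-by-group scan for the earliest record per (tu_id, status).
bruteFirstRecords <- function(df) {
  groups <- split(df, paste(df$tu_id, df$status, sep = "\r"))
  out <- do.call(rbind, lapply(groups, function(g) {
    g <- g[g$year == min(g$year), , drop = FALSE]
    g[order(g$record_id)[1], , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order(out$record_id), , drop = FALSE]
}

# Nearest-site scan, ties to the lowest site index.
bruteNearestSite <- function(sites, queries) {
  vapply(seq_len(nrow(queries)), function(i) {
    d <- sqrt((sites[, 1] - queries[i, 1])^2 +
                (sites[, 2] - queries[i, 2])^2)
    which(d == min(d))[1]
  }, integer(1))
}

# Random well-formed record data.frame.
randomRecords <- function(n, nTU = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    record_id = sprintf("r%03d", sample(n * 10, n)),
    tu_id = sample(sprintf("TU%02d", seq_len(nTU)), n, replace = TRUE),
    tu_name = "tu", lon = round(runif(n, -10, 30), 3),
    lat = round(runif(n, 30, 45), 3),
    year = sample(1700:2010, n, replace = TRUE),
    status = sample(c("cultivated", "wild"), n, replace = TRUE),
    source = "test", stringsAsFactors = FALSE)
}

# Three tight, well-separated Gaussian blobs.
threeBlobs <- function(nPer = 20, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(nPer, centers[i, 1], sd), rnorm(nPer, centers[i, 2], sd))))
}

writeTempCSV <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

recordCSVHeader <- "record_id,tu_id,tu_name,lon,lat,year,status,source"
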