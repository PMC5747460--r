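#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an OccurrenceRecords object from a data.frame
#'
#' @param records data.frame with columns `record_id`, `tu_id`, `tu_name`,
#'   `lon`, `lat`, `year`, `status` (`"cultivated"` or `"wild"`), `source`.
#' @param provenance free-text description of the data source.
#' @return a validated [OccurrenceRecords-class] object.
#' @examples
#' rs <- OccurrenceRecords(data.frame(
#'   record_id = "r1", tu_id = "MT001", tu_name = "Malta", lon = 14.51,
#'   lat = 35.90, year = 1806, status = "cultivated", source = "garden list"))
#' summarizeRecords(rs)
#' @export
OccurrenceRecords <- function(records, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("record_id", "tu_id", "tu_name", "status", "source"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if ("year" %in% names(records)) records[[("year")]] <- as.integer(records$year)
  rownames(records) <- NULL
  new("OccurrenceRecords", records = records[REQUIRED_RECORD_COLS],
      provenance = as.character(provenance))
}

# Numeric parsing that accepts both "." and "," decimal separators (the
# historical tables use comma decimals). Returns NA for unparsable input.
parseDecimal <- function(x) {
  suppressWarnings(as.numeric(gsub(",", ".", trimws(as.character(x)),
                                   fixed = TRUE)))
}

#' Read occurrence records from a delimited text file
#'
#' Reads the occurrence CSV schema
#' `record_id,tu_id,tu_name,lon,lat,year,status,source` (UTF-8; separator
#' auto-detected between comma and semicolon unless given). Coordinates and
#' years written with either "." or "," decimal separators are accepted.
#' Rows that fail to parse or violate the field invariants are collected into
#' a line-numbered report; by default any such row aborts the read.
#'
#' @param path path to the file.
#' @param sep field separator; `NULL` (default) auto-detects "," vs ";" from
#'   the header line.
#' @param lenient if `TRUE`, rows with errors are dropped (with a warning)
#'   instead of aborting; the report is attached as attribute `"rejected"` of
#'   the result.
#' @param provenance provenance string stored on the result (defaults to the
#'   file name).
#' @return an [OccurrenceRecords-class] object.
#' @export
readRecords <- function(path, sep = NULL, lenient = FALSE,
                        provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl(";", header, fixed = TRUE) &&
               !grepl(",", header, fixed = TRUE)) ";" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           encoding = "UTF-8", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(REQUIRED_RECORD_COLS, names(raw))
  if (length(missing) > 0)
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))

  lon <- parseDecimal(raw$lon)
  lat <- parseDecimal(raw$lat)
  year <- parseDecimal(raw$year)
  status <- trimws(raw$status)

  problem <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) == 0) return(NULL)
    # +1 for the header line
    data.frame(line = idx + 1L, record_id = raw$record_id[idx], error = what,
               stringsAsFactors = FALSE)
  }
  rejects <- rbind(
    problem(is.na(lon), "unparsable lon"),
    problem(is.na(lat), "unparsable lat"),
    problem(is.na(year) | year != floor(year), "unparsable year"),
    problem(!is.na(lon) & (lon < -180 | lon > 180), "lon out of [-180, 180]"),
    problem(!is.na(lat) & (lat < -90 | lat > 90), "lat out of [-90, 90]"),
    problem(!is.na(year) & (year < 1500 | year > 2100),
            "year out of [1500, 2100]"),
    problem(!status %in% RECORD_STATUS_LEVELS,
            "status not 'cultivated'/'wild'"))

  if (!is.null(rejects) && nrow(rejects) > 0) {
    report <- paste0("  line ", rejects$line, " (", rejects$record_id, "): ",
                     rejects$error, collapse = "\n")
    if (!lenient)
      stop("row-level error(s) in ", path, ":\n", report)
    warning("dropping ", length(unique(rejects$line)), " row(s) with errors")
    bad <- unique(rejects$line) - 1L
    keep <- setdiff(seq_len(nrow(raw)), bad)
  } else {
    keep <- seq_len(nrow(raw))
  }

  df <- data.frame(record_id = raw$record_id[keep], tu_id = raw$tu_id[keep],
                   tu_name = raw$tu_name[keep], lon = lon[keep],
                   lat = lat[keep], year = as.integer(year[keep]),
                   status = status[keep], source = raw$source[keep],
                   stringsAsFactors = FALSE)
  out <- OccurrenceRecords(df, provenance = provenance)
  attr(out, "rejected") <- rejects
  out
}

#' Write occurrence records as CSV
#'
#' Writes the standard schema with "." decimal separators, UTF-8, header row.
#'
#' @param x an [OccurrenceRecords-class] object.
#' @param path output file path.
#' @param sep field separator (default ",").
#' @return `path`, invisibly.
#' @export
writeRecords <- function(x, path, sep = ",") {
  stopifnot(is(x, "OccurrenceRecords"))
  utils::write.table(x@records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @describeIn firstRecords For each (territorial unit, status) pair keep
#'   exactly the record with the smallest year; ties on year are broken by
#'   the lexicographically smallest `record_id`. Cultivated and wild streams
#'   are independent, so one TU may contribute one record of each status.
#'   The operation is idempotent.
#' @export
setMethod("firstRecords", "OccurrenceRecords", function(x, ...) {
  df <- x@records
  if (nrow(df) == 0) return(x)
  ord <- order(df$tu_id, df$status, df$year, df$record_id, method = "radix")
  sorted <- df[ord, , drop = FALSE]
  keep <- !duplicated(sorted[c("tu_id", "status")])
  out <- sorted[keep, , drop = FALSE]
  # restore original record order for stable, auditable output
  out <- out[order(match(out$record_id, df$record_id)), , drop = FALSE]
  OccurrenceRecords(out, provenance = x@provenance)
})

#' @describeIn filterUntil Inclusive year filter (`year <= cutoff`), order
#'   preserved; `filterUntil(x, Inf)` returns `x` unchanged.
#' @export
setMethod("filterUntil", "OccurrenceRecords", function(x, cutoff, ...) {
  stopifnot(length(cutoff) == 1, is.numeric(cutoff))
  OccurrenceRecords(x@records[x@records$year <= cutoff, , drop = FALSE],
                    provenance = x@provenance)
})

#' @describeIn summarizeRecords Exact counts by status and by territorial
#'   unit, plus the year range. Returns a list with `total`, `cultivated`,
#'   `wild`, `nTU`, `nTUByStatus`, `yearRange`.
#' @export
setMethod("summarizeRecords", "OccurrenceRecords", function(x, ...) {
  df <- x@records
  list(total = nrow(df),
       cultivated = sum(df$status == "cultivated"),
       wild = sum(df$status == "wild"),
       nTU = length(unique(df$tu_id)),
       nTUByStatus = c(
         cultivated = length(unique(df$tu_id[df$status == "cultivated"])),
         wild = length(unique(df$tu_id[df$status == "wild"]))),
       yearRange = if (nrow(df) == 0) c(NA_integer_, NA_integer_)
                   else range(df$year))
})

#' Export records as GeoJSON point features
#'
#' Each record becomes a Point feature carrying all fields as properties;
#' suitable as a map overlay. An optional integer vector of cluster labels is
#' added as property `cluster`.
#'
#' @param x an [OccurrenceRecords-class] object.
#' @param path output path; `NULL` returns the GeoJSON string.
#' @param cluster optional per-record cluster label.
#' @return path (invisibly) or the GeoJSON string.
#' @export
recordsToGeoJSON <- function(x, path = NULL, cluster = NULL) {
  stopifnot(is(x, "OccurrenceRecords"))
  df <- x@records
  if (!is.null(cluster)) stopifnot(length(cluster) == nrow(df))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("lon", "lat")), drop = FALSE])
    if (!is.null(cluster)) props$cluster <- cluster[i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
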