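test_that("well-formed CSVs parse, including comma decimals and semicolons", {
  path <- writeTempCSV(c(recordCSVHeader,
                         'a,TU1,Alpha,14.51,35.90,1806,wild,src',
                         'b,TU2,Beta,-5.35,36.14,1815,wild,src',
                         'c,TU1,Alpha,14.51,35.90,1810,cultivated,src'))
  rs <- readRecords(path)
  expect_s4_class(rs, "OccurrenceRecords")
  expect_equal(length(rs), 3L)
  expect_equal(recordData(rs)$lon[1], 14.51)

  # semicolon separator with comma decimals (the historical-table dialect)
  path2 <- writeTempCSV(c(gsub(",", ";", recordCSVHeader),
                          'a;TU1;Alpha;14,51;35,90;1806;wild;src'))
  rs2 <- readRecords(path2)
  expect_equal(recordData(rs2)$lon, 14.51)
  expect_equal(recordData(rs2)$lat, 35.90)
})

test_that("schema and row-level errors are reported with names and lines", {
  missing <- writeTempCSV(c("record_id,tu_id,tu_name,lon,lat,year,status",
                            "a,TU1,Alpha,1,2,1900,wild"))
  expect_error(readRecords(missing), "source")

  badlat <- writeTempCSV(c(recordCSVHeader,
                           "a,TU1,Alpha,10,91.0,1900,wild,src",
                           "b,TU2,Beta,10,40,1900,wild,src"))
  expect_error(readRecords(badlat), "line 2.*lat")
  rs <- suppressWarnings(readRecords(badlat, lenient = TRUE))
  expect_equal(length(rs), 1L)
  expect_equal(attr(rs, "rejected")$record_id, "a")

  badyear <- writeTempCSV(c(recordCSVHeader,
                            "a,TU1,Alpha,10,40,1423,wild,src"))
  expect_error(readRecords(badyear), "year")
})

test_that("firstRecords keeps the earliest record per (TU, status) stream", {
  df <- data.frame(record_id = c("r1", "r2", "r3"), tu_id = "X",
                   tu_name = "X", lon = 0, lat = 0,
                   year = c(1850, 1820, 1830),
                   status = c("wild", "wild", "cultivated"), source = "s")
  fr <- firstRecords(OccurrenceRecords(df))
  got <- recordData(fr)
  expect_setequal(got$record_id, c("r2", "r3"))   # wild 1820 + cultivated 1830

  # year ties break on the lexicographically smallest record_id
  tie <- df
  tie$year <- 1820
  tie$status <- "wild"
  expect_equal(recordData(firstRecords(OccurrenceRecords(tie)))$record_id,
               "r1")
})

test_that("firstRecords agrees with the brute-force oracle and is idempotent", {
  for (seed in 1:5) {
    df <- randomRecords(60, nTU = 8, seed = seed)
    rs <- OccurrenceRecords(df)
    fr <- firstRecords(rs)
    got <- recordData(fr)
    expect_equal(got[order(got$record_id), ],
                 bruteFirstRecords(df)[names(got)],
                 ignore_attr = TRUE)
    expect_equal(recordData(firstRecords(fr)), got)   # idempotent
    expect_lte(length(fr), length(rs))
    # every discarded record is no earlier than the retained one of its group
    merged <- merge(df, got[c("tu_id", "status", "year")],
                    by = c("tu_id", "status"), suffixes = c("", ".kept"))
    expect_true(all(merged$year >= merged$year.kept))
  }
})

test_that("filterUntil is an inclusive, order-preserving, monotone filter", {
  df <- randomRecords(40, seed = 3)
  df$year <- c(1800L, 1840L, 1841L, df$year[-(1:3)])
  rs <- OccurrenceRecords(df)
  expect_equal(length(filterUntil(rs, 1500)), 0L)
  first3 <- OccurrenceRecords(df[1:3, ])
  expect_equal(recordData(filterUntil(first3, 1840))$record_id,
               df$record_id[1:2])
  expect_equal(recordData(filterUntil(rs, Inf)), recordData(rs))
  cuts <- sort(sample(1700:2010, 6))
  sets <- lapply(cuts, function(cc) recordData(filterUntil(rs, cc))$record_id)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("summarizeRecords counts exactly and totals add up", {
  empty <- OccurrenceRecords(randomRecords(5)[0, ])
  s0 <- summarizeRecords(empty)
  expect_equal(s0$total, 0L)
  expect_equal(unname(s0$nTUByStatus), c(0L, 0L))

  df <- randomRecords(5, seed = 2)
  df$status <- c("cultivated", "cultivated", "wild", "wild", "wild")
  s <- summarizeRecords(OccurrenceRecords(df))
  expect_equal(s$cultivated, 2L)
  expect_equal(s$wild, 3L)
  expect_equal(s$total, s$cultivated + s$wild)
})

test_that("the packaged synthetic reconstruction has the published shape", {
  rs <- syntheticFirstRecords()
  s <- summarizeRecords(rs)
  expect_equal(s$total, 181L)
  expect_equal(unname(s$nTUByStatus["cultivated"]), 30L)
  expect_equal(unname(s$nTUByStatus["wild"]), 151L)
  # the set is already a first-records table
  expect_equal(length(firstRecords(rs)), 181L)
})

test_that("GeoJSON export round-trips coordinates and properties", {
  df <- randomRecords(4, seed = 9)
  rs <- OccurrenceRecords(df)
  gj <- jsonlite::fromJSON(recordsToGeoJSON(rs, cluster = c(1L, 1L, 2L, 2L)),
                           simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 4)
  f1 <- gj$features[[1]]
  expect_equal(unlist(f1$geometry$coordinates), c(df$lon[1], df$lat[1]))
  expect_equal(f1$properties$record_id, df$record_id[1])
  expect_equal(f1$properties$cluster, 1L)
})
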