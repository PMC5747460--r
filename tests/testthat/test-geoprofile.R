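# small helper: explicit params so the oracle sees the same B/eps
smallParams <- function(nx = 10, ny = 10, B = 1, f = 1.2, g = 1.2,
                        eps = 0.05, metric = "euclidean_degrees")
  geoprofileParams(bufferKm = B, f = f, g = g, gridNx = nx, gridNy = ny,
                   metric = metric, epsilonD = eps)

test_that("vectorized surface equals the naive double-loop oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 40, 46))
    metric <- if (rep %% 2 == 0) "haversine_km" else "euclidean_degrees"
    B <- runif(1, 0.5, 3) * if (metric == "haversine_km") 100 else 1
    f <- runif(1, 0.8, 2)
    g <- runif(1, 0.8, 2)
    eps <- B / 20
    gp <- rossmoSurface(pts, smallParams(B = B, f = f, g = g, eps = eps,
                                         metric = metric))
    grid <- profileGrid(gp)
    ref <- naiveRossmo(pts, grid$lon, grid$lat, B = B, f = f, g = g,
                       eps = eps, metric = metric)
    expect_lt(max(abs(profileScores(gp) - ref) / pmax(ref, 1e-300)), 1e-12)
  }
})

test_that("a single observation yields a symmetric ring maximum at d = B", {
  obs <- rbind(c(5, 5))
  gp <- rossmoSurface(obs, smallParams(nx = 81, ny = 81, B = 1),
                      extent = c(1, 9, 1, 9))
  sc <- profileScores(gp)
  grid <- profileGrid(gp)
  d <- sqrt(outer(grid$lat - 5, grid$lon - 5, function(a, b) a^2 + b^2))
  # radial symmetry: scores depend on distance only
  expect_equal(sc, t(sc), tolerance = 1e-12)
  expect_equal(sc[, ncol(sc):1], sc[nrow(sc):1, ], tolerance = 1e-12)
  # maximum attained among the cells closest to the d = B ring
  peakD <- d[which.max(sc)]
  expect_lt(abs(peakD - 1), 0.1)
  # strictly decreasing in d beyond the buffer (compare sorted unique radii)
  outside <- order(d[d > 1.1])
  vOut <- sc[d > 1.1][outside]
  expect_true(all(diff(vOut) <= 1e-15))
})

test_that("mirror-symmetric observations give a mirror-symmetric surface", {
  pts <- rbind(c(-2, 0), c(2, 0))
  gp <- rossmoSurface(pts, smallParams(nx = 40, ny = 20, B = 1),
                      extent = c(-5, 5, -2.5, 2.5))
  sc <- profileScores(gp)
  expect_equal(sc, sc[, ncol(sc):1], tolerance = 1e-12)
})

test_that("surfaces are normalized and non-negative", {
  set.seed(5)
  pts <- cbind(runif(12, 0, 4), runif(12, 0, 4))
  gp <- rossmoSurface(pts, smallParams(nx = 25, ny = 30))
  expect_true(all(profileScores(gp) >= 0))
  expect_equal(sum(profileScores(gp)), 1, tolerance = 1e-9)
  expect_error(rossmoSurface(pts[0, , drop = FALSE], smallParams()),
               "observation")
  expect_error(geoprofileParams(bufferKm = -2), "positive")
})

test_that("contributions add over observations (duplicate-point identity)", {
  set.seed(6)
  pts <- cbind(runif(8, 0, 4), runif(8, 0, 4))
  ext <- c(-1, 5, -1, 5)
  p <- smallParams(nx = 15, ny = 15)
  sDup <- profileScores(rossmoSurface(rbind(pts, pts[3, ]), p, extent = ext))
  sOrig <- profileScores(rossmoSurface(pts, p, extent = ext))
  sOne <- profileScores(rossmoSurface(pts[3, , drop = FALSE], p,
                                      extent = ext))
  # pre-normalization additivity: sDup must be a positive combination of
  # sOrig and sOne with the (unknown) normalizing masses as weights
  X <- cbind(as.vector(sOrig), as.vector(sOne))
  coef <- qr.solve(X, as.vector(sDup))
  expect_true(all(coef > 0))
  expect_lt(max(abs(X %*% coef - as.vector(sDup))), 1e-12)
})

test_that("euclidean surfaces are translation-equivariant", {
  set.seed(7)
  pts <- cbind(runif(10, 0, 3), runif(10, 0, 3))
  shift <- c(11.5, -4.25)
  p <- smallParams(nx = 20, ny = 20)
  ext <- c(-1, 4, -1, 4)
  a <- rossmoSurface(pts, p, extent = ext)
  b <- rossmoSurface(sweep(pts, 2, -shift), p,
                     extent = ext + rep(shift, each = 2))
  expect_equal(profileScores(a), profileScores(b), tolerance = 1e-12)
  expect_equal(originPeak(estimateOrigin(b, 0.1)),
               originPeak(estimateOrigin(a, 0.1)) + shift,
               tolerance = 1e-9)
})

test_that("estimateOrigin extracts the peak and a minimal top-q region", {
  obs <- rbind(c(5, 5))
  gp <- rossmoSurface(obs, smallParams(nx = 61, ny = 61, B = 1),
                      extent = c(1, 9, 1, 9))
  full <- estimateOrigin(gp, q = 1)
  expect_true(all(topRegionMask(full)))

  est <- estimateOrigin(gp, q = 0.05)
  expect_gte(est@mass, 0.05)
  # the top region of a single-observation surface is an annulus around the
  # buffer ring: all flagged cells lie in a distance band about d = B
  idx <- which(topRegionMask(est), arr.ind = TRUE)
  grid <- profileGrid(gp)
  d <- sqrt((grid$lon[idx[, 2]] - 5)^2 + (grid$lat[idx[, 1]] - 5)^2)
  expect_true(all(d > 0.3 & d < 1.7))
  # peak lies inside the top region
  pk <- originPeak(est)
  expect_true(topRegionMask(est)[which(grid$lat == pk[2]),
                                 which(grid$lon == pk[1])])
})

test_that("hitScore spans its (0, 1] range and rejects outside origins", {
  uniform <- new("Geoprofile",
                 scores = matrix(1 / 100, 10, 10), lon = seq(0.5, 9.5),
                 lat = seq(0.5, 9.5), extent = c(0, 10, 0, 10),
                 params = list(), clusterId = "u")
  expect_equal(hitScore(uniform, c(5, 5)), 1)

  obs <- rbind(c(5, 5))
  gp <- rossmoSurface(obs, smallParams(nx = 20, ny = 20, B = 1),
                      extent = c(1, 9, 1, 9))
  pk <- originPeak(estimateOrigin(gp, 0.05))
  nTied <- sum(profileScores(gp) == max(profileScores(gp)))
  expect_equal(hitScore(gp, pk), nTied / 400)
  expect_error(hitScore(gp, c(50, 50)), "extent")
})

test_that("hitScore is stable under grid refinement on smooth surfaces", {
  set.seed(9)
  pts <- cbind(rnorm(30, 10, 0.8), rnorm(30, 44, 0.8))
  origin <- c(10.3, 44.2)
  ext <- c(6, 14, 40, 48)
  h1 <- hitScore(rossmoSurface(pts, smallParams(nx = 50, ny = 50, B = 40,
                                                eps = 2,
                                                metric = "haversine_km"),
                               extent = ext), origin)
  h2 <- hitScore(rossmoSurface(pts, smallParams(nx = 100, ny = 100, B = 40,
                                                eps = 2,
                                                metric = "haversine_km"),
                               extent = ext), origin)
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("surface and origin exports are well-formed", {
  pts <- rbind(c(5, 5), c(6, 5.5))
  gp <- rossmoSurface(pts, smallParams(nx = 12, ny = 8))
  asc <- tempfile(fileext = ".asc")
  writeAsciiGrid(gp, asc)
  hdr <- readLines(asc, n = 7)
  expect_match(hdr[1], "NCOLS 12")
  expect_match(hdr[2], "NROWS 8")
  # non-square lon/lat cells use the DX/DY header extension (7 header lines)
  body <- utils::read.table(asc, skip = 7)
  expect_equal(sum(body), 1, tolerance = 1e-6)

  csv <- tempfile(fileext = ".csv")
  writeSurfaceCSV(gp, csv)
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), 96L)
  expect_equal(sum(long$score), 1, tolerance = 1e-9)

  est <- estimateOrigin(gp, 0.1)
  gj <- jsonlite::fromJSON(originToGeoJSON(est, gp),
                           simplifyVector = FALSE)
  expect_equal(gj$features[[1]]$properties$role, "peak")
  expect_equal(gj$features[[2]]$properties$role, "top_region")
})

test_that("clusterGeoprofiles composes the pipeline per cluster", {
  sc <- invasionScenario(nPoints = 15L)
  sim <- simulateInvasion(sc, seed = 3)
  res <- clusterGeoprofiles(sim$records, cutoff = Inf, seed = 3,
                            params = smallParams(nx = 40, ny = 40, B = 80,
                                                 eps = 5,
                                                 metric = "haversine_km"),
                            q = 0.1, status = "all")
  expect_length(res$clusters, res$selection$k)
  for (cl in res$clusters) {
    expect_s4_class(cl$geoprofile, "Geoprofile")
    expect_s4_class(cl$origin, "OriginEstimate")
    expect_equal(cl$n, nrow(cl$points))
  }
  # a cutoff excluding the late third wave leaves the two early nuclei
  early <- clusterGeoprofiles(sim$records, cutoff = 1842, seed = 3,
                              params = smallParams(nx = 30, ny = 30, B = 80,
                                                   eps = 5,
                                                   metric = "haversine_km"),
                              q = 0.1, status = "all")
  expect_length(early$clusters, 2L)
})
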