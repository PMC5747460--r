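fixturePath <- function()
  system.file("extdata", "oxalis_cpssr_haplotype_frequencies.csv",
              package = "invasiontrace", mustWork = TRUE)

test_that("haplotype calls join allele sizes in locus order", {
  gt <- data.frame(individual_id = c("i1", "i2", "i3"),
                   population_id = "P", region = "invaded",
                   ccmp3 = c(122L, 121L, NA), ccmp4 = c(121L, 122L, 120L))
  calls <- callHaplotypes(gt)
  expect_equal(calls$haplotype, c("122-121", "121-122"))
  excl <- attr(calls, "excluded")
  expect_equal(excl$individual_id, "i3")
  expect_equal(excl$missing_loci, "ccmp3")
  expect_error(callHaplotypes(gt, loci = c("ccmp3", "ccmp9")), "ccmp9")
})

test_that("calls on simulated genotypes recover the simulated truth", {
  pr <- populationProfile("P1", "invaded", 10,
                          c("122-121" = 0.6, "121-122" = 0.4))
  gt <- simulateGenotypes(pr, seed = 5, exactCounts = TRUE)
  calls <- callHaplotypes(gt)
  expect_equal(sort(table(calls$haplotype)),
               sort(table(rep(c("122-121", "121-122"), c(6, 4)))))
})

test_that("frequencyTable computes exact percentages at full precision", {
  calls <- data.frame(
    individual_id = sprintf("i%02d", 1:16),
    population_id = c("solo", rep("pop15", 15)),
    region = "invaded",
    haplotype = c("122-121", rep("122-121", 6), rep("121-122", 9)))
  ft <- frequencyTable(calls)
  f <- haplotypeFreq(ft)
  expect_equal(f["solo", "122-121"], 100)
  expect_equal(f["pop15", "122-121"], 100 * 6 / 15)   # 40%
  expect_equal(f["pop15", "121-122"], 60)
  expect_equal(unname(populationSizes(ft)), c(1, 15))
})

test_that("the Genova-garden composition reproduces its printed values", {
  pr <- populationProfile("Genova O. B.", "invaded", 11,
                          c("122-121" = 7 / 11, "121-122" = 4 / 11))
  ft <- frequencyTable(callHaplotypes(simulateGenotypes(pr, seed = 1,
                                                        exactCounts = TRUE)))
  f <- haplotypeFreq(ft)
  # printed with truncated decimals (63.63 / 36.36); tolerance 0.01
  expect_lt(abs(f[1, "122-121"] - 63.63), 0.01)
  expect_lt(abs(f[1, "121-122"] - 36.36), 0.01)
})

test_that("haplotypeSummary handles the degenerate single-population case", {
  calls <- data.frame(individual_id = "i1", population_id = "P",
                      region = "native", haplotype = "122-121")
  sm <- haplotypeSummary(frequencyTable(calls))
  expect_equal(sm$haplotypes$meanPct, 100)
  expect_equal(sm$haplotypes$nPresent, 1)
  expect_equal(sm$monomorphic$total, 1)
  expect_equal(sm$monomorphic$native, 1)
})

test_that("row sums far from 100 are rejected by the class validity", {
  bad <- matrix(c(50, 30), 1, 2,
                dimnames = list("P", c("122-121", "121-122")))
  expect_error(new("HaplotypeFrequencyTable", freq = bad, n = 1,
                   region = "invaded"),
               "row sums")
})

test_that("the packaged frequency table reproduces its printed summaries", {
  ft <- readFrequencyTable(fixturePath())
  expect_s4_class(ft, "HaplotypeFrequencyTable")
  expect_equal(nrow(haplotypeFreq(ft)), 37L)
  sm <- haplotypeSummary(ft)
  h <- sm$haplotypes
  rownames(h) <- h$haplotype
  expect_lt(abs(h["120-119", "meanPct"] - 1.78), 0.01)
  expect_equal(h["120-119", "nPresent"], 7)
})

test_that("regionContrast separates native and invaded occurrence", {
  ft <- readFrequencyTable(fixturePath())
  rc <- regionContrast(ft)
  tab <- rc$table
  get <- function(hap, reg, col)
    tab[tab$haplotype == hap & tab$region == reg, col]
  # haplotype B occurs only in the invaded range
  expect_equal(get("121-122", "native", "nPresent"), 0)
  expect_equal(get("121-122", "invaded", "nPresent"), 14)
  expect_equal(rc$regions[["121-122"]], "invaded")
  # haplotype E occurs in the native range and four invaded populations
  expect_equal(get("122-120", "native", "nPresent"), 1)
  expect_equal(get("122-120", "invaded", "nPresent"), 4)
  expect_setequal(rc$regions[["122-120"]], c("native", "invaded"))

  # a single-region table degenerates to the global summary
  calls <- data.frame(individual_id = sprintf("i%d", 1:4),
                      population_id = rep(c("P", "Q"), 2),
                      region = "invaded",
                      haplotype = c("122-121", "122-121", "121-122",
                                    "122-121"))
  ft1 <- frequencyTable(calls)
  rc1 <- regionContrast(ft1)
  sub <- rc1$table[rc1$table$region == "invaded", ]
  glob <- haplotypeSummary(ft1)$haplotypes
  expect_equal(sub$meanPct[sub$haplotype == "122-121"],
               glob$meanPct[glob$haplotype == "122-121"])
})

test_that("export rounds to two decimals but internals keep full precision", {
  calls <- data.frame(individual_id = sprintf("i%d", 1:3),
                      population_id = "P", region = "invaded",
                      haplotype = c("122-121", "122-121", "121-122"))
  ft <- frequencyTable(calls)
  expect_equal(haplotypeFreq(ft)[1, "122-121"], 200 / 3)
  path <- tempfile(fileext = ".csv")
  writeFrequencyTable(ft, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back[["122-121"]], 66.67)
})
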