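#' @include AllClasses.R AllGenerics.R
NULL

#' Read a cpSSR genotype table
#'
#' Schema: `individual_id,population_id,region,<locus columns>` with allele
#' sizes in base pairs (positive integers; empty/NA = missing). Extra locus
#' columns beyond the two retained chloroplast loci (ccmp3, ccmp4) are
#' allowed.
#'
#' @param path CSV path.
#' @return data.frame, one row per individual.
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual_id", "population_id", "region")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  loci <- setdiff(names(df), need)
  if (length(loci) == 0) stop("no locus columns found")
  for (l in loci) df[[l]] <- suppressWarnings(as.integer(df[[l]]))
  df
}

#' Call multilocus chloroplast haplotypes from allele sizes
#'
#' The haplotype of an individual is the ordered tuple of its allele sizes at
#' the chosen loci, labelled as hyphen-joined sizes (e.g. "122-121" for
#' ccmp3 = 122, ccmp4 = 121). Individuals missing an allele call at any
#' chosen locus are excluded and reported via the `"excluded"` attribute.
#'
#' @param gt genotype data.frame as returned by [readGenotypes()] or
#'   [simulateGenotypes()].
#' @param loci ordered character vector of locus column names (default the
#'   two retained chloroplast loci `c("ccmp3", "ccmp4")`).
#' @return data.frame `individual_id`, `population_id`, `region`,
#'   `haplotype`; excluded individuals in `attr(, "excluded")`.
#' @export
callHaplotypes <- function(gt, loci = c("ccmp3", "ccmp4")) {
  unknown <- setdiff(loci, names(gt))
  if (length(unknown) > 0)
    stop("unknown locus/loci: ", paste(unknown, collapse = ", "))
  alleles <- as.matrix(gt[loci])
  ok <- rowSums(is.na(alleles)) == 0
  calls <- data.frame(
    individual_id = gt$individual_id[ok],
    population_id = gt$population_id[ok],
    region = gt$region[ok],
    haplotype = apply(alleles[ok, , drop = FALSE], 1, paste, collapse = "-"),
    stringsAsFactors = FALSE)
  excluded <- data.frame(
    individual_id = gt$individual_id[!ok],
    population_id = gt$population_id[!ok],
    missing_loci = vapply(which(!ok), function(i)
      paste(loci[is.na(alleles[i, ])], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(calls, "excluded") <- excluded
  calls
}

#' Build a per-population haplotype frequency table from calls
#'
#' Percentages are `100 * count / n` per population at full precision
#' (rounding to two decimals happens only on export via
#' [writeFrequencyTable()]). Populations with fewer than `minN` called
#' individuals are flagged via the `"smallPopulations"` attribute but kept.
#'
#' @param calls data.frame from [callHaplotypes()].
#' @param minN minimum called sample size before a population is flagged
#'   (default 1).
#' @return a [HaplotypeFrequencyTable-class].
#' @export
frequencyTable <- function(calls, minN = 1L) {
  stopifnot(nrow(calls) >= 1)
  pops <- unique(calls$population_id)
  haps <- sort(unique(calls$haplotype))
  counts <- table(factor(calls$population_id, levels = pops),
                  factor(calls$haplotype, levels = haps))
  n <- rowSums(counts)
  freq <- sweep(unclass(counts), 1, n, "/") * 100
  region <- calls$region[match(pops, calls$population_id)]
  if (anyNA(region) || !all(region %in% c("native", "invaded")))
    stop("missing/invalid region label for population(s): ",
         paste(pops[is.na(region) | !region %in% c("native", "invaded")],
               collapse = ", "))
  ft <- new("HaplotypeFrequencyTable", freq = freq, n = as.numeric(n),
            region = as.character(region))
  attr(ft, "smallPopulations") <- pops[n < minN]
  ft
}

#' Load a per-population haplotype frequency table from CSV
#'
#' Schema: `population,region,n,<haplotype label columns>`; percentages may
#' use "." or "," decimal separators; `n` may be NA when the per-population
#' sample size is not reported.
#'
#' The package ships such a table at
#' `system.file("extdata", "oxalis_cpssr_haplotype_frequencies.csv",
#' package = "invasiontrace")`: published chloroplast (ccmp3-ccmp4)
#' haplotype frequencies for 37 *Oxalis pes-caprae* populations spanning the
#' native South African and the invaded Euro-Mediterranean range,
#' transcribed with their printed (truncated) decimals.
#'
#' @param path CSV path.
#' @return a [HaplotypeFrequencyTable-class].
#' @export
readFrequencyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("population", "region", "n")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  haps <- setdiff(names(df), need)
  freq <- as.matrix(as.data.frame(lapply(df[haps], parseDecimal)))
  colnames(freq) <- haps
  rownames(freq) <- df$population
  new("HaplotypeFrequencyTable", freq = freq,
      n = suppressWarnings(as.numeric(df$n)),
      region = as.character(df$region))
}

#' Write a haplotype frequency table as CSV
#'
#' Percentages are rounded to two decimals on export.
#'
#' @param ft a [HaplotypeFrequencyTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(ft, path) {
  stopifnot(is(ft, "HaplotypeFrequencyTable"))
  df <- data.frame(population = rownames(ft@freq), region = ft@region,
                   n = ft@n, round(ft@freq, 2), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn haplotypeSummary Per-haplotype mean frequency across ALL
#'   populations (zeros included, matching the printed MEAN convention),
#'   count of populations where the haplotype is present (> 0), presence by
#'   region, and the number of monomorphic populations (a single haplotype
#'   at 100%) overall and by region. Returns a list with `haplotypes` (a
#'   data.frame) and `monomorphic`.
#' @export
setMethod("haplotypeSummary", "HaplotypeFrequencyTable", function(x, ...) {
  f <- x@freq
  present <- f > 0
  mono <- rowSums(present) == 1L
  out <- data.frame(haplotype = colnames(f), stringsAsFactors = FALSE)
  out$meanPct <- colMeans(f)
  out$sumPct <- colSums(f)
  out$nPresent <- colSums(present)
  out$nPresentNative <- colSums(present[x@region == "native", , drop = FALSE])
  out$nPresentInvaded <- colSums(present[x@region == "invaded", , drop = FALSE])
  list(haplotypes = out,
       monomorphic = list(
         total = sum(mono),
         native = sum(mono & x@region == "native"),
         invaded = sum(mono & x@region == "invaded"),
         populations = rownames(f)[mono]))
})

#' @describeIn regionContrast Per-haplotype, per-region population counts
#'   with presence counts and mean percentages; `regions` lists, for each
#'   haplotype, the regions in which it occurs at all.
#' @export
setMethod("regionContrast", "HaplotypeFrequencyTable", function(x, ...) {
  f <- x@freq
  regions <- c("native", "invaded")
  rows <- do.call(rbind, lapply(regions, function(r) {
    sub <- f[x@region == r, , drop = FALSE]
    data.frame(haplotype = colnames(f), region = r,
               nPopulations = nrow(sub),
               nPresent = colSums(sub > 0),
               meanPct = if (nrow(sub) > 0) colMeans(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  presence <- lapply(colnames(f), function(h)
    regions[vapply(regions, function(r)
      any(f[x@region == r, h] > 0), logical(1))])
  names(presence) <- colnames(f)
  list(table = rows, regions = presence)
})

#' Default presentation aliases for the retained chloroplast haplotypes
#'
#' Maps hyphen-joined ccmp3-ccmp4 allele-size labels to the single-letter
#' names conventionally used for this marker system. Purely a presentation
#' mapping; all computation uses the size labels.
#'
#' @return named character vector (size label -> letter).
#' @export
haplotypeAliases <- function() {
  c("122-121" = "A", "121-122" = "B", "121-120" = "C",
    "120-119" = "D", "122-120" = "E")
}
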