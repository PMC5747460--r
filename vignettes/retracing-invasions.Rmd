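---
title: "Retracing a multi-origin invasion from historical first records"
author: "invasiontrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retracing a multi-origin invasion from historical first records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasiontrace)
```

## The problem

Where did an invasion start? For species that spread over decades or
centuries, the only spatially extensive evidence is often the historical
record: herbarium sheets, floras, garden catalogues — each one a dated,
georeferenced report that the species was present in some administrative
unit *no later than* a given year (a terminus ante quem). `invasiontrace`
turns such records into quantitative statements about the number of
independent introductions and the most probable introduction areas, and
cross-checks them against uniparentally inherited chloroplast
microsatellite (cpSSR) haplotypes sampled from extant populations. The
motivating system is the Euro-Mediterranean invasion of the South African
geophyte *Oxalis pes-caprae*, long attributed — on anecdote — to a single
garden plant on Malta.

## Data model

An `OccurrenceRecords` object holds one row per report: territorial unit
(TU; NUTS-3 in Europe, GADM elsewhere), a single representative point in
WGS84 decimal degrees, an integer year, and a status flag separating
`cultivated` (garden) from `wild` records — the two streams are always
analysed independently, since a cultivation event is evidence about
propagule sources, not about spread. Three transformations cover the
bookkeeping:

* `firstRecords()` keeps exactly the earliest record per (TU, status)
  pair. Later reports from an already-reported unit carry no information
  about arrival and would over-weight well-surveyed places. Year ties are
  broken by the lexicographically smallest `record_id` — an arbitrary but
  deterministic and auditable rule.
* `filterUntil()` is the inclusive diachronic cutoff (`year <= cutoff`)
  behind "situation as known by 1840/1880/today" snapshots.
* `summarizeRecords()` gives exact counts by status and by TU.

Sources that date a record only to a decade are stored with the earliest
defensible year; the schema deliberately holds a single integer year and a
single point per record (units are mapped as points, not polygons).
`readRecords()` accepts both `.` and `,` decimal separators because
historical compilations commonly use comma decimals.

## How many introductions? K-means + Silhouette

The observation points at a given cutoff are partitioned with Lloyd
K-means (`kmeansPartition()`; at most 300 iterations, best of 20 restarts
from k-means++ starts drawn from a seeded RNG, so every result is exactly
reproducible). The number of clusters is chosen by the mean Silhouette
width (`selectK()`):

$$ s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))} $$

with \(a(i)\) the mean distance of point \(i\) to its own cluster's other
members and \(b(i)\) the smallest mean distance to any other cluster.
Members of singleton clusters get \(s(i) = 0\) (the standard convention).
The scan covers \(k = 2, \dots, \min(8, n-1)\); ties on the mean width go
to the smaller \(k\) (parsimony). The full profile over \(k\) is returned
so that near-ties — which are common, and scientifically meaningful — are
visible rather than hidden behind a single winner.

Distances for clustering and Silhouette default to plain Euclidean
distance on raw lon/lat degrees. That mirrors how coordinate CSVs are
almost always fed to off-the-shelf K-means in this literature, and at
Mediterranean latitudes the longitude compression (~0.8) does not change
the cluster structure; a metrically correct haversine option
(`metric = "haversine_km"`) is available for the Silhouette widths and for
all geoprofiling.

## Where did each cluster start? The Rossmo geoprofile

For each cluster, `rossmoSurface()` scores every cell \(j\) of a regular
lon/lat grid as a candidate anchor (introduction) point of the cluster's
events, using the criminal-geographic-targeting form

$$ S_j = \sum_i \begin{cases}
  d_{ij}^{-f} & d_{ij} > B \\
  B^{\,g-f} \, (2B - d_{ij})^{-g} & d_{ij} \le B
\end{cases} $$

— distance decay away from each observation, but an *increasing* term
inside a buffer of radius \(B\), encoding the assumption that events
cluster near, not at, their source. With \(f = g\) (the default) each
observation contributes a ring-shaped maximum at \(d = B\) and the score
is continuous across the buffer edge. The surface is normalized to unit
mass and interpreted as a relative origin-probability map.

Tunable parameters, defaults, and the reasoning behind them
(`geoprofileParams()`):

* `f = g = 1.2`: conventional mild decay; nothing in the historical-record
  setting justifies a sharper kernel.
* `bufferKm = "auto"`: half the mean nearest-neighbour distance among the
  cluster's observations. This adapts the buffer to the sampling density
  instead of hard-coding a kilometre value; a fixed `B` can be supplied.
* grid 200 × 200, padding 10% of the bounding-box span per side: fine
  enough that peak positions are limited by the data, not the raster.
* `metric = "haversine_km"`: great-circle distances for surfaces, where
  kilometres (not degrees) are the meaningful unit.
* `epsilonD`: distances are clamped below at half the grid-cell diagonal,
  keeping \(d^{-f}\) finite at cells containing an observation. Clamping
  (rather than excluding cells) keeps the surface defined everywhere; the
  clamp is also capped below `B` so clamped cells stay inside the buffer
  branch. The resolved `B` and clamp are stored on every `Geoprofile`.
* Cells are lon/lat-regular; the variation of physical cell area with
  latitude is ignored in the normalization, matching pixel-based practice.
  Scores are per-cell quantities.

`estimateOrigin()` extracts the peak cell (ties: lowest row-major index)
and the smallest set of top-scoring cells holding a fraction `q` (default
0.05) of the total mass — the operational version of the "highest
probability area" shaded on geoprofiling maps. `hitScore()` evaluates a
surface against a known origin as the fraction of cells scoring at least
as high as the origin's cell: 1/(number of cells) is perfect, 1 is
uninformative.

`clusterGeoprofiles()` composes the whole chain at one cutoff:
filter, first records, Silhouette scan, partition, one surface and origin
estimate per cluster. It profiles the **wild** stream by default: the
correspondence between inferred origin areas and historically documented
cultivation sites is then an independent result, not a circularity.
`voronoiAssign()` partitions the territory among cluster centroids
(nearest-site assignment, ties to the lowest site index); cell polygons
are not constructed — assignment is all the analysis needs, and exact
spherical Voronoi polygons are out of scope.

## cpSSR haplotypes

`callHaplotypes()` forms each individual's haplotype as the ordered tuple
of allele sizes at the retained chloroplast loci (default ccmp3, ccmp4),
labelled `"122-121"` style; individuals missing any chosen locus are
excluded and reported, never silently dropped. `frequencyTable()` keeps
full-precision percentages internally and rounds only on export.
`haplotypeSummary()` follows the printed-table conventions of this
literature: the per-haplotype mean is taken over **all** populations,
zeros included; a population is monomorphic when a single haplotype is at
100%; presence means frequency > 0. `regionContrast()` splits all of this
by native versus invaded range. Letter aliases (A–E) for the size-pair
labels are a presentation mapping only (`haplotypeAliases()`).

The packaged table
(`inst/extdata/oxalis_cpssr_haplotype_frequencies.csv`) transcribes a
published 37-population survey with its printed truncated decimals; row
sums are therefore 100 ± 0.05 rather than exactly 100, and comparisons
against printed numbers should use an absolute tolerance of 0.01
percentage points (printed values are inconsistently truncated/rounded).
Sample sizes per population were not published and are stored as NA; all
summaries are population-level means, which is what the printed summary
rows are.

## The simulator: what it emulates, and what it does not

`invasionScenario()` / `simulateInvasion()` generate occurrence records
with known ground truth. The default scenario encodes the study
conditions used throughout the tests: three origins more than 1000 km
apart — southern Iberia (start 1780), the Sicily/Malta area (1800), and
the western Anatolian coast (1845) — with 40 records each. Displacement
from the origin is exponential with scale 150 km (long-tailed,
harbour-mediated jumps rather than diffusive creep; a Gamma kernel is
available), bearing uniform, geometry by the exact spherical
destination-point formula. The year of first record is
`start + distance / 8 km·yr⁻¹ + N(0, 5 yr)`, rounded and floored at the
start year — an apparent spread rate that stretches a ~150 km
displacement into a couple of decades of record lag, consistent with a
two-century invasion. Records within 50 km of their origin are cultivated
with probability 0.15, mimicking gardens near introduction points. TU
codes come from a 0.5° tiling. Everything is deterministic given a seed.

`simulateGenotypes()` draws individuals multinomially from specified
population haplotype profiles; an exact-counts mode (largest-remainder
apportionment) reproduces published composition tables bit-exactly.

What the simulator does **not** emulate: uneven and time-varying survey
effort, geocoding error, coastline-constrained habitat, spatially
correlated reporting, or record loss. Passing recovery tests therefore
demonstrates that the method chain works when its assumptions hold — not
that real compilations are free of the biases the historical literature
documents at length.

The package also ships
`inst/extdata/synthetic_first_records_euromed.csv`
(`syntheticFirstRecords()`): a *synthetic reconstruction* of the
Euro-Mediterranean first-record compilation, built because the original
per-record coordinate table is not redistributable here. Historically
attested anchor localities (the early wild stations from Malta and
Gibraltar to Zakynthos and Alexandria, and documented garden records)
carry their approximate real coordinates and defensible years; the
remaining records are deterministic, formula-generated infill (sunflower
layout around each nucleus, record year growing with distance at
8 km·yr⁻¹) chosen so the set has the published structure — 181 first
reports, 30 cultivated and 151 wild TUs, two nuclei established before
1840 and an eastern one appearing between 1840 and 1880. Conclusions
drawn from it about exact cluster boundaries or peak cells are
conclusions about the reconstruction, not about the historical data; the
tests treat the published cluster numbers as soft targets (within the top
two Silhouette values) for exactly this reason. On this reconstruction
the Silhouette profile puts k = 2 first at every cutoff, with k = 3 an
effective tie from 1880 onwards — the three-cluster structure is present
but, with these synthetic coordinates, not dominant.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 20-instance brute-force
oracle comparisons on 10 × 10 grids (vectorized vs. naive double loop,
relative error ≤ 1e-12); 50-seed recovery studies of the default scenario
at the full 200 × 200 grid; 20-seed scans for the three-blob Silhouette
property; 10 000-draw law-of-large-numbers checks on the displacement
kernel. Restart RNG for `selectK` is derived as `seed + k`, making the
scan deterministic while decoupling the k values. Degenerate inputs are
defined, not special-cased away: single-point clusters fall back to an
extent-scaled buffer, duplicate points are allowed (k must not exceed the
number of distinct points), an empty record set filters and summarizes to
empty/zero.

## Known limitations

* First records bound arrival from above; systematic reporting lag shifts
  all years and can distort cluster chronology, though not geography.
* Euclidean-on-degrees clustering is a reproduction-first default; use
  haversine for high-latitude or longitudinally wide data.
* The Rossmo surface treats observations as independent; serial
  colonization (a secondary focus seeding its own neighbourhood) inflates
  apparent origins — which is precisely why per-cutoff reanalysis matters.
* Voronoi output is an assignment function, not polygon geometry.
* Letter aliases for haplotypes and the native/invaded dichotomy are
  conveniences; nothing population-genetic beyond frequencies is computed.
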