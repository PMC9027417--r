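---
title: "Methods: diversity hotspots, reserve gaps and suitability post-processing"
author: "hotspotDiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity hotspots, reserve gaps and suitability post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotDiv)
```

## The problem

National-scale conservation planning for a large flora — the motivating
case is the medicinal flora of China, with hundreds of thousands of
georeferenced herbarium records for roughly ten thousand species — needs
three things from occurrence data: a defensible map of diversity
hotspots, a measure of how well the existing reserve network covers
them, and an outlook on how climate change moves the suitable habitat
those hotspots are meant to protect. `hotspotDiv` implements this
workflow on a regular degree grid, from raw occurrence CSVs to
hotspot/gap tables, and ships a fully seeded synthetic generator so the
whole pipeline can be exercised and tested without any external data.

## Grid and incidence

Occurrences are binned on a regular WGS84 grid (default resolution 0.5
degrees). No projection is applied: cells are degree squares, and areas
are reported nominally as $(res \times 110\ \mathrm{km})^2$ — 3025 km²
for a half-degree cell, which is the round convention used in
coarse-grid atlases of China. Cells are half-open boxes, closed on the
grid's outermost north/east edge, with 0-based row-major ids from the
southwest corner, so point assignment is deterministic everywhere
including boundaries. Cells straddling a real coastline or border are
treated like any others; clipping the grid to a national boundary
polygon is deliberately out of scope.

Records are dropped (and counted) when coordinates are missing or
unparseable, when the species is absent from the catalog, or when the
point falls outside the grid extent; the retained records become a
sparse boolean species-by-cell incidence matrix. Duplicate records
collapse, so incidence is invariant to record order and duplication.
Subspecific taxa are kept as distinct identifiers; no name resolution is
attempted.

## Two hotspot algorithms

Species are partitioned into five (overlapping) conservation groups:
all, endemic, threatened (VU/EN/CR), CITES-listed, and nationally
protected. For each cell $c$ and group $g$ with $N_g$ members,
$r_{gc} = S_{gc}/N_g$ and the **composite richness index** is

$$R_c = \sum_{g} r_{gc}, \qquad 0 \le R_c \le 5 .$$

Using ratios rather than raw counts puts the small groups (a few dozen
nationally protected species) on the same footing as the full flora.
The **top-5% richness algorithm** ranks occupied cells by $R_c$ and
keeps the top `round(0.05 * n_occupied)` (a fixed `kOverride` is
available); all cells tied with the cutoff score are retained, so a
request for 150 can return 151.

The **complementarity algorithm** is greedy set cover: repeatedly pick
the cell with the most not-yet-covered species, remove its species, and
stop when every species is covered. Each selected cell is valued by its
gain $G_c$, the composite ratio sum over the species it newly covers;
over a full solution each nonempty group's gains total exactly 1, a
useful invariant the tests assert to 1e-9. The selection criterion is
the remaining all-species count (the most literal reading of the
procedure this package follows); selecting directly by composite gain is
exposed as `criterion = "composite_gain"` since the choice is genuinely
ambiguous in the source material. Ties are broken by larger composite
gain, then smaller cell id; gain comparisons use a 1e-9 tolerance so
exact rational ties are not split by floating-point rounding.

**Integration**: cells found by both algorithms are first-class
hotspots, ordered by the sum of their two rank positions. Cells found by
exactly one algorithm fill the remaining slots (second class), ordered
by their rank among the cells of their own ranking not already taken; at
equal rank a richness-algorithm cell precedes a complementarity one, so
two disjoint rankings interleave. The two classes always partition a
`kTotal`-cell set when enough candidates exist.

## Correlating distribution patterns

The ten patterns (five groups × two algorithms) are expressed as
cell-indexed vectors over the whole grid with absences as zero, and
correlated pairwise with Pearson's $r$ (two-sided $t$-test $p$-values,
no multiple-testing correction). A seven-class verbal taxonomy is
applied to $|r|$: no correlation (0), very weak (< 0.2), weak (< 0.4),
moderate (< 0.6), strong (< 0.8), very strong (< 1), perfect (1).
Classification happens after rounding $r$ to two decimals, the precision
at which such coefficients are reported. A z-score/min-max normalization
switch exists for presentation parity, but Pearson $r$ is invariant
under positive affine transforms — a property the tests verify — so it
cannot change any result.

## Reserve effectiveness and gaps

Reserve polygons (GeoJSON, national or provincial tier) are overlaid on
the grid. The default coverage rule counts a cell as covered when its
box shares *any positive area* with a reserve of the chosen tiers; a
centroid rule is available for sensitivity analysis, and no minimum
overlap fraction is imposed since none is defensible a priori. Because
no geometry engine is a package dependency, the overlay uses exact
planar primitives implemented here: Sutherland–Hodgman clipping of
polygon rings against cell rectangles with shoelace areas (holes
subtracted), even-odd point-in-polygon for centroids, and a
self-intersection check that rejects bow-tie rings outright.

Hotspot cells split into protected cells and conservation gaps, and a
Table-1-style report counts, for each area class (whole occupied area,
hotspots, hotspots covered by NNRs/PNRs/either, the corresponding gaps,
and all cells covered per tier), the species present in at least one
member cell per group, with proportions of $N_g$ formatted as
`count/percent`. Percentages round half-away-from-zero at the printed
precision. A separate three-way partition (threatened; endemic excluding
threatened; remaining) supports composition summaries.

## Suitability post-processing

The package does not fit distribution models. It prepares inputs for an
external presence-only modeller and consumes its continuous suitability
rasters (ESRI ASCII, one per species per scenario, values in [0, 1],
default 5 arc-minutes):

* **Modeling floor** — only group species (threatened by default) with
  at least 5 records are modeled.
* **Replication plan** — 5–29 records: jackknife with as many replicates
  as records; 30 or more: 10-fold cross-validation with 10 replicates.
  The boundary value 30 is assigned to the cross-validation branch
  (`cvBreakpoint` makes it configurable) because the jackknife rule is
  stated for small samples.
* **Predictor screening** — while any pair of candidate variables has
  $|r|$ strictly above 0.70, remove from the worst pair the variable
  with the larger mean absolute correlation to the remaining set. A pair
  at exactly 0.70 is kept (the comparison carries a 1e-9 tolerance).
  The result always satisfies the bound, is a subset of the input, and
  is deterministic.
* **Thresholding and superposition** — suitability below $\tau = 0.75$
  is rejected per species ($\tau$ itself is retained); surviving values
  are summed per pixel into the community map
  $V_x = \sum_s v_{sx}[v_{sx} \ge \tau]$, and the SHA (suitable habitat
  area) mask is $V_x > 0$. Raising $\tau$ can only shrink both.
* **Overlap classes** — a 0.5-degree cell decomposes into 6 × 6 fine
  sub-cells; a cell is *completely* covered when all 36 sub-cells are
  SHA-positive, *partially* when at least one is, *none* otherwise.
  "Completely covered" is operationalised this way because no formal
  definition exists in the source literature; `minFraction` switches to
  a fractional rule for sensitivity runs.
* **Stability** — the long-term stable SHA is the pixelwise AND of the
  current and future masks; a hotspot cell counts as "in stable SHA"
  under the same complete-coverage rule, and stable cells intersect
  with gaps and reserves for the climate-exposure overlays.

## The synthetic study generator

`simConfig()` fixes the study conditions; a single master seed drives
independent sub-streams per stage (catalog, occurrences, reserves,
suitability), so outputs are reproducible bit-for-bit and a change to
one stage leaves the others untouched.

* **Catalog** — independent Bernoulli memberships at rates matching the
  motivating flora: endemic 32.9%, threatened 6.4%, CITES 3.5%,
  nationally protected 0.8%; threatened species draw VU/EN/CR uniformly.
* **Extent** — the demo extent is a 10° × 10° window (100–110°E,
  20–30°N, 400 half-degree cells), a realistic southern-China-sized
  region that keeps tests fast; it is fully configurable.
* **Occurrences** — every species gets a range centre (a planted cell's
  centroid with probability proportional to the boost weight, otherwise
  uniform) and a per-species range breadth drawn log-normally with
  median `rangeSd` (1°, sdlog 0.5), reproducing the skewed mix of
  narrow- and wide-ranged species real floras show. Records are drawn
  from the isotropic normal around the centre and accepted by rejection
  sampling with density proportional to normal × cell weight: planted
  cells carry `hotspotBoost` (10) times the sampling weight of an
  ordinary cell, which is what "planted high-diversity cell" means
  here — presences concentrate into planted cells and their immediate
  neighbours are relatively depleted, so the planted signal is crisp.
  Out-of-extent draws are rejected the same way (a truncated normal);
  clamping instead would pile records on the boundary and fabricate
  edge hotspots. Planted cells are drawn at least `2 * rangeSd` from
  the extent boundary so edge truncation of background ranges cannot
  confound them. Record counts are log-uniform on 8–600, calibrated
  once so the generated range-size distribution lands near the
  herbarium reference quantiles (about 9% of species under 5 cells and
  about 66% above 20 cells, both checked in tests to ±10 points).
* **Reserves** — random rectangles (0.5–2.5° sides), alternating
  national/provincial, added until the exact rectangle-union area
  (coordinate compression) reaches the target fraction of the extent;
  fractions 0 and 1 degenerate to an empty set and a single
  extent-covering reserve.
* **Suitability** — per-species Gaussian bumps at the niche centre
  (peak uniform in [0.8, 1.0], sd = the species' range breadth) on the
  6-fold refined grid; the future scenario shifts every centre north by
  2°, emulating a poleward habitat shift.

What the generator does **not** emulate: real topography and climate
surfaces, spatial sampling bias along roads and rivers, taxonomic error,
non-rectangular reserves, or dispersal limits. Passing tests therefore
demonstrate the pipeline's correctness and its ability to recover
planted structure under controlled conditions — not predictive validity
on real Chinese data.

## Problem sizes and numerical choices

The test suite runs the full default generator (2000 species, 400
cells) across 50 seeds for the planted-hotspot recovery property,
compares the greedy implementation against a brute-force simulation on
500 random instances of at most 12 cells and 20 species, and checks
integration conservation on 1000 random ranking pairs; these sizes keep
the whole suite under a few minutes on one CPU while leaving the
statistical checks well-powered. Degenerate inputs are handled
explicitly: empty groups contribute zero to $R_c$ with a warning,
constant pattern vectors are excluded from correlograms (their
correlation is undefined), species with zero occurrences make the
set-cover loop fail fast, and misaligned rasters or non-divisible
resolutions are errors, not silent resampling.

## Known limitations

* Nominal areas ignore the cosine shrinkage of longitude with latitude;
  at 50°N a "3025 km²" cell is nearer 2000 km². The convention is kept
  because the downstream statistics are cell counts, not areas.
* The greedy solution is a heuristic set cover; no optimality gap is
  reported.
* The positive-area coverage rule counts a sliver-overlap cell as
  protected; use the centroid rule to bound the sensitivity.
* The per-species rasters are held in memory as a dense array; at 5
  arc-minutes over a continental extent with thousands of species a
  tiled backend would be needed.
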