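Package: hotspotDiv
Title: Diversity Hotspot Identification, Reserve Gap Analysis and
    Habitat-Suitability Post-Processing on Occurrence Grids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatial conservation prioritization from
    presence-only occurrence records. Occurrences are assigned to a
    regular degree grid and summarised as a species-by-cell incidence
    matrix; diversity hotspots are identified both by a composite
    top-5% richness index over five conservation groups (all, endemic,
    threatened, CITES-listed, nationally protected species) and by a
    greedy complementarity (set-cover) rule, then integrated into
    first- and second-class hotspots by rank summation. Reserve-network
    overlays quantify conservation effectiveness and gaps, and
    species-distribution-model suitability surfaces are post-processed
    (predictor screening, thresholding, superposition, climate-change
    stability) and overlaid on hotspots and gaps. A fully seeded
    synthetic-data generator with planted hotspot structure makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hotspotDiv-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'geogrid.R'
    'io-geojson.R'
    'io-asc.R'
    'occurrences.R'
    'prioritization.R'
    'patternStats.R'
    'reserves.R'
    'suitability.R'
    'syntheticData.R'
    'pipeline.R'
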