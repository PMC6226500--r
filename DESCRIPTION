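Package: latgaps
Title: Latitudinal Range Gaps and Inventory Completeness for Marine
    Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to clean Darwin-Core-style marine species occurrence
    tables, bin records into latitudinal bands, detect spatial gaps
    (disjunctions) within each species' latitudinal extent, and estimate
    per-band sampling effort and inventory completeness by sample coverage
    (singletons and doubletons) and by the curvilinearity of species
    accumulation curves.  Includes bathymetric stratification (euphotic,
    bathyal, abyssal), cross-taxon aggregation with standardised curves,
    band-width resolution sweeps, and a synthetic occurrence generator with
    known ground truth (contiguous latitudinal ranges sampled under a
    latitude-dependent effort profile) for end-to-end validation of the
    gap statistic under sampling bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
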