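---
title: "Detecting latitudinal range gaps and estimating inventory completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latitudinal range gaps and estimating inventory completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latgaps)
```

## The problem

Occurrence repositories such as OBIS record where marine species have been
*seen*, not where they *live*. When sampling effort varies strongly with
latitude — intense at northern and southern mid-latitudes, sparse in the
tropics — apparent absences concentrate exactly where effort is lowest, and
the observed latitudinal diversity gradient can acquire an artefactual
equatorial dip. `latgaps` implements the analytical chain for diagnosing
this: quality-control of occurrence records, latitudinal binning, detection
of *spatial gaps* within each species' latitudinal extent, and two
per-band estimates of inventory completeness, together with a synthetic
occurrence generator that provides ground truth for validating every stage.

## The gap statistic

Latitude is discretised into bands (default: 5° bands from −80° to 85°, 33
bands; the south bound excludes the Antarctic continent and the north bound
the Arctic ice cap). For each species we form the set of occupied bands. The
central assumption is **range contiguity**: at this coarse scale a species'
true latitudinal distribution is taken to be a single interval. Under that
assumption, any unoccupied band lying *strictly between* the species'
lowest and highest occupied bands is a spatial gap — an absence attributable
to sampling rather than to a genuinely disjunct range. Per band,

* **observed richness** = number of species recorded in the band,
* **missing richness** = number of species for which the band is a gap.

A species recorded in a single band, or in a contiguous run of bands,
contributes no missing richness anywhere. Absences *outside* a species'
recorded extremes are invisible to the statistic (edge truncation); the
package reports this blind spot (`recovery_report()`) rather than
extrapolating beyond the recorded extent.

Two conventions are fixed here because the definitions need them and
several reasonable variants exist:

* Bands are half-open `[low, high)`, with the topmost band closed, so every
  latitude in the span maps to exactly one band. Band indices are 1-based.
* "Absent from the equator" means the `[0°, 5°)` band lies strictly inside a
  species' band extent and is unoccupied.

## Quality control

`apply_qc()` applies the cleaning rules in a fixed, audited order: drop
missing and (0, 0) coordinates; drop on-land records when a coastline
predicate is supplied (building a buffered coastline is out of scope, so
land filtering is pluggable and skipped with a warning otherwise); round
coordinates to two decimals; keep only species-level records, collapsing
subspecies to the binomial; resolve names against a user-supplied status
table (synonyms remapped; invalid, fossil, non-marine and unresolved names
dropped, each counted separately); drop latitudes outside [−80°, 85°]
(bounds inclusive); deduplicate on (name, latitude, longitude, date),
keeping undated records only when their name/location combination is
unique. Rounding *precedes* deduplication so that coordinate-precision
jitter between source datasets cannot split one sampling event into
several; rounding is half-away-from-zero, which is deterministic across
platforms. The QC report satisfies the bookkeeping identity
`n_input − Σ removed = n_output`, and the whole procedure is idempotent.

A *sampling event* is a unique (latitude, longitude, date) combination.
Records without a date form one event key per location — QC guarantees at
most one undated record per (species, location), and merging undated with
dated events would undercount effort. Events are keyed on rounded
coordinates for the same double-counting reason.

## Inventory completeness

Two estimators, both in [0, 1] (1 = complete inventory):

**Sample coverage.** With `n` records in a band, `f1` species represented
by exactly one record and `f2` by exactly two,
\[
\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2}.
\]
Records are treated as the specimen proxy — occurrence rows are the only
individual-level signal available — so `f1`/`f2` are counted from per-band
record counts per species. (An incidence-frequency variant using events as
sampling units would also be defensible; the record-based form is what the
rest of the package assumes.) Coverage is computed for any band with at
least two records; `n = 0` is undefined and `n = 1` returns 0.

**Accumulation-curve curvilinearity.** The species accumulation curve
(SAC) gives the expected number of distinct species in the first *k*
sampling events over random orderings of events. Completeness is one minus
the mean slope of the final 10% of the curve, clamped to [0, 1]: a
saturated survey has a flat tail (slope ≈ 0), a survey still discovering
one species per event has slope 1. Because only the tail is used, the
estimate is computed only for bands with **more than 40 events**;
sparser bands return `NA`, which propagates as missing — never as zero —
so sparse bands cannot masquerade as poorly sampled ones.

The curve itself can be computed two ways. `method = "random"` averages
`n_perm` (default 100) random orderings with a mandatory seed, bit-for-bit
reproducible. `method = "exact"` evaluates the analytic expectation
\(E[S(k)] = \sum_s \bigl(1 - \binom{n-n_s}{k}/\binom{n}{k}\bigr)\), which
equals the average over *all* orderings; it is used in tests (verified
against exhaustive enumeration and against `vegan::specaccum`) and in
large simulation studies, where only the two tail points are needed.

## Bathymetric strata

Records partition into euphotic [0, 200) m, bathyal [200, 2000) m and
abyssal [2000, 6500] m. The printed stratum ranges touch without stating
boundary ownership; boundaries here belong to the deeper stratum and the
abyssal stratum closes at 6500 m, below which records are unassigned.
When sample depth is missing, benthic species (user-supplied habit table)
fall back to the seafloor depth at the record's coordinates, queried from a
pluggable nearest-node bathymetry grid; pelagic species never use the
fallback, since their sampling depth need not reflect the bottom.
`stratified_analysis()` reruns the entire pipeline independently inside
each stratum: a species contiguous overall can legitimately be disjunct
within one stratum.

## The synthetic generator

`make_world()` realises the null world in which the contiguity assumption
holds exactly: every species' true range is one latitude interval, so
*every* detected gap is a sampling artefact. Defaults: 500 species; range
midpoints uniform on [−70°, 75°] (or truncated-normal about the equator for
a unimodal-tropical richness target); range widths lognormal with median
20° (sdlog 0.6) — a realistic width spread for marine taxa at this scale;
60% of species benthic; species depths lognormal (median 200 m).

`simulate_records()` draws Poisson numbers of sampling events per band at
the effort profile's rate, places them uniformly within the band, and
records each truly present species at each event with its detection
probability — per-event Bernoulli detection, the simplest exchangeable
observation model, with an optional lognormal spread of species
detectabilities (median `p`) to emulate the rare species that dominate
real assemblages. The bimodal effort preset mirrors global marine survey
effort: mid-latitude plateaus (band centres within 10° of ±40°), an
equatorial trough at a configurable fraction of the peak rate (default
1/30, matching the order of magnitude of the real equatorial deficit), and
a linear taper toward the poles. Noise injection appends the five classes
of QC-violating rows (on-land, zero coordinates, out-of-bounds latitude,
exact duplicates, undated copies) at configurable per-record rates;
`synthetic_land_mask()` flags exactly the rectangle the on-land noise uses.

What the generator does **not** emulate: longitudinal structure (ranges are
latitudinal intervals, not 2-D polygons), environmental covariates,
temporal turnover, spatial autocorrelation of events within bands, and
taxonomic error. Passing the recovery tests therefore shows the pipeline
is correct *given* contiguous ranges and exchangeable detection — it
cannot show that real marine ranges are contiguous, which is the analysis'
standing assumption.

## Validation studies and problem sizes

Two simulation studies back the test suite, sized to run a full study in a
few minutes on one core:

* **Null-world recovery.** 50 worlds of 500 species, uniform effort of 500
  events/band, flat detection 0.1. With ~50 events expected per present
  species per band, detection saturates and per-band missing richness
  should be below 2% of true richness — spurious gaps essentially never
  arise under uniform effort.
* **Bias reproduction.** The same worlds under the bimodal profile with
  2000-event peaks and the 1/30 equatorial trough. The peak rate is set so
  that the trough (~67 events/band) stays above the 40-event SAC
  threshold, letting both completeness estimators be compared at the
  equator. Detection uses the lognormal spread (median 0.1, sdlog 1.25):
  with flat detectability, 67 events would saturate detection and no
  tropical gap could appear — rare species are the mechanism through which
  effort deficits become apparent absences. The expected signature:
  depressed detected fraction of true richness and a missing-richness peak
  in the trough bands, and both completeness estimators lower there than
  at mid-latitudes. The per-seed dip check uses the detected *fraction*
  (observed/true) rather than raw observed richness, because band-to-band
  noise in a single world's true richness can mask an artefact that is
  plainly present; the ground truth exists precisely to allow this
  normalisation.

## Aggregation across groups

`aggregate_groups()` standardises each group's observed richness, missing
richness and event counts by their own maxima (so taxa of very different
sizes are comparable on [0, 1]) and averages across groups per band, with
the population form (denominator *n*) of the standard deviation — the
denominator is a fixed convention here, chosen for reproducibility. The
two completeness estimators are already on [0, 1] and are averaged
*unstandardised*: rescaling a coverage curve whose maximum is 0.7 to reach
1 would fabricate completeness. Bands where a metric is undefined for a
group are excluded from that band's mean for that metric.
`resolution_sweep()` reruns completeness at several band widths;
completeness typically rises at coarser resolutions, so the tropical
deficit should be judged across widths, not at one.

## Numerical choices and edge cases

* Band assignment adds a 10⁻⁹ tolerance before flooring, so latitudes
  sitting on a band edge after floating-point arithmetic land in the upper
  band deterministically.
* Coordinate rounding adds the same guard so decimals stored just under a
  half-boundary (10.005 is 10.004999… in binary) still round away from
  zero.
* `species_gap_profile()` refuses all-absent rows; `band_absence_ratio()`
  signals (rather than returning `Inf`) when observed richness is zero.
* Functions that consume a seed save and restore the caller's RNG state.
* Per-band SAC seeds are derived as `seed + band`, keeping bands
  independent but the whole table reproducible from one integer.
* Negative sample depths are blanked (kept as depth-missing records), not
  dropped.

## Limitations

The gap statistic is conservative by construction: it cannot see absences
beyond a species' recorded extremes, so total missing richness is a lower
bound, and the reported capture fraction quantifies exactly how much the
edge-truncation blind spot costs on synthetic data. Completeness at 5°
bands is a large-scale summary; fine-scale completeness is generally
lower, so tropical under-sampling is, if anything, understated. Name
resolution applies only the supplied status table — no fuzzy matching — and
the land filter is only as good as the predicate plugged in.
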