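#' Bathymetric stratum labels
#'
#' The three depth strata used throughout: euphotic `[0, 200)` m, bathyal
#' `[200, 2000)` m, abyssal `[2000, 6500]` m. Boundaries belong to the deeper
#' stratum; depths beyond 6500 m (and records whose depth cannot be resolved)
#' are `unassigned`.
#' @return Character vector of the four labels.
#' @export
stratum_levels <- function() c("euphotic", "bathyal", "abyssal", "unassigned")

# internal: depth (m) -> stratum label
depth_to_stratum <- function(depth) {
  out <- rep("unassigned", length(depth))
  ok <- !is.na(depth)
  out[ok & depth >= 0 & depth < 200] <- "euphotic"
  out[ok & depth >= 200 & depth < 2000] <- "bathyal"
  out[ok & depth >= 2000 & depth <= 6500] <- "abyssal"
  factor(out, levels = stratum_levels())
}

#' Habit table
#'
#' Species-to-habit mapping used to decide whether seafloor depth may stand
#' in for a missing sample depth: it may for benthic species (they live on
#' the bottom), never for pelagic ones.
#'
#' @param species Character vector of species names.
#' @param habit `"benthic"` or `"pelagic"` per species.
#' @return Named character vector (species -> habit) of class `habit_table`.
#' @export
habit_table <- function(species, habit) {
  habit <- match.arg(habit, c("benthic", "pelagic"), several.ok = TRUE)
  structure(stats::setNames(rep_len(habit, length(species)),
                            as.character(species)),
            class = "habit_table")
}

#' Gridded bathymetry lookup
#'
#' Wraps a regular (lat, lon, depth) table as a nearest-node lookup function,
#' the pluggable stand-in for a global bathymetry raster. Depth is metres,
#' positive down; queries outside the grid's node range return `NA`.
#'
#' @param nodes Data frame with numeric columns `lat`, `lon`, `depth`.
#' @return A function `(lat, lon) -> depth` of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("lat", "lon", "depth") %in% names(nodes)))
  lats <- sort(unique(nodes$lat))
  lons <- sort(unique(nodes$lon))
  depth <- matrix(NA_real_, length(lats), length(lons))
  depth[cbind(match(nodes$lat, lats), match(nodes$lon, lons))] <- nodes$depth
  half_lat <- if (length(lats) > 1) max(diff(lats)) / 2 else Inf
  half_lon <- if (length(lons) > 1) max(diff(lons)) / 2 else Inf
  nearest <- function(x, nodes_sorted, half) {
    i <- findInterval(x, nodes_sorted, all.inside = TRUE)
    i <- ifelse(abs(x - nodes_sorted[pmin(i + 1, length(nodes_sorted))]) <
                  abs(x - nodes_sorted[i]), pmin(i + 1, length(nodes_sorted)), i)
    i[abs(x - nodes_sorted[i]) > half] <- NA_integer_
    i
  }
  structure(function(lat, lon) {
    li <- nearest(lat, lats, half_lat)
    lj <- nearest(lon, lons, half_lon)
    out <- rep(NA_real_, length(lat))
    ok <- !is.na(li) & !is.na(lj)
    out[ok] <- depth[cbind(li[ok], lj[ok])]
    out
  }, class = c("bathymetry_grid", "function"))
}

#' Assign records to bathymetric strata
#'
#' Records with a sample depth are labelled by the depth interval rule.
#' Records without one fall back to the seafloor depth at their coordinates
#' — but only for benthic species and only when a bathymetry lookup is
#' supplied. Everything else is `unassigned`.
#'
#' @param records Cleaned occurrence data frame.
#' @param habit A [habit_table()] covering the species in `records`; species
#'   absent from it are treated as pelagic (no seafloor fallback).
#' @param bathy Optional [bathymetry_grid()] (or any `function(lat, lon)`
#'   returning seafloor depth in metres).
#' @return Factor of stratum labels, one per record.
#' @export
assign_stratum <- function(records, habit, bathy = NULL) {
  depth <- records$sample_depth_m
  if (!is.null(bathy)) {
    h <- unclass(habit)[records$species_name]
    fallback <- is.na(depth) & !is.na(h) & h == "benthic"
    if (any(fallback))
      depth[fallback] <- bathy(records$latitude[fallback],
                               records$longitude[fallback])
  }
  depth_to_stratum(depth)
}

#' Depth-stratified gap and completeness analysis
#'
#' Runs the full per-band pipeline (occupancy, gap richness, sampling effort,
#' completeness) independently within each bathymetric stratum. Gap profiles
#' are recomputed per stratum: a species' extent in the euphotic stratum uses
#' only its euphotic records, so a species contiguous overall may be disjunct
#' within a stratum.
#'
#' @inheritParams assign_stratum
#' @inheritParams completeness_by_band
#' @return A list of class `stratified_gap_analysis` with elements
#'   `strata` (named list of [gap_analysis()] objects for euphotic, bathyal
#'   and abyssal), `assignment` (per-record stratum factor) and
#'   `n_unassigned`.
#' @export
stratified_analysis <- function(records, habit, bathy = NULL,
                                grid = band_grid(), n_perm = 100, seed = 1,
                                min_events = 40,
                                sac_method = c("random", "exact")) {
  sac_method <- match.arg(sac_method)
  lab <- assign_stratum(records, habit, bathy)
  strata <- stats::setNames(vector("list", 3), stratum_levels()[1:3])
  for (s in names(strata)) {
    strata[[s]] <- gap_analysis(records[lab == s, , drop = FALSE],
                                grid = grid, n_perm = n_perm,
                                seed = seed + match(s, names(strata)),
                                min_events = min_events,
                                sac_method = sac_method)
  }
  structure(list(strata = strata, assignment = lab,
                 n_unassigned = sum(lab == "unassigned")),
            class = "stratified_gap_analysis")
}

#' @export
print.stratified_gap_analysis <- function(x, ...) {
  cat("Depth-stratified latitudinal gap analysis\n")
  for (s in names(x$strata))
    cat(sprintf("  %-9s %7d records, %5d species\n", s,
                sum(x$strata[[s]]$effort$n_records),
                length(x$strata[[s]]$occupancy$species)))
  cat(sprintf("  %-9s %7d records\n", "unassigned", x$n_unassigned))
  invisible(x)
}
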