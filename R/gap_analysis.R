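#' Latitudinal gap and completeness analysis
#'
#' The central entry point: from a cleaned occurrence table, computes the
#' species-by-band occupancy, observed and missing (gap) richness per band,
#' sampling effort (unique events), and both inventory-completeness
#' estimators (sample coverage; accumulation-curve curvilinearity).
#'
#' @param records Cleaned occurrence data frame ([apply_qc()] output; raw
#'   tables must be cleaned first).
#' @param grid A [band_grid()].
#' @inheritParams completeness_by_band
#' @return Object of class `gap_analysis`: list with `grid`, `occupancy`,
#'   `richness` ([richness_vectors()]), `effort` ([count_sampling_events()]),
#'   `completeness` ([completeness_by_band()]), `species`
#'   ([species_gap_table()]), `gap_summary` ([gap_species_summary()] or
#'   `NULL` for empty input), and `band_table` joining the per-band outputs.
#' @examples
#' w <- make_world(n_species = 40, seed = 7)
#' rec <- simulate_records(w, effort_profile(events_per_band = 60), seed = 7)
#' cleaned <- apply_qc(rec, world_names_table(w),
#'                     land_mask = synthetic_land_mask)
#' fit <- gap_analysis(cleaned$records, seed = 7)
#' fit
#' @export
gap_analysis <- function(records, grid = band_grid(), n_perm = 100, seed = 1,
                         min_events = 40, sac_method = c("random", "exact")) {
  sac_method <- match.arg(sac_method)
  occ <- build_occupancy(records, grid)
  rich <- richness_vectors(occ)
  eff <- count_sampling_events(records, grid)
  comp <- completeness_by_band(records, grid, n_perm = n_perm, seed = seed,
                               min_events = min_events,
                               sac_method = sac_method)
  band_table <- data.frame(rich[, c("band", "lat_low", "lat_high",
                                    "observed", "missing")],
                           n_records = eff$n_records,
                           n_events = eff$n_events,
                           f1 = comp$f1, f2 = comp$f2,
                           coverage = comp$coverage, sac = comp$sac)
  structure(list(grid = grid, occupancy = occ, richness = rich, effort = eff,
                 completeness = comp, species = species_gap_table(occ),
                 gap_summary = if (length(occ$species) > 0)
                   gap_species_summary(occ) else NULL,
                 band_table = band_table,
                 call = match.call()),
            class = "gap_analysis")
}

#' @export
print.gap_analysis <- function(x, ...) {
  cat("Latitudinal gap analysis\n")
  cat(sprintf("  grid: [%g, %g] in %g-degree bands (%d bands)\n",
              x$grid$lower, x$grid$upper, x$grid$width, x$grid$n_bands))
  cat(sprintf("  records: %d   sampling events: %d   species: %d\n",
              sum(x$effort$n_records), sum(x$effort$n_events),
              length(x$occupancy$species)))
  if (!is.null(x$gap_summary))
    cat(sprintf("  species with a latitudinal gap: %d (%.2f%%)\n",
                x$gap_summary$n_gap_species, 100 * x$gap_summary$fraction))
  invisible(x)
}

#' @export
summary.gap_analysis <- function(object, ...) {
  bt <- object$band_table
  print(object)
  eq <- bt[bt$lat_low <= 0 & bt$lat_high > 0, ]
  if (nrow(eq) == 1 && eq$observed > 0)
    cat(sprintf("  equatorial band [%g, %g): %d observed, %d missing (ratio %.2f)\n",
                eq$lat_low, eq$lat_high, eq$observed, eq$missing,
                eq$missing / eq$observed))
  defined <- !is.na(bt$coverage)
  if (any(defined))
    cat(sprintf("  coverage: defined in %d bands, mean %.3f\n",
                sum(defined), mean(bt$coverage[defined])))
  defined <- !is.na(bt$sac)
  if (any(defined))
    cat(sprintf("  SAC completeness: defined in %d bands, mean %.3f\n",
                sum(defined), mean(bt$sac[defined])))
  invisible(bt)
}

#' Plot a gap analysis
#'
#' Two stacked panels against band-centre latitude: observed and missing
#' richness; standardised sampling effort with the two completeness
#' estimators.
#'
#' @param x A [gap_analysis()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gap_analysis <- function(x, ...) {
  bt <- x$band_table
  mid <- (bt$lat_low + bt$lat_high) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(mid, bt$observed, type = "b", pch = 16,
                 xlab = "latitude (band centre)", ylab = "species",
                 ylim = range(c(bt$observed, bt$missing)),
                 main = "Observed (filled) and missing (open) richness", ...)
  graphics::lines(mid, bt$missing, type = "b", pch = 1)
  eff <- suppressWarnings(standardise_curve(bt$n_events))
  graphics::plot(mid, eff, type = "b", pch = 0, ylim = c(0, 1),
                 xlab = "latitude (band centre)", ylab = "standardised value",
                 main = "Effort (squares) and completeness (coverage: filled; SAC: open)")
  graphics::lines(mid, bt$coverage, type = "b", pch = 16)
  graphics::lines(mid, bt$sac, type = "b", pch = 1)
  invisible(x)
}
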