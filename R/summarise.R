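#' Standardise a per-band curve to [0, 1]
#'
#' Divides by the vector's maximum (ignoring `NA`). An all-zero (or all-`NA`)
#' vector is returned unchanged with a warning and the attribute
#' `all_zero = TRUE`.
#'
#' @param values Numeric per-band vector.
#' @return Standardised vector.
#' @export
standardise_curve <- function(values) {
  m <- suppressWarnings(max(values, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) {
    warning("curve has no positive values; returned unstandardised",
            call. = FALSE)
    attr(values, "all_zero") <- TRUE
    return(values)
  }
  values / m
}

#' Per-group curve set
#'
#' Bundles one taxonomic group's per-band vectors for aggregation, typically
#' from a [gap_analysis()] object.
#'
#' @param x A [gap_analysis()] object.
#' @param group Group label.
#' @return List of class `group_curves`: `group`, `grid`, `observed`,
#'   `missing`, `events`, `coverage`, `sac`.
#' @export
group_curves <- function(x, group) {
  stopifnot(inherits(x, "gap_analysis"))
  structure(list(group = group, grid = x$grid,
                 observed = x$richness$observed,
                 missing = x$richness$missing,
                 events = x$effort$n_events,
                 coverage = x$completeness$coverage,
                 sac = x$completeness$sac),
            class = "group_curves")
}

#' Aggregate standardised curves across taxonomic groups
#'
#' Count metrics (observed and missing richness, sampling events) are first
#' standardised within each group by [standardise_curve()]; the two
#' completeness estimators are already on `[0, 1]` and enter unscaled. Per
#' band and metric, the mean and population standard deviation (denominator
#' `n`) are taken across groups, skipping groups for which the metric is
#' undefined at that band.
#'
#' @param curves List of [group_curves()] on a common grid.
#' @return Data frame of class `aggregate_summary`, long format: `band`,
#'   `lat_low`, `lat_high`, `metric`, `mean`, `sd`, `n_groups`.
#' @export
aggregate_groups <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$grid
  for (cv in curves)
    if (!same_grid(cv$grid, grid))
      stop("all groups must share the same band grid", call. = FALSE)
  bb <- band_bounds(grid)
  metrics <- c("observed", "missing", "events", "coverage", "sac")
  scaled <- c("observed", "missing", "events")
  rows <- list()
  for (mt in metrics) {
    vals <- vapply(curves, function(cv) {
      v <- as.numeric(cv[[mt]])
      if (mt %in% scaled) v <- suppressWarnings(standardise_curve(v))
      v
    }, numeric(grid$n_bands))
    vals <- matrix(vals, nrow = grid$n_bands)
    mu <- apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE))
    sd_pop <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else sqrt(mean((v - mean(v))^2))
    })
    rows[[mt]] <- data.frame(bb[, c("band", "lat_low", "lat_high")],
                             metric = mt, mean = mu, sd = sd_pop,
                             n_groups = apply(vals, 1,
                                              function(v) sum(!is.na(v))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aggregate_summary", "data.frame")
  out
}

#' Completeness across band-width resolutions
#'
#' Re-runs the per-band completeness pipeline at each requested band width
#' on the same records — completeness estimates are scale-dependent and tend
#' to rise at coarser resolutions.
#'
#' @param records Cleaned occurrence data frame.
#' @param widths Band widths in degrees; each must divide the grid span.
#' @param lower,upper Grid edges.
#' @inheritParams completeness_by_band
#' @return Data frame: `width` plus the [completeness_by_band()] columns;
#'   zero rows when `widths` is empty.
#' @export
resolution_sweep <- function(records, widths, lower = -80, upper = 85,
                             n_perm = 100, seed = 1, min_events = 40,
                             sac_method = c("random", "exact")) {
  sac_method <- match.arg(sac_method)
  out <- lapply(widths, function(w) {
    g <- band_grid(lower, upper, w)
    ct <- completeness_by_band(records, g, n_perm = n_perm, seed = seed,
                               min_events = min_events,
                               sac_method = sac_method)
    cbind(width = w, as.data.frame(ct))
  })
  if (length(out) == 0)
    return(data.frame(width = numeric(0), band = integer(0),
                      lat_low = numeric(0), lat_high = numeric(0),
                      n_records = integer(0), n_events = integer(0),
                      f1 = integer(0), f2 = integer(0),
                      coverage = numeric(0), sac = numeric(0)))
  do.call(rbind, out)
}
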