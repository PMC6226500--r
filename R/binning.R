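# internal: one event key per distinct (lat, lon, date); undated records at a
# location form a single key of their own (QC guarantees at most one undated
# record per species/location, and merging them with dated events would
# undercount effort)
event_key <- function(records) {
  date_key <- ifelse(is.na(records$event_date), "<undated>",
                     format(records$event_date, "%Y-%m-%d"))
  paste(records$latitude, records$longitude, date_key, sep = "\r")
}

#' Count sampling events and records per latitudinal band
#'
#' A sampling event is a unique combination of (rounded) latitude, longitude
#' and sampling date. Records with a missing date form one event per location.
#'
#' @param records Cleaned occurrence data frame (see [apply_qc()]).
#' @param grid A [band_grid()].
#' @return A data frame of class `effort_vector` with one row per band:
#'   `band`, `lat_low`, `lat_high`, `n_events`, `n_records`.
#' @export
count_sampling_events <- function(records, grid = band_grid()) {
  bb <- band_bounds(grid)
  out <- data.frame(band = bb$band, lat_low = bb$lat_low,
                    lat_high = bb$lat_high,
                    n_events = 0L, n_records = 0L)
  if (nrow(records) > 0) {
    b <- band_index(records$latitude, grid)
    key <- event_key(records)
    rec <- tabulate(b, grid$n_bands)
    ev <- tapply(key, factor(b, levels = seq_len(grid$n_bands)),
                 function(k) length(unique(k)))
    ev[is.na(ev)] <- 0
    out$n_records <- as.integer(rec)
    out$n_events <- as.integer(ev)
  }
  class(out) <- c("effort_vector", "data.frame")
  out
}

#' Species-by-band occupancy matrix
#'
#' Builds the presence/absence and record-count matrices underlying the gap
#' and richness statistics.
#'
#' @param records Cleaned occurrence data frame.
#' @param grid A [band_grid()].
#' @param species Optional character vector fixing the species set (and row
#'   order); species without records get all-absent rows. Defaults to the
#'   sorted species observed in `records`.
#' @return An object of class `occupancy`: a list with `species`, `grid`,
#'   `counts` (species x band integer matrix) and `presence` (logical matrix,
#'   `counts > 0`).
#' @export
build_occupancy <- function(records, grid = band_grid(), species = NULL) {
  if (is.null(species)) species <- sort(unique(records$species_name))
  counts <- matrix(0L, nrow = length(species), ncol = grid$n_bands,
                   dimnames = list(species, NULL))
  if (nrow(records) > 0) {
    b <- band_index(records$latitude, grid)
    tab <- table(factor(records$species_name, levels = species),
                 factor(b, levels = seq_len(grid$n_bands)))
    counts[] <- as.integer(tab)
  }
  structure(list(species = species, grid = grid, counts = counts,
                 presence = counts > 0L),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("Occupancy matrix: %d species x %d bands, %d records\n",
              length(x$species), x$grid$n_bands, sum(x$counts)))
  invisible(x)
}
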