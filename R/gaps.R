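#' Gap profile of one species
#'
#' Under the range-contiguity assumption, a species' latitudinal distribution
#' is a single interval of bands; any unoccupied band lying strictly between
#' its lowest and highest occupied bands is a spatial gap — an absence more
#' plausibly attributed to missing sampling than to a genuinely disjunct
#' range.
#'
#' @param presence_row Logical vector over bands (one species' row of an
#'   [build_occupancy()] matrix). Must contain at least one `TRUE`.
#' @return A list of class `gap_profile`: `first_band`, `last_band`,
#'   `occupied` (integer indices), `gap_bands` (integer indices, possibly
#'   empty).
#' @examples
#' # a species seen at 0, 10, 30 and 40 degrees on a 10-degree grid has a
#' # gap in the band containing 20 degrees
#' g <- band_grid(0, 50, 10)
#' occ <- band_index(c(0, 10, 30, 40), g)
#' row <- seq_len(g$n_bands) %in% occ
#' species_gap_profile(row)$gap_bands  # the band spanning [20, 30)
#' @export
species_gap_profile <- function(presence_row) {
  presence_row <- as.logical(presence_row)
  occ <- which(presence_row)
  if (length(occ) == 0)
    stop("species without any occupied band cannot be profiled", call. = FALSE)
  first <- occ[1]; last <- occ[length(occ)]
  gaps <- if (last - first <= 1) integer(0) else
    setdiff(seq.int(first + 1L, last - 1L), occ)
  structure(list(first_band = first, last_band = last,
                 occupied = occ, gap_bands = as.integer(gaps)),
            class = "gap_profile")
}

# internal: first/last occupied band and per-cell interior indicator for a
# whole presence matrix at once
range_span <- function(presence) {
  stopifnot(is.matrix(presence))
  if (any(rowSums(presence) == 0))
    stop("every species needs at least one occupied band", call. = FALSE)
  first <- max.col(presence, ties.method = "first")
  last <- max.col(presence, ties.method = "last")
  list(first = first, last = last)
}

#' Observed and missing species richness per band
#'
#' `observed[b]` counts the species recorded in band `b`; `missing[b]` counts
#' the species for which `b` is a spatial gap (unoccupied, strictly inside
#' the species' occupied extent).
#'
#' @param occupancy An [build_occupancy()] object.
#' @return A data frame of class `richness_vectors` with columns `band`,
#'   `lat_low`, `lat_high`, `observed`, `missing`.
#' @export
richness_vectors <- function(occupancy) {
  p <- occupancy$presence
  bb <- band_bounds(occupancy$grid)
  if (nrow(p) == 0) {
    out <- data.frame(bb[, c("band", "lat_low", "lat_high")],
                      observed = 0L, missing = 0L)
  } else {
    sp <- range_span(p)
    cols <- matrix(seq_len(ncol(p)), nrow = nrow(p), ncol = ncol(p),
                   byrow = TRUE)
    interior <- cols > sp$first & cols < sp$last
    out <- data.frame(bb[, c("band", "lat_low", "lat_high")],
                      observed = as.integer(colSums(p)),
                      missing = as.integer(colSums(interior & !p)))
  }
  class(out) <- c("richness_vectors", "data.frame")
  out
}

#' Count and fraction of species with a spatial gap
#'
#' A species has a gap iff its occupied band count is smaller than the length
#' of its occupied span.
#'
#' @param occupancy An [build_occupancy()] object with at least one species.
#' @return List with `n_gap_species` and `fraction` (of all species).
#' @export
gap_species_summary <- function(occupancy) {
  p <- occupancy$presence
  if (nrow(p) == 0) stop("occupancy matrix has no species", call. = FALSE)
  sp <- range_span(p)
  has_gap <- (sp$last - sp$first + 1L) > rowSums(p)
  list(n_gap_species = sum(has_gap),
       fraction = sum(has_gap) / nrow(p))
}

#' Ratio of missing to observed richness in one band
#'
#' @param vectors A [richness_vectors()] data frame.
#' @param band Band index.
#' @return `missing[band] / observed[band]`.
#' @export
band_absence_ratio <- function(vectors, band) {
  i <- match(band, vectors$band)
  if (is.na(i)) stop("band ", band, " not in the grid", call. = FALSE)
  if (vectors$observed[i] == 0)
    stop("absence ratio undefined: no species observed in band ", band,
         call. = FALSE)
  vectors$missing[i] / vectors$observed[i]
}

#' Per-species gap table
#'
#' @param occupancy An [build_occupancy()] object.
#' @return Data frame with `species`, `first_band`, `last_band`, `n_occupied`,
#'   `n_gaps`.
#' @export
species_gap_table <- function(occupancy) {
  p <- occupancy$presence
  if (nrow(p) == 0)
    return(data.frame(species = character(0), first_band = integer(0),
                      last_band = integer(0), n_occupied = integer(0),
                      n_gaps = integer(0)))
  sp <- range_span(p)
  data.frame(species = occupancy$species,
             first_band = sp$first, last_band = sp$last,
             n_occupied = as.integer(rowSums(p)),
             n_gaps = as.integer((sp$last - sp$first + 1L) - rowSums(p)),
             row.names = NULL)
}
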