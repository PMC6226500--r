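#' Synthetic world with contiguous latitudinal ranges
#'
#' Generates the ground truth against which the gap statistic is validated: a
#' set of species whose true latitudinal distributions are single intervals
#' (the contiguity assumption — the null world in which every detected gap is
#' a sampling artefact). Range midpoints are uniform over `midpoint_range`
#' (or tropically concentrated), range widths lognormal with median
#' `exp(width_meanlog)` degrees. Each species also gets a habit (benthic or
#' pelagic) and a typical depth, used by the stratification module.
#'
#' @param n_species Number of species.
#' @param grid A [band_grid()].
#' @param midpoint_range Range-midpoint support in degrees.
#' @param width_meanlog,width_sdlog Lognormal parameters of range width in
#'   degrees (default: median 20 degrees).
#' @param richness_shape `"uniform"` (midpoints uniform) or
#'   `"unimodal-tropical"` (midpoints normal around the equator, truncated to
#'   `midpoint_range`, s.d. `tropical_sd`).
#' @param tropical_sd S.d. of tropical midpoints, degrees.
#' @param p_benthic Probability a species is benthic.
#' @param depth_meanlog,depth_sdlog Lognormal parameters of species' typical
#'   depth (m).
#' @param seed Integer seed; the world is deterministic given the seed.
#' @return Object of class `true_world`: list with `species` (data frame:
#'   `species`, `lat_min`, `lat_max`, `habit`, `depth_m`), `occupancy`
#'   (species x band logical matrix of true presence), `richness` (true
#'   per-band richness), `grid`, `seed`.
#' @export
make_world <- function(n_species = 500, grid = band_grid(),
                       midpoint_range = c(-70, 75),
                       width_meanlog = log(20), width_sdlog = 0.6,
                       richness_shape = c("uniform", "unimodal-tropical"),
                       tropical_sd = 25, p_benthic = 0.6,
                       depth_meanlog = log(200), depth_sdlog = 1.2,
                       seed = 1) {
  richness_shape <- match.arg(richness_shape)
  stopifnot(n_species >= 1, midpoint_range[1] >= grid$lower,
            midpoint_range[2] <= grid$upper)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  mid <- if (richness_shape == "uniform") {
    stats::runif(n_species, midpoint_range[1], midpoint_range[2])
  } else {
    # truncated normal about the equator via inverse-CDF
    u <- stats::runif(n_species,
                      stats::pnorm(midpoint_range[1], 0, tropical_sd),
                      stats::pnorm(midpoint_range[2], 0, tropical_sd))
    stats::qnorm(u, 0, tropical_sd)
  }
  w <- stats::rlnorm(n_species, width_meanlog, width_sdlog)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("degenerate range-width distribution: widths must be positive",
         call. = FALSE)
  lo <- pmax(mid - w / 2, grid$lower)
  hi <- pmin(mid + w / 2, grid$upper)
  sp <- sprintf("sp%05d", seq_len(n_species))
  occ <- matrix(FALSE, n_species, grid$n_bands, dimnames = list(sp, NULL))
  b_lo <- band_index(lo, grid); b_hi <- band_index(hi, grid)
  for (i in seq_len(n_species)) occ[i, b_lo[i]:b_hi[i]] <- TRUE
  habit <- ifelse(stats::runif(n_species) < p_benthic, "benthic", "pelagic")
  depth <- stats::rlnorm(n_species, depth_meanlog, depth_sdlog)
  structure(list(
    species = data.frame(species = sp, lat_min = lo, lat_max = hi,
                         habit = habit, depth_m = depth,
                         stringsAsFactors = FALSE),
    occupancy = occ, richness = as.integer(colSums(occ)),
    grid = grid, seed = seed), class = "true_world")
}

#' @export
print.true_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d species, %d bands, richness %d-%d per band\n",
              nrow(x$species), x$grid$n_bands, min(x$richness), max(x$richness)))
  invisible(x)
}

#' Latitude-dependent sampling-effort profile
#'
#' Expected number of sampling events per band. The `"bimodal"` preset
#' emulates the effort pattern of global marine surveying: peaks at
#' mid-latitudes (band centres within `peak_halfwidth` of `peak_lat` in
#' either hemisphere), a trough at the equator at `trough_ratio` times the
#' peak rate, linear shoulders in between, and a taper back to the trough
#' rate toward the poles.
#'
#' @param grid A [band_grid()].
#' @param type `"uniform"` or `"bimodal"`.
#' @param events_per_band Peak (or uniform) expected events per band.
#' @param trough_ratio Equatorial rate as a fraction of the peak (default
#'   1/30).
#' @param peak_lat,peak_halfwidth Centre and half-width of the mid-latitude
#'   plateau, degrees.
#' @param trough_halfwidth Half-width of the equatorial trough, degrees.
#' @return Numeric vector of per-band rates, class `effort_profile`, with the
#'   grid attached as attribute `grid`.
#' @export
effort_profile <- function(grid = band_grid(),
                           type = c("uniform", "bimodal"),
                           events_per_band = 500, trough_ratio = 1 / 30,
                           peak_lat = 40, peak_halfwidth = 10,
                           trough_halfwidth = 15) {
  type <- match.arg(type)
  ctr <- band_bounds(grid)$lat_mid
  shape <- if (type == "uniform") rep(1, grid$n_bands) else {
    a <- abs(ctr)
    inner <- peak_lat - peak_halfwidth
    outer <- peak_lat + peak_halfwidth
    pole <- max(abs(c(grid$lower, grid$upper)))
    s <- numeric(length(a))
    s[a <= trough_halfwidth] <- trough_ratio
    ramp <- a > trough_halfwidth & a < inner
    s[ramp] <- trough_ratio + (1 - trough_ratio) *
      (a[ramp] - trough_halfwidth) / (inner - trough_halfwidth)
    s[a >= inner & a <= outer] <- 1
    taper <- a > outer
    s[taper] <- trough_ratio + (1 - trough_ratio) *
      pmax(0, (pole - a[taper]) / (pole - outer))
    s
  }
  structure(events_per_band * shape, class = "effort_profile", grid = grid)
}

#' Detection model
#'
#' Per-event, per-species detection: a species truly present in a band is
#' recorded at a sampling event in that band with probability `p`. With
#' `sdlog > 0`, species-specific probabilities are drawn lognormal with
#' median `p` (capped at 1), emulating the detectability spread of real
#' assemblages, where many species are rare.
#'
#' @param p Median per-event detection probability.
#' @param sdlog Lognormal spread of species detectabilities (0 = identical).
#' @return Object of class `detection_model`.
#' @export
detection_model <- function(p = 0.1, sdlog = 0) {
  stopifnot(p >= 0, p <= 1, sdlog >= 0)
  structure(list(p = p, sdlog = sdlog), class = "detection_model")
}

#' Noise rates for QC-violating records
#'
#' Rates (per clean base record) at which the generator injects each class of
#' defective row: on-land coordinates (inside [synthetic_land_mask()]'s
#' rectangle), (0, 0) coordinates, out-of-bounds latitudes, exact duplicates,
#' and undated copies of existing records.
#'
#' @param on_land,zero_coordinates,out_of_bounds,duplicates,missing_date
#'   Non-negative rates.
#' @return Named list of class `noise_rates`.
#' @export
noise_rates <- function(on_land = 0, zero_coordinates = 0, out_of_bounds = 0,
                        duplicates = 0, missing_date = 0) {
  r <- list(on_land = on_land, zero_coordinates = zero_coordinates,
            out_of_bounds = out_of_bounds, duplicates = duplicates,
            missing_date = missing_date)
  stopifnot(all(unlist(r) >= 0))
  structure(r, class = "noise_rates")
}

#' Land mask matching the generator's on-land noise
#'
#' The generator places its on-land noise records inside a fixed rectangle
#' (latitude 44-46, longitude 40-50); this predicate flags exactly that
#' rectangle, standing in for a buffered-coastline test.
#'
#' @param lat,lon Numeric vectors.
#' @return Logical vector, `TRUE` on land.
#' @export
synthetic_land_mask <- function(lat, lon) {
  !is.na(lat) & !is.na(lon) & lat >= 44 & lat <= 46 & lon >= 40 & lon <= 50
}

#' Smooth synthetic bathymetry table
#'
#' A deterministic seafloor-depth surface on a regular grid, for exercising
#' the stratification fallback without a real raster: depth deepens away
#' from the poles and undulates with longitude, spanning the euphotic through
#' abyssal range.
#'
#' @param res Node spacing in degrees.
#' @return Data frame (`lat`, `lon`, `depth`) suitable for
#'   [bathymetry_grid()].
#' @export
synthetic_bathymetry <- function(res = 5) {
  g <- expand.grid(lat = seq(-80, 85, by = res),
                   lon = seq(-180, 180, by = res))
  g$depth <- 100 + 3000 * (1 - abs(g$lat) / 90) +
    2000 * (1 + sin(g$lon * pi / 90)) / 2
  g
}

#' Simulate occurrence records from a synthetic world
#'
#' Draws sampling events band by band (Poisson counts at the effort profile's
#' rate, uniform coordinates within the band, dates uniform in the window),
#' then records each truly-present species at each event with its detection
#' probability. Optional noise injection appends QC-violating rows at the
#' configured rates. Output is in the raw-record format that [apply_qc()]
#' consumes.
#'
#' @param world A [make_world()] object.
#' @param effort An [effort_profile()] on the same grid.
#' @param det A [detection_model()].
#' @param seed Integer seed.
#' @param noise A [noise_rates()] object.
#' @param date_window Two dates bounding event dates.
#' @param depth_missing_rate Fraction of records whose sample depth is
#'   withheld (emulating incomplete depth capture).
#' @param group Taxon-group label stamped on every record.
#' @return Data frame of raw records (`scientific_name`, `latitude`,
#'   `longitude`, `event_date`, `sample_depth_m`, `taxon_rank`,
#'   `taxon_group`).
#' @export
simulate_records <- function(world, effort, det = detection_model(), seed = 1,
                             noise = noise_rates(),
                             date_window = as.Date(c("1950-01-01",
                                                     "2015-12-31")),
                             depth_missing_rate = 1 / 3,
                             group = "synthetic") {
  grid <- world$grid
  lambda <- as.numeric(effort)
  stopifnot(length(lambda) == grid$n_bands, all(lambda >= 0))
  if (!is.null(attr(effort, "grid")) && !same_grid(attr(effort, "grid"), grid))
    stop("effort profile and world use different grids", call. = FALSE)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  S <- nrow(world$species)
  p_s <- if (det$sdlog > 0)
    pmin(1, stats::rlnorm(S, log(det$p), det$sdlog)) else rep(det$p, S)
  bb <- band_bounds(grid)
  span <- as.integer(date_window[2] - date_window[1]) + 1L
  sp_i <- list(); ev_lat <- list(); ev_lon <- list(); ev_date <- list()
  for (b in seq_len(grid$n_bands)) {
    n_e <- stats::rpois(1, lambda[b])
    present <- which(world$occupancy[, b])
    if (n_e == 0 || length(present) == 0) next
    lat_e <- stats::runif(n_e, bb$lat_low[b], bb$lat_high[b])
    lon_e <- stats::runif(n_e, -180, 180)
    date_e <- date_window[1] + sample.int(span, n_e, replace = TRUE) - 1L
    hit <- which(matrix(stats::runif(n_e * length(present)) <
                          rep(p_s[present], each = n_e),
                        nrow = n_e), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    sp_i[[b]] <- present[hit[, 2]]
    ev_lat[[b]] <- lat_e[hit[, 1]]
    ev_lon[[b]] <- lon_e[hit[, 1]]
    ev_date[[b]] <- date_e[hit[, 1]]
  }
  sp_i <- unlist(sp_i); n <- length(sp_i)
  if (n == 0) {
    return(data.frame(scientific_name = character(0), latitude = numeric(0),
                      longitude = numeric(0), event_date = as.Date(character(0)),
                      sample_depth_m = numeric(0), taxon_rank = character(0),
                      taxon_group = character(0), stringsAsFactors = FALSE))
  }
  rec <- data.frame(
    scientific_name = world$species$species[sp_i],
    latitude = unlist(ev_lat), longitude = unlist(ev_lon),
    event_date = as.Date(unlist(ev_date), origin = "1970-01-01"),
    sample_depth_m = world$species$depth_m[sp_i] *
      stats::rlnorm(n, 0, 0.3),
    taxon_rank = "species", taxon_group = group,
    stringsAsFactors = FALSE)
  if (n > 0 && depth_missing_rate > 0)
    rec$sample_depth_m[stats::runif(n) < depth_missing_rate] <- NA_real_

  if (n > 0) {
    rnd_species <- function(k) world$species$species[
      sample.int(S, k, replace = TRUE)]
    rnd_dates <- function(k) date_window[1] +
      sample.int(span, k, replace = TRUE) - 1L
    blank <- function(k, lat, lon) data.frame(
      scientific_name = rnd_species(k), latitude = lat, longitude = lon,
      event_date = rnd_dates(k), sample_depth_m = NA_real_,
      taxon_rank = "species", taxon_group = group, stringsAsFactors = FALSE)
    extras <- list()
    k <- stats::rbinom(1, n, noise$on_land)
    if (k > 0) extras$land <- blank(k, stats::runif(k, 44, 46),
                                    stats::runif(k, 40, 50))
    k <- stats::rbinom(1, n, noise$zero_coordinates)
    if (k > 0) extras$zero <- blank(k, 0, 0)
    k <- stats::rbinom(1, n, noise$out_of_bounds)
    if (k > 0) {
      south <- stats::runif(k) < 0.5
      extras$oob <- blank(k, ifelse(south, stats::runif(k, -90, -80.5),
                                    stats::runif(k, 85.5, 90)),
                          stats::runif(k, -180, 180))
    }
    k <- stats::rbinom(1, n, noise$duplicates)
    if (k > 0) extras$dup <- rec[sample.int(n, k, replace = TRUE), ]
    k <- stats::rbinom(1, n, noise$missing_date)
    if (k > 0) {
      und <- rec[sample.int(n, k, replace = TRUE), ]
      und$event_date <- as.Date(NA)
      extras$undated <- und
    }
    if (length(extras)) rec <- rbind(rec, do.call(rbind, extras))
    rec <- rec[sample.int(nrow(rec)), ]
  }
  rownames(rec) <- NULL
  rec
}

#' Name-status table accepting every species of a world
#'
#' @param world A [make_world()] object.
#' @return A [name_status_table()] marking every species accepted.
#' @export
world_names_table <- function(world) {
  name_status_table(world$species$species, "accepted")
}

#' Ground-truth recovery report
#'
#' Compares pipeline output with a synthetic world's truth: per band, the
#' true richness, observed richness, gap-based missing richness, and the
#' number of species truly present but unrecorded. The capture fraction is
#' the share of truly-present-but-unrecorded (species, band) cells that the
#' gap statistic flags; absences outside a species' recorded extent (edge
#' truncation) are invisible to the statistic and count as uncaptured.
#'
#' @param world A [make_world()] object.
#' @param occupancy An [build_occupancy()] matrix computed from records
#'   simulated on the same grid.
#' @return List of class `recovery_report`: `bands` (data frame: `band`,
#'   `lat_low`, `lat_high`, `true_richness`, `observed`, `missing`,
#'   `n_unrecorded`, `n_captured`) and `capture_fraction` (`NA` when nothing
#'   was unrecorded).
#' @export
recovery_report <- function(world, occupancy) {
  if (!same_grid(world$grid, occupancy$grid))
    stop("world and occupancy use different grids", call. = FALSE)
  sp_true <- world$species$species
  unknown <- setdiff(occupancy$species, sp_true)
  if (length(unknown))
    stop("occupancy contains species absent from the world: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  nb <- world$grid$n_bands
  obs <- matrix(FALSE, length(sp_true), nb, dimnames = list(sp_true, NULL))
  gap <- matrix(FALSE, length(sp_true), nb, dimnames = list(sp_true, NULL))
  if (length(occupancy$species) > 0) {
    obs[occupancy$species, ] <- occupancy$presence
    sp <- range_span(occupancy$presence)
    cols <- matrix(seq_len(nb), nrow = length(occupancy$species), ncol = nb,
                   byrow = TRUE)
    gap[occupancy$species, ] <- (cols > sp$first & cols < sp$last) &
      !occupancy$presence
  }
  unrecorded <- world$occupancy & !obs
  captured <- unrecorded & gap
  bands <- data.frame(band_bounds(world$grid)[, c("band", "lat_low", "lat_high")],
                      true_richness = world$richness,
                      observed = as.integer(colSums(obs)),
                      missing = as.integer(colSums(gap)),
                      n_unrecorded = as.integer(colSums(unrecorded)),
                      n_captured = as.integer(colSums(captured)))
  structure(list(bands = bands,
                 capture_fraction = if (sum(unrecorded) == 0) NA_real_ else
                   sum(captured) / sum(unrecorded)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Ground-truth recovery report\n")
  cat(sprintf("  true species-band cells unrecorded: %d\n",
              sum(x$bands$n_unrecorded)))
  cat(sprintf("  captured by the gap statistic:      %d (fraction %s)\n",
              sum(x$bands$n_captured),
              ifelse(is.na(x$capture_fraction), "NA",
                     sprintf("%.3f", x$capture_fraction))))
  invisible(x)
}
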