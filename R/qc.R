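#' Default Darwin Core column map
#'
#' Maps the canonical internal field names to the Darwin Core column names
#' used by OBIS/GBIF occurrence downloads. Any entry can be overridden when
#' calling [read_occurrences()].
#'
#' @return Named character vector: internal field -> source column.
#' @export
dwc_column_map <- function() {
  c(scientific_name = "scientificName",
    latitude        = "decimalLatitude",
    longitude       = "decimalLongitude",
    event_date      = "eventDate",
    sample_depth_m  = "minimumDepthInMeters",
    taxon_rank      = "taxonRank",
    taxon_group     = "taxonGroup")
}

#' Read an occurrence table
#'
#' Reads a delimited occurrence file into the canonical raw-record data frame
#' used by the rest of the pipeline. Coordinates and depths that fail to parse
#' as numbers become `NA`, as do unparseable dates; no rounding or filtering
#' happens at read time (see [apply_qc()]).
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named character vector mapping internal fields
#'   (`scientific_name`, `latitude`, `longitude`, `event_date`,
#'   `sample_depth_m`, `taxon_rank`, `taxon_group`) to source column names.
#'   Defaults to Darwin Core names ([dwc_column_map()]). Fields mapped to
#'   columns absent from the file are an error, except the optional
#'   `sample_depth_m`, `taxon_rank` and `taxon_group`, which default to
#'   missing / `"species"` / `NA`.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A data frame of raw records with the canonical columns.
#' @export
read_occurrences <- function(path, column_map = dwc_column_map(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- dwc_column_map()
  cmap[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = c("NA", ""))
  required <- c("scientific_name", "latitude", "longitude", "event_date")
  missing_req <- required[!cmap[required] %in% names(raw)]
  if (length(missing_req))
    stop("column_map refers to columns absent from ", path, ": ",
         paste(cmap[missing_req], collapse = ", "), call. = FALSE)
  pick <- function(field, default = NA_character_) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  data.frame(
    scientific_name = as.character(pick("scientific_name")),
    latitude        = num(pick("latitude")),
    longitude       = num(pick("longitude")),
    event_date      = parse_event_date(pick("event_date")),
    sample_depth_m  = num(pick("sample_depth_m")),
    taxon_rank      = {
      r <- as.character(pick("taxon_rank", "species"))
      r[is.na(r)] <- "species"
      r
    },
    taxon_group     = as.character(pick("taxon_group")),
    stringsAsFactors = FALSE
  )
}

# lenient ISO-ish date parser; anything unparseable becomes NA
parse_event_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(x)
  out[ok] <- as.Date(suppressWarnings(
    vapply(x[ok], function(d) {
      p <- tryCatch(as.Date(d, tryFormats = c("%Y-%m-%d", "%Y/%m/%d", "%d/%m/%Y")),
                    error = function(e) as.Date(NA))
      as.numeric(p)
    }, numeric(1))))
  out
}

#' Build a name-status table
#'
#' The stand-in for a taxonomic backbone lookup: a table declaring, for every
#' raw name expected in the data, whether it is accepted, a synonym (with its
#' accepted name), or to be discarded (invalid, non-marine, fossil).
#'
#' @param raw_name Character vector of raw names.
#' @param status One of `"accepted"`, `"synonym"`, `"invalid"`,
#'   `"non_marine"`, `"fossil"` per name.
#' @param accepted_name Accepted name per entry; required for synonyms,
#'   defaults to `raw_name` for accepted entries.
#' @return A data frame of class `name_status_table`.
#' @export
name_status_table <- function(raw_name, status, accepted_name = NULL) {
  status <- match.arg(status, c("accepted", "synonym", "invalid",
                                "non_marine", "fossil"), several.ok = TRUE)
  status <- rep_len(status, length(raw_name))
  if (is.null(accepted_name)) accepted_name <- rep(NA_character_, length(raw_name))
  accepted_name <- as.character(rep_len(accepted_name, length(raw_name)))
  accepted_name[status == "accepted" & is.na(accepted_name)] <-
    raw_name[status == "accepted" & is.na(accepted_name)]
  if (any(status == "synonym" & is.na(accepted_name)))
    stop("synonym entries need an accepted_name", call. = FALSE)
  structure(data.frame(raw_name = as.character(raw_name), status = status,
                       accepted_name = accepted_name, stringsAsFactors = FALSE),
            class = c("name_status_table", "data.frame"))
}

# round half away from zero, to `digits` decimals (deterministic across
# platforms, unlike round()'s round-half-even)
round_away <- function(x, digits = 2) {
  m <- 10^digits
  # tiny guard so decimals stored just under a half-boundary (10.005 is
  # 10.004999... in binary) still round away from zero
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Quality-control filtering of occurrence records
#'
#' Applies the cleaning rules for marine occurrence data in a fixed, audited
#' order, returning the cleaned records and a [qc_report] accounting for every
#' dropped row. The rules, in order:
#'
#' 1. drop records with missing coordinates;
#' 2. drop records at exactly (0, 0);
#' 3. drop records on land (only when a `land_mask` is supplied; otherwise the
#'    step is skipped with a warning);
#' 4. round coordinates to 2 decimal places (half away from zero);
#' 5. drop records above species rank; collapse subspecies names to the
#'    binomial;
#' 6. resolve names against `names`: synonyms are mapped to their accepted
#'    name; invalid, non-marine and fossil names are dropped, each counted
#'    under its own rule; names absent from the table are dropped as
#'    `name_unresolved`;
#' 7. drop latitudes below -80 or above 85 (bounds inclusive: -80 and 85 are
#'    kept);
#' 8. deduplicate on (species name, latitude, longitude, date), keeping the
#'    first record; records with a missing date are kept only when their
#'    (name, latitude, longitude) combination is unique in the dataset.
#'
#' Negative sample depths are treated as data errors and set to missing (the
#' record itself is kept). The function is idempotent: re-running it on its
#' own output removes nothing.
#'
#' @param records Data frame of raw records as returned by
#'   [read_occurrences()] or [simulate_records()]. Cleaned frames (with a
#'   `species_name` column and no `taxon_rank`) are accepted too.
#' @param names A [name_status_table()] covering the raw names. Accepted
#'   names appearing as mapping targets are implicitly accepted.
#' @param land_mask Optional predicate `function(lat, lon)` returning `TRUE`
#'   for points on land (within the coastline buffer).
#' @return A list with elements `records` (cleaned data frame with columns
#'   `species_name`, `latitude`, `longitude`, `event_date`, `sample_depth_m`,
#'   `taxon_group`) and `report` (a `qc_report`).
#' @export
apply_qc <- function(records, names, land_mask = NULL) {
  stopifnot(is.data.frame(records))
  if (!inherits(names, "name_status_table"))
    stop("`names` must be a name_status_table", call. = FALSE)
  df <- records
  if (!"scientific_name" %in% base::names(df) && "species_name" %in% base::names(df))
    df$scientific_name <- df$species_name
  if (!"taxon_rank" %in% base::names(df)) df$taxon_rank <- "species"
  if (!"taxon_group" %in% base::names(df)) df$taxon_group <- NA_character_
  if (!"sample_depth_m" %in% base::names(df)) df$sample_depth_m <- NA_real_
  if (!"event_date" %in% base::names(df)) df$event_date <- as.Date(NA)
  df$event_date <- parse_event_date(df$event_date)

  n_input <- nrow(df)
  rules <- character(0); removed <- integer(0)
  log_rule <- function(rule, n) {
    rules <<- c(rules, rule); removed <<- c(removed, as.integer(n))
  }

  # 1. missing coordinates
  keep <- !is.na(df$latitude) & !is.na(df$longitude)
  log_rule("missing_coordinates", sum(!keep)); df <- df[keep, , drop = FALSE]

  # 2. (0, 0) coordinates
  keep <- !(df$latitude == 0 & df$longitude == 0)
  log_rule("zero_coordinates", sum(!keep)); df <- df[keep, , drop = FALSE]

  # 3. on-land records (pluggable coastline-buffer predicate)
  if (is.null(land_mask)) {
    warning("no land mask supplied; on-land filtering skipped", call. = FALSE)
    log_rule("on_land", 0L)
  } else {
    on_land <- land_mask(df$latitude, df$longitude)
    on_land[is.na(on_land)] <- FALSE
    log_rule("on_land", sum(on_land)); df <- df[!on_land, , drop = FALSE]
  }

  # 4. coordinate rounding (precedes deduplication deliberately)
  df$latitude <- round_away(df$latitude, 2)
  df$longitude <- round_away(df$longitude, 2)
  log_rule("round_coordinates", 0L)

  # 5. taxonomic rank
  keep <- df$taxon_rank %in% c("species", "subspecies")
  log_rule("not_species_level", sum(!keep)); df <- df[keep, , drop = FALSE]
  is_ssp <- df$taxon_rank == "subspecies"
  if (any(is_ssp)) {
    df$scientific_name[is_ssp] <- vapply(
      strsplit(df$scientific_name[is_ssp], "\\s+"),
      function(w) paste(utils::head(w, 2), collapse = " "), character(1))
  }

  # 6. name resolution
  lut_status <- stats::setNames(names$status, names$raw_name)
  lut_accept <- stats::setNames(names$accepted_name, names$raw_name)
  # accepted targets of the mapping are themselves valid names, so a cleaned
  # dataset passes straight through a second run
  targets <- unique(stats::na.omit(names$accepted_name))
  new_targets <- setdiff(targets, names$raw_name)
  if (length(new_targets)) {
    lut_status[new_targets] <- "accepted"
    lut_accept[new_targets] <- new_targets
  }
  st <- lut_status[df$scientific_name]
  st[is.na(st)] <- "unresolved"
  for (bad in c("invalid", "non_marine", "fossil", "unresolved")) {
    drop <- st == bad
    log_rule(paste0("name_", sub("^unresolved$", "unresolved", bad)), sum(drop))
    df <- df[!drop, , drop = FALSE]; st <- st[!drop]
  }
  df$species_name <- ifelse(st == "synonym" | st == "accepted",
                            unname(lut_accept[df$scientific_name]),
                            df$scientific_name)

  # 7. latitude bounds (inclusive)
  keep <- df$latitude >= -80 & df$latitude <= 85
  log_rule("latitude_bounds", sum(!keep)); df <- df[keep, , drop = FALSE]

  # 8. deduplication
  date_key <- ifelse(is.na(df$event_date), "<undated>",
                     format(df$event_date, "%Y-%m-%d"))
  full_key <- paste(df$species_name, df$latitude, df$longitude, date_key,
                    sep = "\r")
  coord_key <- paste(df$species_name, df$latitude, df$longitude, sep = "\r")
  coord_n <- table(coord_key)
  dup <- duplicated(full_key) |
    (is.na(df$event_date) & coord_n[coord_key] > 1)
  log_rule("duplicates", sum(dup)); df <- df[!dup, , drop = FALSE]

  # depth validation (records kept, bad depths blanked)
  bad_depth <- !is.na(df$sample_depth_m) & df$sample_depth_m < 0
  df$sample_depth_m[bad_depth] <- NA_real_

  out <- df[, c("species_name", "latitude", "longitude", "event_date",
                "sample_depth_m", "taxon_group")]
  rownames(out) <- NULL
  report <- structure(list(rules = data.frame(rule = rules,
                                              n_removed = removed,
                                              stringsAsFactors = FALSE),
                           n_input = n_input, n_output = nrow(out),
                           n_depth_blanked = sum(bad_depth),
                           land_mask_applied = !is.null(land_mask)),
                      class = "qc_report")
  stopifnot(report$n_input - sum(report$rules$n_removed) == report$n_output)
  list(records = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Occurrence quality-control report\n")
  cat(sprintf("  records in:  %d\n  records out: %d\n", x$n_input, x$n_output))
  if (!x$land_mask_applied)
    cat("  (on-land filtering skipped: no land mask supplied)\n")
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  %-22s %8d removed\n", x$rules$rule[i], x$rules$n_removed[i]))
  if (x$n_depth_blanked > 0)
    cat(sprintf("  negative sample depths set missing: %d\n", x$n_depth_blanked))
  invisible(x)
}

#' Write a QC report to JSON
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, n_output = report$n_output,
         land_mask_applied = report$land_mask_applied,
         rules = report$rules),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
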