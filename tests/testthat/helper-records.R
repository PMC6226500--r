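# build a raw-record data frame from parallel vectors, filling defaults
raw_records <- function(name, lat, lon, date = NA, depth = NA_real_,
                        rank = "species", group = "test") {
  n <- max(length(name), length(lat), length(lon), length(date), length(depth))
  data.frame(scientific_name = rep_len(name, n),
             latitude = rep_len(lat, n),
             longitude = rep_len(lon, n),
             event_date = as.Date(rep_len(date, n)),
             sample_depth_m = rep_len(depth, n),
             taxon_rank = rep_len(rank, n),
             taxon_group = rep_len(group, n),
             stringsAsFactors = FALSE)
}

# cleaned-record frame (skips QC for tests that start mid-pipeline)
clean_records <- function(name, lat, lon, date = NA, depth = NA_real_,
                          group = "test") {
  n <- max(length(name), length(lat), length(lon), length(date), length(depth))
  data.frame(species_name = rep_len(name, n),
             latitude = rep_len(lat, n),
             longitude = rep_len(lon, n),
             event_date = as.Date(rep_len(date, n)),
             sample_depth_m = rep_len(depth, n),
             taxon_group = rep_len(group, n),
             stringsAsFactors = FALSE)
}

# name table accepting every name it is given
accept_all <- function(names) name_status_table(unique(names), "accepted")

# brute-force gap definition: unoccupied bands strictly between the extreme
# occupied bands
brute_gaps <- function(v) {
  occ <- which(v)
  inside <- setdiff(seq(min(occ), max(occ)), occ)
  as.integer(inside)
}

# occupancy object from a logical presence matrix (counts = presence)
occupancy_from_matrix <- function(m, grid = band_grid(), species = NULL) {
  sp <- if (is.null(species)) sprintf("sp%04d", seq_len(nrow(m))) else species
  rownames(m) <- sp
  structure(list(species = sp, grid = grid,
                 counts = m + 0L, presence = m > 0),
            class = "occupancy")
}
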