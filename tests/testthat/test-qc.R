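test_that("read_occurrences passes values through without rounding and blanks unparseables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,decimalLatitude,decimalLongitude,eventDate,minimumDepthInMeters,taxonRank",
    "Aa bb,12.345678,-45.1,2001-05-04,10,species",
    "Cc dd,notanumber,7.2,,,species",
    "Ee ff,3.5,8.0,garbage-date,5,species"), f)
  r <- read_occurrences(f)
  expect_equal(nrow(r), 3)
  expect_equal(r$latitude[1], 12.345678)   # no rounding at read time
  expect_equal(r$longitude[1], -45.1)
  expect_true(is.na(r$latitude[2]))        # unparseable coordinate
  expect_true(is.na(r$event_date[2]))      # empty date
  expect_true(is.na(r$event_date[3]))      # unparseable date
  expect_equal(r$event_date[1], as.Date("2001-05-04"))
  expect_error(read_occurrences(file.path(tempdir(), "nope.csv")), "not found")
  expect_error(read_occurrences(f, column_map = c(latitude = "noSuchColumn")),
               "absent")
})

test_that("each QC rule drops what it should, in order", {
  names_tab <- name_status_table(
    raw_name = c("Good sp", "Old name", "Bad name", "Land sp", "Fossil sp",
                 "Sub species"),
    status = c("accepted", "synonym", "invalid", "non_marine", "fossil",
               "accepted"),
    accepted_name = c(NA, "Good sp", NA, NA, NA, NA))
  rec <- raw_records(
    name = c("Good sp", "Good sp", "Good sp", "Good sp", "Old name",
             "Bad name", "Land sp", "Fossil sp", "Mystery sp", "Good sp",
             "Sub species ssp"),
    lat = c(10.001, NA, 0, 87, 10.001, 10, 10, 10, 10, -80.5, 10),
    lon = c(20.004, 5, 0, 5, 20.001, 5, 5, 5, 5, 5, 5),
    date = as.Date("2000-01-01"),
    rank = c(rep("species", 10), "subspecies"))
  rec$taxon_rank[10] <- "higher"
  out <- suppressWarnings(apply_qc(rec, names_tab))
  rep <- out$report
  counts <- setNames(rep$rules$n_removed, rep$rules$rule)
  expect_equal(counts[["missing_coordinates"]], 1L)
  expect_equal(counts[["zero_coordinates"]], 1L)
  expect_equal(counts[["not_species_level"]], 1L)
  expect_equal(counts[["name_invalid"]], 1L)
  expect_equal(counts[["name_non_marine"]], 1L)
  expect_equal(counts[["name_fossil"]], 1L)
  expect_equal(counts[["name_unresolved"]], 1L)
  expect_equal(counts[["latitude_bounds"]], 1L)
  # rows 1 and 5: synonym resolves to Good sp at the same rounded coordinates
  # and date -> duplicate; subspecies collapses to the binomial "Sub species"
  expect_equal(counts[["duplicates"]], 1L)
  expect_equal(rep$n_input - sum(rep$rules$n_removed), rep$n_output)
  expect_setequal(out$records$species_name, c("Good sp", "Sub species"))
  expect_equal(out$records$latitude[out$records$species_name == "Good sp"], 10.00)
})

test_that("latitude bounds are inclusive and rounding is half away from zero", {
  rec <- raw_records("Aa bb", lat = c(-80, 85, 10.005, -10.005),
                     lon = c(1, 2, 3, 4), date = as.Date("2000-01-01"))
  out <- suppressWarnings(apply_qc(rec, accept_all("Aa bb")))
  expect_equal(nrow(out$records), 4)          # both extremes retained
  expect_equal(sort(out$records$latitude), c(-80, -10.01, 10.01, 85))
})

test_that("undated records survive only when their name/coordinates combination is unique", {
  rec <- raw_records("Aa bb",
                     lat = c(10, 10, 20), lon = c(5, 5, 5),
                     date = as.Date(c("2000-01-01", NA, NA)))
  out <- suppressWarnings(apply_qc(rec, accept_all("Aa bb")))
  # undated copy of a dated location is a duplicate; the unique undated
  # location is kept
  expect_equal(nrow(out$records), 2)
  expect_equal(sum(is.na(out$records$event_date)), 1)
  expect_equal(out$records$latitude[is.na(out$records$event_date)], 20)
})

test_that("a clean input passes untouched and the land mask is honoured", {
  rec <- raw_records("Aa bb", lat = c(10, 45), lon = c(5, 45),
                     date = as.Date(c("2000-01-01", "2000-01-02")))
  out <- suppressWarnings(apply_qc(rec, accept_all("Aa bb")))
  expect_equal(out$report$n_output, 2)
  expect_true(all(out$report$rules$n_removed == 0))
  out2 <- apply_qc(rec, accept_all("Aa bb"), land_mask = synthetic_land_mask)
  expect_equal(setNames(out2$report$rules$n_removed, out2$report$rules$rule)[["on_land"]], 1L)
  expect_warning(apply_qc(rec, accept_all("Aa bb")), "land mask")
})

test_that("QC is idempotent and order-insensitive on noisy synthetic data", {
  w <- make_world(n_species = 80, seed = 11)
  rec <- simulate_records(w, effort_profile(events_per_band = 80), seed = 11,
                          noise = noise_rates(0.02, 0.02, 0.02, 0.02, 0.02))
  nt <- world_names_table(w)
  pass1 <- apply_qc(rec, nt, land_mask = synthetic_land_mask)
  expect_equal(pass1$report$n_input - sum(pass1$report$rules$n_removed),
               pass1$report$n_output)
  pass2 <- apply_qc(pass1$records, nt, land_mask = synthetic_land_mask)
  expect_equal(sum(pass2$report$rules$n_removed), 0)
  expect_equal(nrow(pass2$records), nrow(pass1$records))
  # shuffling the input changes neither the size nor the retained keys
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  pass3 <- apply_qc(shuffled, nt, land_mask = synthetic_land_mask)
  expect_equal(pass3$report$n_output, pass1$report$n_output)
  key <- function(d) sort(paste(d$species_name, d$latitude, d$longitude,
                                d$event_date))
  expect_equal(key(pass3$records), key(pass1$records))
})

test_that("negative sample depths are blanked, not dropped", {
  rec <- raw_records("Aa bb", lat = c(10, 11), lon = 5,
                     date = as.Date("2000-01-01"), depth = c(-3, 40))
  out <- suppressWarnings(apply_qc(rec, accept_all("Aa bb")))
  expect_equal(nrow(out$records), 2)
  expect_true(is.na(out$records$sample_depth_m[out$records$latitude == 10]))
  expect_equal(out$report$n_depth_blanked, 1L)
})
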