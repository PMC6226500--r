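test_that("worlds are deterministic given a seed and every true range is an interval", {
  w1 <- make_world(n_species = 50, seed = 42)
  w2 <- make_world(n_species = 50, seed = 42)
  expect_identical(w1$occupancy, w2$occupancy)
  expect_identical(w1$species, w2$species)
  expect_false(identical(w1$occupancy, make_world(n_species = 50, seed = 43)$occupancy))
  for (s in seq_len(50)) {
    occ <- which(w1$occupancy[s, ])
    expect_equal(occ, seq(min(occ), max(occ)))    # no true gaps, ever
  }
  expect_error(make_world(10, width_meanlog = -Inf, seed = 1), "degenerate")
})

test_that("a single species' true bands are those intersecting its interval", {
  # force a known interval by making the width distribution near-degenerate
  w <- make_world(n_species = 1, midpoint_range = c(0, 0),
                  width_meanlog = log(30), width_sdlog = 1e-12, seed = 1)
  expect_equal(w$species$lat_min, -15, tolerance = 1e-6)
  expect_equal(w$species$lat_max, 15, tolerance = 1e-6)
  g <- w$grid
  expect_equal(which(w$occupancy[1, ]),
               seq(band_index(-15, g), band_index(15, g)))
})

test_that("tropical worlds concentrate richness near the equator", {
  rich <- Reduce(`+`, lapply(1:15, function(s)
    make_world(n_species = 100, richness_shape = "unimodal-tropical",
               seed = s)$richness))
  peak <- band_bounds(band_grid())$lat_mid[which.max(rich)]
  expect_lt(abs(peak), 15)
})

test_that("perfect detection recovers the true occupancy with no missing richness", {
  w <- make_world(n_species = 40, seed = 9)
  rec <- simulate_records(w, effort_profile(events_per_band = 10),
                          det = detection_model(p = 1), seed = 9)
  rec$species_name <- rec$scientific_name
  occ <- build_occupancy(rec, w$grid, species = w$species$species)
  expect_identical(unname(occ$presence), unname(w$occupancy))
  expect_true(all(richness_vectors(occ)$missing == 0))
  rr <- recovery_report(w, occ)
  expect_true(is.na(rr$capture_fraction))         # nothing unrecorded
  expect_equal(rr$bands$observed, rr$bands$true_richness)
})

test_that("zero effort yields zero records and seeds reproduce simulations exactly", {
  w <- make_world(n_species = 20, seed = 2)
  none <- effort_profile(events_per_band = 0)
  expect_equal(nrow(simulate_records(w, none, seed = 1)), 0)
  r1 <- simulate_records(w, effort_profile(events_per_band = 30), seed = 5)
  r2 <- simulate_records(w, effort_profile(events_per_band = 30), seed = 5)
  expect_identical(r1, r2)
})

test_that("the recovery report separates capturable interior absences from edge truncation", {
  g <- band_grid()
  sp <- data.frame(species = "sp00001", lat_min = -30, lat_max = -10,
                   habit = "benthic", depth_m = 100, stringsAsFactors = FALSE)
  occ_true <- matrix(seq_len(33) %in% 11:15, 1, 33,
                     dimnames = list("sp00001", NULL))
  w <- structure(list(species = sp, occupancy = occ_true,
                      richness = as.integer(colSums(occ_true)),
                      grid = g, seed = 1), class = "true_world")
  # unsampled interior band: flagged by the gap statistic
  m <- matrix(seq_len(33) %in% c(11, 12, 14, 15), 1, 33)
  rr <- recovery_report(w, occupancy_from_matrix(m, g, "sp00001"))
  expect_equal(rr$capture_fraction, 1)
  expect_equal(rr$bands$n_unrecorded[13], 1L)
  expect_equal(rr$bands$n_captured[13], 1L)
  # unsampled range-edge band: invisible to the statistic
  m2 <- matrix(seq_len(33) %in% 11:14, 1, 33)
  rr2 <- recovery_report(w, occupancy_from_matrix(m2, g, "sp00001"))
  expect_equal(rr2$capture_fraction, 0)
  expect_equal(rr2$bands$n_unrecorded[15], 1L)
  expect_equal(rr2$bands$n_captured[15], 0L)
  # grid mismatch is an error
  expect_error(recovery_report(w, occupancy_from_matrix(
    matrix(TRUE, 1, 11), band_grid(-80, 85, 15), "sp00001")), "grids")
})

test_that("missing richness never exceeds unrecorded truth within the observed extent", {
  for (s in 1:5) {
    w <- make_world(n_species = 80, seed = 100 + s)
    rec <- simulate_records(w, effort_profile(events_per_band = 20),
                            det = detection_model(0.05), seed = 200 + s)
    if (nrow(rec) == 0) next
    rec$species_name <- rec$scientific_name
    occ <- build_occupancy(rec, w$grid)
    rr <- recovery_report(w, occ)
    # every flagged gap is a genuine unrecorded presence (clean simulation:
    # observations never fall outside true ranges)
    expect_true(all(rr$bands$missing <= rr$bands$n_unrecorded))
    expect_true(all(rr$bands$n_captured == rr$bands$missing))
  }
})
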