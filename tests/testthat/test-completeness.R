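test_that("sample coverage matches its closed form and limiting cases", {
  expect_equal(sample_coverage(10, 2, 1), 0.82)       # 1 - 0.2 * (18/20)
  expect_equal(sample_coverage(100, 0, 5), 1)
  expect_equal(sample_coverage(7, 7, 0), 0)           # all singletons
  expect_true(is.na(sample_coverage(0, 0, 0)))
  expect_equal(sample_coverage(1, 1, 0), 0)
  expect_error(sample_coverage(3, 2, 1), "exceed")
  expect_error(sample_coverage(-1, 0, 0))
})

test_that("coverage is monotone in the rare-species counts", {
  # more singletons at fixed n, f2 never raises coverage
  cov <- vapply(0:6, function(f1) sample_coverage(20, f1, 2), numeric(1))
  expect_true(all(diff(cov) <= 0))
  # converting a singleton to a doubleton by one extra record never lowers it
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:200, 1); f2 <- sample(0:5, 1)
    f1 <- sample(seq_len(max(1, n - 2 * f2 - 1)), 1)
    expect_gte(sample_coverage(n + 1, f1 - 1, f2 + 1),
               sample_coverage(n, f1, f2) - 1e-12)
  }
})

test_that("accumulation curves behave at the degenerate extremes", {
  # every event sees all species: curve constant at S
  inc <- matrix(TRUE, 5, 4)
  expect_equal(accumulation_curve(inc, method = "exact"), rep(4, 5))
  expect_equal(accumulation_curve(inc, n_perm = 10, seed = 1), rep(4, 5))
  # every event contributes exactly one new species: curve is the diagonal
  expect_equal(accumulation_curve(diag(6) > 0, method = "exact"), 1:6)
  expect_error(accumulation_curve(matrix(FALSE, 0, 2)), "at least one")
})

test_that("the exact curve equals the full permutation average and Monte-Carlo converges to it", {
  # worked 3-event example: {A,B}, {B}, {C}
  inc <- rbind(c(TRUE, TRUE, FALSE),
               c(FALSE, TRUE, FALSE),
               c(FALSE, FALSE, TRUE))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  oracle <- colMeans(t(apply(perms, 1, function(p) {
    seen <- matrix(FALSE, 1, 3)
    vapply(seq_len(3), function(k) {
      seen[inc[p[k], ]] <<- TRUE
      sum(seen)
    }, numeric(1))
  })))
  expect_equal(oracle, c(4 / 3, 7 / 3, 3))
  expect_equal(accumulation_curve(inc, method = "exact"), oracle,
               tolerance = 1e-12)
  mc <- accumulation_curve(inc, n_perm = 5000, seed = 7)
  expect_lt(max(abs(mc - oracle)), 0.03)
  # bit-for-bit reproducible at a fixed seed, different across seeds
  expect_identical(accumulation_curve(inc, n_perm = 50, seed = 3),
                   accumulation_curve(inc, n_perm = 50, seed = 3))
})

test_that("the exact curve agrees with an established accumulation implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  comm <- matrix(rbinom(30 * 12, 1, 0.25), nrow = 30)
  comm <- comm[, colSums(comm) > 0]
  ours <- accumulation_curve(comm > 0, method = "exact")
  ref <- vegan::specaccum(comm, method = "exact")$richness
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("curves are non-decreasing and end at the observed species count", {
  set.seed(13)
  for (i in 1:10) {
    inc <- matrix(runif(25 * 8) < 0.3, 25, 8)
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
    if (ncol(inc) == 0) next
    for (m in c("exact", "random")) {
      cv <- accumulation_curve(inc, n_perm = 30, seed = i, method = m)
      expect_true(all(diff(cv) >= -1e-12))
      expect_equal(cv[length(cv)], ncol(inc))
    }
  }
})

test_that("tail curvilinearity maps to [0,1] and respects the event threshold", {
  flat <- c(seq_len(20), rep(20, 80))
  expect_equal(sac_completeness(flat), 1)
  expect_equal(sac_completeness(seq_len(100)), 0)      # one new species/event
  expect_true(is.na(sac_completeness(seq_len(40))))    # at the threshold
  expect_false(is.na(sac_completeness(seq_len(41))))
  # tail length is floor(10%) but at least one event
  curve <- c(1, 2, rep(2, 40))
  expect_equal(sac_completeness(curve, min_events = 10), 1)
})

test_that("per-band completeness combines both estimators with NA where undefined", {
  g <- band_grid()
  # empty band: everything NA/0
  ct0 <- completeness_by_band(clean_records("x", 1, 1)[0, ], g)
  expect_true(all(is.na(ct0$coverage)) && all(is.na(ct0$sac)))
  # heavy singleton load: 10 species, one record each -> coverage 0
  r <- clean_records(sprintf("sp%02d", 1:10), lat = 2, lon = 1:10,
                     date = as.Date("2000-01-01"))
  ct <- completeness_by_band(r, g)
  expect_equal(ct$f1[17], 10L)
  expect_lt(ct$coverage[17], 0.5)
  expect_true(is.na(ct$sac[17]))                 # only 10 events
  # many replicated full events: both estimators reach 1
  r2 <- clean_records(rep(c("Aa", "Bb", "Cc"), 60),
                      lat = 2, lon = rep(1:60, each = 3),
                      date = as.Date("2000-01-01"))
  ct2 <- completeness_by_band(r2, g, n_perm = 20, seed = 1)
  expect_equal(ct2$coverage[17], 1)
  expect_equal(ct2$sac[17], 1)
  expect_equal(ct2$n_events[17], 60L)
  # exact and random SAC agree on a well-sampled band
  ct3 <- completeness_by_band(r2, g, sac_method = "exact")
  expect_equal(ct3$sac[17], ct2$sac[17], tolerance = 0.02)
})
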