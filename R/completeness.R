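#' Sample coverage from singleton and doubleton counts
#'
#' Coverage estimates the proportion of individuals in the assemblage that
#' belong to species already recorded, from the record total `n` and the
#' counts of species seen exactly once (`f1`) and exactly twice (`f2`):
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.}
#' A band with no singletons has estimated coverage 1; a band where every
#' record is a different species has coverage 0.
#'
#' @param n Total number of records (specimen proxy).
#' @param f1 Number of singleton species.
#' @param f2 Number of doubleton species.
#' @return Coverage in `[0, 1]`; `NA` when `n == 0`; 0 when `n == 1`.
#' @examples
#' sample_coverage(10, 2, 1)  # 0.82
#' @export
sample_coverage <- function(n, f1, f2) {
  stopifnot(length(n) == 1, length(f1) == 1, length(f2) == 1,
            n >= 0, f1 >= 0, f2 >= 0)
  if (f1 + 2 * f2 > n)
    stop("f1 + 2*f2 cannot exceed n", call. = FALSE)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  if (f1 == 0) return(1)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Species accumulation curve over sampling events
#'
#' Expected number of distinct species in the first `k` sampling events when
#' events are accumulated in random order. `method = "random"` averages
#' `n_perm` random orderings (reproducible at a fixed seed);
#' `method = "exact"` evaluates the analytic expectation
#' \deqn{E[S(k)] = \sum_s \left(1 - \binom{n - n_s}{k} / \binom{n}{k}\right)}
#' where \eqn{n_s} is the number of events containing species `s` — equal to
#' the average over all `n!` orderings.
#'
#' @param incidence Logical (or 0/1) event-by-species matrix with at least
#'   one event.
#' @param n_perm Number of random orderings (`method = "random"`).
#' @param seed Integer seed; required for `method = "random"`.
#' @param method `"random"` or `"exact"`.
#' @return Numeric vector of length `nrow(incidence)`; non-decreasing, with
#'   final value equal to the number of species observed in any event.
#' @export
accumulation_curve <- function(incidence, n_perm = 100, seed = NULL,
                               method = c("random", "exact")) {
  method <- match.arg(method)
  incidence <- as.matrix(incidence) > 0
  n_ev <- nrow(incidence)
  if (is.null(n_ev) || n_ev < 1 || ncol(incidence) < 1)
    stop("incidence matrix needs at least one event and one species",
         call. = FALSE)
  ns <- colSums(incidence)
  keep <- ns > 0
  ns <- ns[keep]
  if (method == "exact") {
    k <- seq_len(n_ev)
    # log-scale hypergeometric term; choose(n - ns, k) is 0 when k > n - ns
    curve <- vapply(k, function(kk) {
      miss <- exp(lchoose(n_ev - ns, kk) - lchoose(n_ev, kk))
      miss[n_ev - ns < kk] <- 0
      sum(1 - miss)
    }, numeric(1))
    return(curve)
  }
  if (is.null(seed)) stop("a seed is required for method = 'random'",
                          call. = FALSE)
  stopifnot(n_perm >= 1)
  ev_by_sp <- apply(incidence[, keep, drop = FALSE], 2, which, simplify = FALSE)
  acc <- numeric(n_ev)
  pos <- integer(n_ev)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(n_perm)) {
    pos[sample.int(n_ev)] <- seq_len(n_ev)
    first <- vapply(ev_by_sp, function(ix) min(pos[ix]), numeric(1))
    acc <- acc + cumsum(tabulate(first, n_ev))
  }
  acc / n_perm
}

# seed hygiene: functions taking an explicit seed must not disturb the
# caller's RNG stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Completeness from the tail slope of an accumulation curve
#'
#' The curvilinearity measure: one minus the mean per-event species gain over
#' the final fraction of the curve, clamped to `[0, 1]`. A saturated (flat)
#' tail gives completeness 1; a curve still gaining one species per event
#' gives 0. Bands with `min_events` or fewer events are too short for the
#' tail to be meaningful, and return `NA`.
#'
#' @param curve Expected accumulation curve (length `n_events`).
#' @param n_events Number of events; defaults to `length(curve)`.
#' @param tail_fraction Fraction of the curve used as tail (default 0.10).
#' @param min_events Completeness is only computed when
#'   `n_events > min_events` (default 40).
#' @return Completeness in `[0, 1]`, or `NA`.
#' @export
sac_completeness <- function(curve, n_events = length(curve),
                             tail_fraction = 0.10, min_events = 40) {
  stopifnot(n_events == length(curve))
  if (n_events <= min_events) return(NA_real_)
  m <- max(1L, floor(tail_fraction * n_events))
  slope <- (curve[n_events] - curve[n_events - m]) / m
  min(max(1 - slope, 0), 1)
}

# internal: exact-expectation tail slope without building the whole curve;
# evaluates E[S(n)] - E[S(n - m)] analytically
sac_completeness_exact <- function(ns, n_events, tail_fraction = 0.10,
                                   min_events = 40) {
  if (n_events <= min_events) return(NA_real_)
  m <- max(1L, floor(tail_fraction * n_events))
  e_at <- function(k) {
    miss <- exp(lchoose(n_events - ns, k) - lchoose(n_events, k))
    miss[n_events - ns < k] <- 0
    sum(1 - miss)
  }
  slope <- (e_at(n_events) - e_at(n_events - m)) / m
  min(max(1 - slope, 0), 1)
}

# internal: per-band abundance and incidence structures
band_incidence <- function(records, grid, band) {
  b <- band_index(records$latitude, grid)
  rec <- records[b == band, , drop = FALSE]
  abund <- table(rec$species_name)
  key <- event_key(rec)
  list(records = rec, n_records = nrow(rec),
       n_events = length(unique(key)),
       abundance = abund,
       f1 = sum(abund == 1), f2 = sum(abund == 2),
       event_key = key)
}

#' Per-band inventory completeness
#'
#' Computes, for every band: record and event counts, singleton/doubleton
#' counts, sample coverage, and accumulation-curve completeness. Coverage is
#' computed for any band with at least 2 records; the accumulation-curve
#' estimate only for bands with more than `min_events` events. Undefined
#' values are `NA`, never 0.
#'
#' @param records Cleaned occurrence data frame.
#' @param grid A [band_grid()].
#' @param n_perm Random orderings per band (`sac_method = "random"`).
#' @param seed Base seed; band `b` uses `seed + b` so bands are independent
#'   but the whole table is reproducible.
#' @param min_events Event threshold for the accumulation-curve estimate.
#' @param tail_fraction Tail fraction for [sac_completeness()].
#' @param sac_method `"random"` (Monte-Carlo, the default) or `"exact"`
#'   (analytic expectation).
#' @return Data frame of class `completeness_table`: `band`, `lat_low`,
#'   `lat_high`, `n_records`, `n_events`, `f1`, `f2`, `coverage`, `sac`.
#' @export
completeness_by_band <- function(records, grid = band_grid(), n_perm = 100,
                                 seed = 1, min_events = 40,
                                 tail_fraction = 0.10,
                                 sac_method = c("random", "exact")) {
  sac_method <- match.arg(sac_method)
  bb <- band_bounds(grid)
  out <- data.frame(bb[, c("band", "lat_low", "lat_high")],
                    n_records = 0L, n_events = 0L, f1 = 0L, f2 = 0L,
                    coverage = NA_real_, sac = NA_real_)
  if (nrow(records) == 0) {
    class(out) <- c("completeness_table", "data.frame")
    return(out)
  }
  b_all <- band_index(records$latitude, grid)
  for (b in seq_len(grid$n_bands)) {
    rec <- records[b_all == b, , drop = FALSE]
    if (nrow(rec) == 0) next
    abund <- table(rec$species_name)
    key <- event_key(rec)
    n_ev <- length(unique(key))
    out$n_records[b] <- nrow(rec)
    out$n_events[b] <- n_ev
    out$f1[b] <- sum(abund == 1)
    out$f2[b] <- sum(abund == 2)
    if (nrow(rec) >= 2)
      out$coverage[b] <- sample_coverage(nrow(rec), out$f1[b], out$f2[b])
    if (n_ev > min_events) {
      ev_f <- factor(key)
      ns <- colSums(table(ev_f, rec$species_name) > 0)
      if (sac_method == "exact") {
        out$sac[b] <- sac_completeness_exact(ns, n_ev, tail_fraction,
                                             min_events)
      } else {
        inc <- table(ev_f, rec$species_name) > 0
        curve <- accumulation_curve(inc, n_perm = n_perm, seed = seed + b,
                                    method = "random")
        out$sac[b] <- sac_completeness(curve, n_ev, tail_fraction, min_events)
      }
    }
  }
  class(out) <- c("completeness_table", "data.frame")
  out
}
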