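# Shared fixture builders. Everything is generated in code; no data files.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# A fix table from parallel vectors, with sensible defaults.
make_fixes <- function(lon, lat, timestamp, individual_id = "b1",
                       altitude = 10, speed = 1, sampling_interval = 60L) {
  tibble::tibble(
    individual_id = individual_id,
    timestamp = timestamp,
    lon = lon, lat = lat,
    altitude = rep_len(altitude, length(lon)),
    speed = rep_len(speed, length(lon)),
    sampling_interval = rep_len(as.integer(sampling_interval), length(lon))
  )
}

# Fixes at given distances (m) and bearings (deg) from a site, on a regular
# time grid.
fixes_at <- function(site, dist_m, bearing = 90, t0 = UTC("2013-05-01 08:00:00"),
                     dt = 60, ...) {
  p <- geosphere::destPoint(cbind(site$lon, site$lat),
                            rep_len(bearing, length(dist_m)), dist_m,
                            r = 6371000)
  make_fixes(p[, 1], p[, 2], t0 + seq_along(dist_m) * dt - dt,
             sampling_interval = dt, ...)
}

test_colony <- function() site("colony", lon = -6.0, lat = 37.3)

# Subsample a fix table to a coarser cadence (factor must divide evenly).
subsample_fixes <- function(fixes, factor) {
  out <- fixes[seq(1, nrow(fixes), by = factor), , drop = FALSE]
  out$sampling_interval <- as.integer(fixes$sampling_interval[1] * factor)
  out
}

# Hand-written Holm step-down, kept deliberately independent of
# stats::p.adjust: sort ascending, multiply by (m - i + 1), running max,
# cap at 1, restore order.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# The acceptance-scale cohort is expensive; build it once per test run and
# share it across test files.
.sim_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_cohort(n_individuals = 30,
                                      days_per_individual = 10,
                                      cadence = 60, seed = 42)
    .sim_cache$pipeline <- run_pipeline(.sim_cache$sim$fixes,
                                        .sim_cache$sim$sites,
                                        .sim_cache$sim$individuals,
                                        .sim_cache$sim$breeding)
  }
  list(sim = .sim_cache$sim, pipeline = .sim_cache$pipeline)
}
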