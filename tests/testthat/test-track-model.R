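test_that("geodesic distance matches the haversine oracle and its properties", {
  # identity
  expect_equal(geodesic_distance(-6, 37, -6, 37), 0)
  # one degree of latitude on a 6371 km sphere
  expect_equal(geodesic_distance(-6, 37, -6, 38), 111194.93, tolerance = 1e-4)
  # symmetry on random pairs
  set.seed(1)
  a <- cbind(runif(100, -10, 10), runif(100, 30, 45))
  b <- cbind(runif(100, -10, 10), runif(100, 30, 45))
  expect_equal(geodesic_distance(a[, 1], a[, 2], b[, 1], b[, 2]),
               geodesic_distance(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_true(all(geodesic_distance(a[, 1], a[, 2], b[, 1], b[, 2]) >= 0))
  expect_error(geodesic_distance(200, 37, -6, 38), "out of range")
  expect_error(geodesic_distance(-6, 97, -6, 38), "out of range")
})

test_that("subsampled path length never exceeds the original", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 120
    lon <- -6 + cumsum(rnorm(n, 0, 0.001))
    lat <- 37 + cumsum(rnorm(n, 0, 0.001))
    full <- path_length(lon, lat)
    for (f in c(2, 3, 5, 10)) {
      idx <- seq(1, n, by = f)
      expect_lte(path_length(lon[idx], lat[idx]), full + 1e-9)
    }
  }
})

test_that("solar times match an independent ephemeris within 2 minutes", {
  # frozen values from an independent Julian-transit sunrise-equation
  # implementation (apparent upper limb, standard refraction)
  oracle <- tibble::tribble(
    ~date, ~lat, ~lon, ~sunrise, ~sunset,
    "2013-06-21", 37.39, -5.98, "2013-06-21 05:04:35", "2013-06-21 19:49:07",
    "2013-04-10", 37.20, -6.05, "2013-04-10 05:57:33", "2013-04-10 18:55:16",
    "2013-03-01", 37.39, -5.98, "2013-03-01 06:56:25", "2013-03-01 18:18:45"
  )
  for (i in seq_len(nrow(oracle))) {
    st <- solar_times(as.Date(oracle$date[i]), oracle$lon[i], oracle$lat[i])
    expect_lt(abs(as.numeric(st$sunrise) - as.numeric(UTC(oracle$sunrise[i]))),
              120)
    expect_lt(abs(as.numeric(st$sunset) - as.numeric(UTC(oracle$sunset[i]))),
              120)
    expect_true(st$sunrise < st$sunset)
  }
})

test_that("solar geometry behaves: equinox symmetry, pre-solstice monotonicity, polar error", {
  eq <- solar_times(as.Date("2013-03-20"), 0, 0)
  expect_lt(abs(eq$day_length - 12 * 3600), 10 * 60)
  season <- seq(as.Date("2013-03-01"), as.Date("2013-06-21"), by = 1)
  dl <- solar_times(season, -5.98, 37.39)$day_length
  expect_true(all(diff(dl) > 0))
  expect_error(solar_times(as.Date("2013-06-21"), 0, 80), "polar")
})

test_that("read_fixes parses, validates and infers cadence", {
  dia <- movebank_dialect()
  hdr <- paste(unlist(dia), collapse = ",")
  f <- tempfile(fileext = ".csv")

  # well-formed 3-row file for one bird
  writeLines(c(hdr,
    "kes1,2013-05-01 08:00:00,-6.001,37.301,60,4.2",
    "kes1,2013-05-01 08:03:00,-6.002,37.302,58,3.0",
    "kes1,2013-05-01 08:06:00,-6.003,37.303,55,2.1"), f)
  fx <- read_fixes(f)
  expect_equal(nrow(fx), 3)
  expect_equal(unique(fx$individual_id), "kes1")
  # modal gap of 180 s lands on the legal 3-min cadence
  expect_equal(unique(fx$sampling_interval), 180L)
  expect_equal(attr(fx, "n_skipped"), 0L)

  # header-only file: empty collection, no warnings
  writeLines(hdr, f)
  expect_silent(fx0 <- read_fixes(f))
  expect_equal(nrow(fx0), 0)

  # missing mandatory column is a hard error
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_fixes(f), "mandatory column")

  # malformed rows are skipped with a warning; duplicates keep the first
  writeLines(c(hdr,
    "kes1,2013-05-01 08:00:00,-6.001,37.301,60,4.2",
    "kes1,not-a-time,-6.002,37.302,58,3.0",
    "kes1,2013-05-01 08:01:00,-600,37.302,58,3.0",
    "kes1,2013-05-01 08:01:00,-6.002,37.302,58,3.0",
    "kes1,2013-05-01 08:01:00,-6.009,37.309,58,3.0"), f)
  expect_warning(expect_warning(fx2 <- read_fixes(f), "skipped"), "duplicate")
  expect_equal(nrow(fx2), 2)
  expect_equal(attr(fx2, "n_skipped"), 2L)
  expect_equal(fx2$lon[2], -6.002)
})

test_that("write/read round trip preserves clean fixes", {
  sim <- simulate_day(paper_summary_preset()[1, ], "female", "courtship",
                      as.Date("2013-04-15"), default_sites()[1:2, ],
                      cadence = 300, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_fixes(sim$fixes, f)
  back <- read_fixes(f, sampling_interval = 300)
  expect_equal(back$timestamp, sim$fixes$timestamp)
  expect_equal(back$lon, sim$fixes$lon)
  expect_equal(back$lat, sim$fixes$lat)
  expect_equal(back$speed, sim$fixes$speed)
  expect_equal(back$altitude, sim$fixes$altitude)
})

test_that("sites and dialect configuration load from files", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,lon,lat,radius_m", "colony,-6.0,37.3,50",
               "roost,-5.99,37.3,"), f)
  s <- read_sites(f)
  expect_equal(s$radius_m, c(50, 50))

  y <- tempfile(fileext = ".yml")
  writeLines(c("columns:", "  individual_id: id", "  timestamp: time",
               "  lon: x", "  lat: y", "  altitude: alt",
               "  speed: spd"), y)
  d <- read_dialect(y)
  expect_equal(d$lon, "x")
  writeLines(c("columns:", "  individual_id: id"), y)
  expect_error(read_dialect(y), "missing roles")
})
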