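colony <- test_colony()

test_that("attendance mask uses an inclusive 50 m buffer", {
  fx <- fixes_at(colony, c(10, 50, 50.9, 300, 0))
  m <- attendance_mask(fx, colony)
  expect_equal(m, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("foraging events need clumping and variable speed", {
  # straight transit at constant speed: no clump, no CV
  transit <- fixes_at(colony, seq(500, 5000, by = 600), speed = 10)
  expect_equal(nrow(detect_foraging_events(transit)), 0)

  # hand-built hover cluster: 8 fixes within 40 m, speeds 0-8 m/s
  sp <- c(0, 6, 1, 7, 0, 5, 2, 8)
  cl <- fixes_at(colony, 2000 + c(0, 12, -8, 15, 3, -14, 9, -5),
                 bearing = 90, speed = sp)
  ev <- detect_foraging_events(cl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_fixes, 8L)
  # hand CV oracle: sd/mean of the speed vector
  expect_equal(ev$speed_cv, sd(sp) / mean(sp), tolerance = 1e-10)

  # two clusters separated by a 2 km transit give two events
  two <- dplyr::bind_rows(
    fixes_at(colony, 2000 + c(0, 12, -8, 15), speed = c(0, 6, 1, 7)),
    fixes_at(colony, c(2600, 3200, 3800),
             t0 = UTC("2013-05-01 08:04:00"), speed = 10),
    fixes_at(colony, 4000 + c(0, -11, 14, 6),
             t0 = UTC("2013-05-01 08:07:00"), speed = c(0, 7, 1, 6))
  )
  two$timestamp <- UTC("2013-05-01 08:00:00") + 60 * (seq_len(nrow(two)) - 1)
  expect_equal(nrow(detect_foraging_events(two)), 2)
})

# A hand-built tracking day: colony bouts around excursions; speeds chosen
# so the far clumps qualify as foraging events.
toy_day <- function(max_dist = 2000) {
  sp <- c(0, 6, 1, 7, 0, 5)
  parts <- list(
    fixes_at(colony, rep(10, 3), speed = 0.5),
    fixes_at(colony, c(600, 1300), speed = 10),
    fixes_at(colony, max_dist + c(0, 12, -8, 15, 3, -14), speed = sp),
    fixes_at(colony, c(1300, 600), speed = 10),
    fixes_at(colony, rep(12, 3), speed = 0.5),
    fixes_at(colony, c(700, 1400), speed = 10),
    fixes_at(colony, max_dist + c(5, -10, 13, -2, 9, -12), bearing = 270,
             speed = sp),
    fixes_at(colony, c(1400, 700), speed = 10),
    fixes_at(colony, rep(9, 3), speed = 0.5)
  )
  fx <- dplyr::bind_rows(parts)
  fx$timestamp <- UTC("2013-05-01 07:00:00") + 60 * (seq_len(nrow(fx)) - 1)
  fx
}

test_that("trips require leaving 300 m and containing a foraging event", {
  # a clumped stop at only 250 m never qualifies
  near <- dplyr::bind_rows(
    fixes_at(colony, rep(10, 3), speed = 0.5),
    fixes_at(colony, 250 + c(0, 12, -8, 15, 3, -14), speed = c(0, 6, 1, 7, 0, 5)),
    fixes_at(colony, rep(10, 3), speed = 0.5)
  )
  near$timestamp <- UTC("2013-05-01 07:00:00") + 60 * (seq_len(nrow(near)) - 1)
  seg <- segment_trips(near, colony)
  expect_equal(nrow(seg), 1)
  expect_false(seg$is_trip)
  expect_true(seg$complete)

  # two 2 km excursions with clumps: two complete trips
  seg2 <- segment_trips(toy_day(), colony)
  expect_equal(sum(seg2$is_trip & seg2$complete), 2)
  expect_true(all(seg2$max_dist_colony_m > 300))

  # a track wholly inside the buffer yields nothing
  inside <- fixes_at(colony, rep(20, 10), speed = 0.3)
  expect_equal(nrow(segment_trips(inside, colony)), 0)

  # truncated track: the opening excursion is incomplete
  cut <- toy_day()[-(1:4), ]
  segc <- segment_trips(cut, colony)
  expect_false(segc$complete[1])
})

test_that("trip endpoints anchor at the buffer and trips are disjoint", {
  seg <- segment_trips(toy_day(), colony)
  trips <- seg[seg$is_trip, ]
  expect_true(all(trips$departure < trips$arrival))
  # ordered and non-overlapping
  expect_true(all(head(trips$arrival, -1) <= tail(trips$departure, -1)))
})

test_that("complete days need sunrise-to-sunset coverage without gaps", {
  june <- solar_times(as.Date("2013-06-20"), colony$lon, colony$lat)
  t_full <- seq(UTC("2013-06-20 04:50:00"), UTC("2013-06-20 20:00:00"), by = 60)
  fx <- make_fixes(rep(colony$lon, length(t_full)),
                   rep(colony$lat, length(t_full)), t_full)
  cd <- complete_days(fx, colony)
  expect_true(cd$complete)
  expect_equal(cd$day_length, june$day_length)

  # first fix two hours after sunrise
  late <- fx[fx$timestamp >= june$sunrise + 7200, ]
  expect_false(complete_days(late, colony)$complete)

  # one-hour internal gap at 1-min cadence
  gap <- fx[fx$timestamp < UTC("2013-06-20 10:00:00") |
              fx$timestamp > UTC("2013-06-20 11:00:00"), ]
  expect_false(complete_days(gap, colony)$complete)
})

test_that("coarser cadences never detect more trips on the same path", {
  sim <- simulate_day(paper_summary_preset()[1, ], "male", "incubation",
                      as.Date("2013-05-10"), default_sites()[1:2, ],
                      cadence = 60, seed = 99)
  sites <- default_sites()[1:2, ]
  n60 <- sum(segment_trips(sim$fixes, sites)$is_trip)
  prev <- n60
  for (f in c(3, 5, 10)) {
    fx <- subsample_fixes(sim$fixes, f)
    n <- sum(segment_trips(fx, sites)$is_trip)
    expect_lte(n, n60)
  }
})
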