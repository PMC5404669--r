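sites <- default_sites()[1:2, ]
preset <- paper_summary_preset()

test_that("moment-matched draws hit their targets", {
  set.seed(1)
  x <- rlnorm_mm(1e5, 1.16, 1.28)
  expect_equal(mean(x), 1.16, tolerance = 0.02)
  expect_equal(sd(x), 1.28, tolerance = 0.05)
  b <- cpforage:::rbeta_mm(1e5, 0.1941, 0.1294)
  expect_equal(mean(b), 0.1941, tolerance = 0.02)
  expect_equal(sd(b), 0.1294, tolerance = 0.05)
})

test_that("a fixed seed reproduces a day bit for bit", {
  a <- simulate_day(preset[1, ], "female", "courtship",
                    as.Date("2013-04-10"), sites, seed = 5)
  b <- simulate_day(preset[1, ], "female", "courtship",
                    as.Date("2013-04-10"), sites, seed = 5)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth, b$truth)
  c <- simulate_day(preset[1, ], "female", "courtship",
                    as.Date("2013-04-10"), sites, seed = 6)
  expect_false(identical(a$fixes, c$fixes))
})

test_that("generated fixes satisfy the track-model invariants", {
  for (dt in c(60, 300)) {
    d <- simulate_day(preset[1, ], "male", "nestling", as.Date("2013-06-10"),
                      sites, cadence = dt, seed = 9)
    fx <- d$fixes
    expect_true(all(diff(as.numeric(fx$timestamp)) == dt))
    expect_true(all(fx$speed >= 0))
    expect_true(all(abs(fx$lat) <= 90 & abs(fx$lon) <= 180))
    expect_equal(unique(fx$sampling_interval), as.integer(dt))
    # the day covers sunrise to sunset at the colony
    cd <- complete_days(fx, sites[1, ])
    expect_true(cd$complete)
  }
})

test_that("zero perch probability yields zero detected bouts", {
  p0 <- preset[1, ]
  p0$perch_prob <- 0
  d <- simulate_day(p0, "female", "incubation", as.Date("2013-05-02"),
                    sites, seed = 31)
  seg <- segment_trips(d$fixes, sites)
  trips <- dplyr::filter(seg, is_trip, complete)
  expect_equal(nrow(detect_perch_bouts(trips, d$fixes)), 0)
  expect_equal(nrow(d$truth$perch_bouts), 0)
})

test_that("segmentation recovers the planted trip count day by day", {
  # ground-truth recovery across a spread of dates and both sexes
  ok <- 0L; n <- 0L
  for (s in 1:20) {
    date <- as.Date("2013-03-20") + s * 4
    per <- c("establishment", "courtship", "incubation",
             "nestling")[1 + (s %% 4)]
    d <- simulate_day(preset[1, ], c("female", "male")[1 + s %% 2], per,
                      date, sites, seed = 400 + s)
    seg <- segment_trips(d$fixes, sites)
    n <- n + 1L
    ok <- ok + (sum(seg$is_trip & seg$complete) == d$truth$day$K)
  }
  expect_gte(ok / n, 0.99)
})

test_that("body-mass generator is exact in the noise-free case", {
  pars <- body_mass_params(individual_sd_g = 0, residual_sd_g = 0,
                           curve = function(doy) 0)
  d <- simulate_body_mass(pars, n_individuals = 10, seed = 3)
  means <- tapply(d$mass, d$sex, mean)
  expect_equal(unname(means["male"] - means["female"]), -18.28)

  # doubling the residual noise inflates the SE of the recovered offset
  set.seed(4)
  d1 <- simulate_body_mass(body_mass_params(residual_sd_g = 4), seed = 8)
  d2 <- simulate_body_mass(body_mass_params(residual_sd_g = 16), seed = 8)
  f1 <- fit_smooth(d1, "mass", fixed = "sex", random = "individual_id")
  f2 <- fit_smooth(d2, "mass", fixed = "sex", random = "individual_id")
  se <- function(f) f$coefficients$std_error[f$coefficients$term == "sexmale"]
  expect_gt(se(f2), se(f1))
})

test_that("habitat composition preset and counts behave", {
  p <- habitat_use_preset()
  expect_equal(sum(p), 1)
  expect_equal(length(p), 9)

  counts <- simulate_habitat_counts(n_per_sex = 161, seed = 1)
  expect_equal(rowSums(counts), c(female = 161, male = 161))

  # disjoint supports: overwhelming rejection
  pf <- c(rep(1 / 4, 4), rep(0, 5))
  pm <- c(rep(0, 5), rep(1 / 4, 4))
  cts <- simulate_habitat_counts(pf, pm, n_per_sex = 161, seed = 2)
  keep <- colSums(cts) > 0
  expect_lt(suppressWarnings(chisq_homogeneity(cts[, keep]))$p_value, 0.001)

  # null calibration: rejection rate near the nominal 5%
  set.seed(6)
  rej <- mean(replicate(1000, {
    ct <- simulate_habitat_counts(n_per_sex = 161,
                                  seed = sample.int(1e8, 1))
    suppressWarnings(chisq_homogeneity(ct))$p_value < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.08)
})

test_that("cohort simulation is reproducible and internally consistent", {
  sim <- simulate_cohort(n_individuals = 4, days_per_individual = 4,
                         seed = 77,
                         period_mix = c(establishment = 1, courtship = 1,
                                        incubation = 1, nestling = 1))
  expect_equal(nrow(sim$truth$days), 16)
  expect_equal(sort(unique(sim$fixes$individual_id)),
               sim$individuals$individual_id)
  # every planted trip lies inside its day's daylight window
  st <- solar_times(sim$truth$trips$date, sim$sites$lon[1], sim$sites$lat[1])
  expect_true(all(sim$truth$trips$start >= st$sunrise - 120))
  sim2 <- simulate_cohort(n_individuals = 4, days_per_individual = 4,
                          seed = 77,
                          period_mix = c(establishment = 1, courtship = 1,
                                         incubation = 1, nestling = 1))
  expect_identical(sim$fixes, sim2$fixes)
})
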