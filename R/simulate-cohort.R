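#' Default study layout: two colonies with a roost each
#'
#' Colony coordinates in the Guadalquivir valley (SW Spain) at the study
#' latitude; each colony has one roost anchor 1 km away. All anchors use
#' the standard 50 m attendance buffer.
#'
#' @return Site tibble with a `colony_group` column linking roosts to
#'   their colony.
#' @export
default_sites <- function() {
  c1 <- site("colonyA", lon = -6.05, lat = 37.20)
  r1 <- site("roostA", lon = dest_point(-6.05, 37.20, 110, 1000)[1, "lon"],
             lat = dest_point(-6.05, 37.20, 110, 1000)[1, "lat"])
  c2 <- site("colonyB", lon = -5.88, lat = 37.32)
  r2 <- site("roostB", lon = dest_point(-5.88, 37.32, 250, 1000)[1, "lon"],
             lat = dest_point(-5.88, 37.32, 250, 1000)[1, "lat"])
  dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(c1, r1), colony_group = "colonyA"),
    dplyr::mutate(dplyr::bind_rows(c2, r2), colony_group = "colonyB")
  )
}

# Deterministic per-individual-day RNG stream seed, derived from the
# master seed, the individual index and the date so any day can be
# regenerated independently. Kept below 2^31.
day_seed <- function(master_seed, ind_index, date) {
  (as.numeric(master_seed) * 48271 + ind_index * 99991 +
     as.numeric(as.Date(date))) %% 2147483399 + 1
}

#' Simulate a tracked breeding cohort
#'
#' Generates breeding records, per-day GPS tracks and full ground truth
#' for a cohort of breeding lesser kestrels split evenly between sexes and
#' between two colonies. Each individual contributes `days_per_individual`
#' complete tracking days spread over the four phenological periods
#' (default 2 establishment / 3 courtship / 2 incubation / 3 nestling,
#' mirroring the typical field distribution of complete days).
#'
#' @param n_individuals Number of individuals (split female/male).
#' @param days_per_individual Tracking days per individual.
#' @param cadence GPS sampling interval in seconds.
#' @param seed Master seed; every individual-day derives its own stream.
#' @param params Strategy parameter grid ([strategy_params()] /
#'   [paper_summary_preset()]).
#' @param sites Site table from [default_sites()] (or same structure).
#' @param period_mix Named integer vector: days per period, summing to
#'   `days_per_individual`.
#' @param years Years the deployments are spread over.
#' @return List: `fixes`, `individuals` (id, sex, colony, year),
#'   `breeding` (records), `sites`, and `truth` (`days`, `trips`,
#'   `perch_bouts`).
#' @export
simulate_cohort <- function(n_individuals = 30, days_per_individual = 10,
                            cadence = 60, seed = 42,
                            params = paper_summary_preset(),
                            sites = default_sites(),
                            period_mix = c(establishment = 2, courtship = 3,
                                           incubation = 2, nestling = 3),
                            years = 2012:2015) {
  stopifnot(sum(period_mix) == days_per_individual,
            all(names(period_mix) == period_levels()))
  force(seed)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  groups <- unique(sites$colony_group)
  ids <- sprintf("bird%02d", seq_len(n_individuals))
  individuals <- tibble::tibble(
    individual_id = ids,
    sex = rep(c("female", "male"), length.out = n_individuals),
    colony = rep(groups, length.out = n_individuals),
    year = factor(rep(years, length.out = n_individuals))
  )

  # breeding phenology: laying centred on 20 April, incubation ~29 d,
  # nestling ~36 d, pre-laying presence ~5 weeks
  laying <- as.Date("2013-04-20") + round(rnorm(n_individuals, 0, 6))
  arrival <- laying - COURTSHIP_DAYS - round(runif(n_individuals, 12, 25))
  hatching <- laying + round(runif(n_individuals, 28, 30))
  fledging <- hatching + round(runif(n_individuals, 34, 38))
  breeding <- breeding_record(ids, arrival, laying, hatching, fledging,
                              brood_size = 1 + rbinom(n_individuals, 4, 0.6))

  sample_days <- function(i) {
    rec <- breeding[i, ]
    windows <- list(
      establishment = seq(rec$arrival, rec$laying - COURTSHIP_DAYS - 1, by = 1),
      courtship = seq(rec$laying - COURTSHIP_DAYS, rec$laying - 1, by = 1),
      incubation = seq(rec$laying, rec$hatching - 1, by = 1),
      nestling = seq(rec$hatching, rec$fledging - 1, by = 1)
    )
    dplyr::bind_rows(lapply(period_levels(), function(p) {
      w <- windows[[p]]
      tibble::tibble(period = p,
                     date = sort(sample(w, min(period_mix[[p]], length(w)))))
    }))
  }
  schedule <- dplyr::bind_rows(lapply(seq_len(n_individuals), function(i) {
    dplyr::mutate(sample_days(i), individual_id = ids[i])
  }))

  fixes <- vector("list", nrow(schedule))
  t_days <- vector("list", nrow(schedule))
  t_trips <- vector("list", nrow(schedule))
  t_perch <- vector("list", nrow(schedule))
  for (r in seq_len(nrow(schedule))) {
    id <- schedule$individual_id[r]
    i <- match(id, ids)
    grp <- individuals$colony[i]
    day_sites <- sites[sites$colony_group == grp, ]
    p_row <- params[params$sex == individuals$sex[i] &
                      params$period == schedule$period[r], ]
    sim <- simulate_day(p_row, individuals$sex[i], schedule$period[r],
                        schedule$date[r], day_sites, cadence = cadence,
                        seed = day_seed(seed, i, schedule$date[r]),
                        individual_id = id)
    fixes[[r]] <- sim$fixes
    t_days[[r]] <- sim$truth$day
    t_trips[[r]] <- sim$truth$trips
    t_perch[[r]] <- sim$truth$perch_bouts
  }
  list(
    fixes = dplyr::bind_rows(fixes),
    individuals = individuals,
    breeding = breeding,
    sites = sites,
    truth = list(days = dplyr::bind_rows(t_days),
                 trips = dplyr::bind_rows(t_trips),
                 perch_bouts = dplyr::bind_rows(t_perch))
  )
}

#' Body-mass generation parameters
#'
#' @param baseline_g Female baseline mass (g).
#' @param sex_offset_g Additive male minus female offset (g).
#' @param individual_sd_g SD of individual random intercepts (g).
#' @param residual_sd_g Residual SD (g).
#' @param curve Smooth seasonal trend, a function of day-of-year returning
#'   grams around baseline: roughly steady through courtship/incubation
#'   and declining through the nestling period.
#' @return Parameter list.
#' @export
body_mass_params <- function(baseline_g = 147, sex_offset_g = -18.28,
                             individual_sd_g = 5, residual_sd_g = 6,
                             curve = NULL) {
  if (is.null(curve)) {
    curve <- function(doy) {
      6 * exp(-((doy - 125) / 35)^2) - 14 * plogis((doy - 160) / 12)
    }
  }
  list(baseline_g = baseline_g, sex_offset_g = sex_offset_g,
       individual_sd_g = individual_sd_g, residual_sd_g = residual_sd_g,
       curve = curve)
}

#' Simulate body-mass measurements across the season
#'
#' `mass = baseline + offset x male + curve(doy) + individual intercept +
#' noise`: the structure the smooth-plus-sex additive model assumes, with
#' the planted sex offset recoverable by [fit_smooth()].
#'
#' @param params [body_mass_params()].
#' @param n_individuals Number of adults (alternating female/male).
#' @param n_per_individual Measurements per individual.
#' @param doy_range Day-of-year span of the season.
#' @param seed RNG seed.
#' @return Tibble: `individual_id`, `sex`, `doy`, `mass`.
#' @export
simulate_body_mass <- function(params = body_mass_params(),
                               n_individuals = 30, n_per_individual = 9,
                               doy_range = c(65, 200), seed = 1) {
  force(seed)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("ad%02d", seq_len(n_individuals))
  sexes <- rep(c("female", "male"), length.out = n_individuals)
  b <- rnorm(n_individuals, 0, params$individual_sd_g)
  dplyr::bind_rows(lapply(seq_len(n_individuals), function(i) {
    doy <- sort(round(runif(n_per_individual, doy_range[1], doy_range[2])))
    tibble::tibble(
      individual_id = ids[i], sex = sexes[i], doy = doy,
      mass = params$baseline_g +
        params$sex_offset_g * (sexes[i] == "male") +
        params$curve(doy) + b[i] +
        rnorm(n_per_individual, 0, params$residual_sd_g)
    )
  }))
}

#' Foraging-habitat composition preset
#'
#' The pooled nine-class habitat-use composition at foraging locations
#' (stubble, cereal, seedlings, pastures, ploughed, sunflower, others,
#' vineyards, tree groves), renormalised to sum to one.
#'
#' @return Named probability vector of length 9.
#' @export
habitat_use_preset <- function() {
  p <- c(stubble = 25.05, cereal = 18.26, seedlings = 12.42,
         pastures = 11.18, ploughed = 9.01, sunflower = 7.76,
         others = 7.14, vineyards = 5.90, tree_groves = 3.10)
  p / sum(p)
}

#' Simulate sex-specific habitat-use counts
#'
#' Multinomial draws of foraging-location habitat classes per sex, feeding
#' [chisq_homogeneity()].
#'
#' @param p_female,p_male Class probability vectors (must each sum to 1).
#' @param n_per_sex Foraging locations sampled per sex.
#' @param seed RNG seed.
#' @return 2 x k count matrix with rows `female`, `male`.
#' @export
simulate_habitat_counts <- function(p_female = habitat_use_preset(),
                                    p_male = habitat_use_preset(),
                                    n_per_sex = 161, seed = 1) {
  stopifnot(abs(sum(p_female) - 1) < 1e-8, abs(sum(p_male) - 1) < 1e-8,
            length(p_female) == length(p_male))
  force(seed)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  counts <- rbind(
    female = as.vector(rmultinom(1, n_per_sex, p_female)),
    male = as.vector(rmultinom(1, n_per_sex, p_male))
  )
  colnames(counts) <- names(p_female)
  counts
}
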