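#' Run the full segmentation, metrics and perch-hunting pipeline
#'
#' Chains the analysis stages over a fix set: per colony group, trip
#' segmentation against the colony + roost anchors, complete-day
#' identification, trip and daily metrics, perch-bout detection and
#' per-trip perch summaries, and sex/period annotation.
#'
#' @param fixes Fixes tibble (e.g. from [read_fixes()] or
#'   [simulate_cohort()]).
#' @param sites Site table with a `colony_group` column (colony first
#'   within each group).
#' @param individuals Tibble `individual_id`, `sex`, `colony` (group
#'   name), optional `year`.
#' @param breeding Breeding records for period assignment.
#' @param event_params Overrides for [detect_foraging_events()].
#' @return List of tibbles: `trips` (complete foraging trips with metrics
#'   and perch summary), `excursions` (all segmented excursions), `days`
#'   (complete days with metrics), `bouts` (perch bouts).
#' @export
run_pipeline <- function(fixes, sites, individuals, breeding,
                         event_params = list()) {
  groups <- unique(sites$colony_group)
  all_exc <- all_days <- all_trips <- all_bouts <- list()
  for (g in groups) {
    g_sites <- sites[sites$colony_group == g, ]
    colony <- g_sites[1, ]
    g_ids <- individuals$individual_id[individuals$colony == g]
    idx_global <- which(fixes$individual_id %in% g_ids)
    fx <- fixes[idx_global, , drop = FALSE]
    if (nrow(fx) == 0) next
    exc <- segment_trips(fx, g_sites, event_params = event_params)
    days <- complete_days(fx, colony)
    trips <- dplyr::filter(exc, .data$is_trip, .data$complete)
    trips <- trip_metrics(trips, fx, colony)
    bouts <- detect_perch_bouts(trips, fx)
    trips <- summarize_perching(trips, bouts)
    days_c <- dplyr::filter(days, .data$complete)
    days_c <- daily_metrics(days_c, fx, exc, colony)
    # re-express fix indices against the full input fix table so the trip
    # rows stay valid outside this call
    for (col in c("dep_idx", "arr_idx", "first_out", "last_out")) {
      exc[[col]] <- idx_global[exc[[col]]]
      trips[[col]] <- idx_global[trips[[col]]]
    }
    all_exc[[g]] <- exc
    all_days[[g]] <- days_c
    all_trips[[g]] <- trips
    all_bouts[[g]] <- bouts
  }
  trips <- annotate_periods(dplyr::bind_rows(all_trips), individuals,
                            breeding)
  days <- annotate_periods(dplyr::bind_rows(all_days), individuals,
                           breeding)
  list(trips = trips,
       excursions = dplyr::bind_rows(all_exc),
       days = days,
       bouts = dplyr::bind_rows(all_bouts))
}

#' Pooled movement summaries
#'
#' Pooled means (and SDs) of the six movement variables plus the
#' perch-hunting summary, in the units the daily/trip analyses use:
#' hours, km, trips/day, percent of daylight, minutes.
#'
#' @param pipeline Output of [run_pipeline()].
#' @return One-row tibble of pooled statistics.
#' @export
pooled_summary <- function(pipeline) {
  tr <- pipeline$trips
  dy <- pipeline$days
  perching <- tr[tr$has_perching == 1, , drop = FALSE]
  tibble::tibble(
    n_trips = nrow(tr),
    n_days = nrow(dy),
    trip_duration_h = mean(tr$duration_h),
    trip_duration_sd = sd(tr$duration_h),
    trip_distance_km = mean(tr$distance_km),
    trip_distance_sd = sd(tr$distance_km),
    trip_max_distance_km = mean(tr$max_distance_km),
    trip_max_distance_sd = sd(tr$max_distance_km),
    daily_distance_km = mean(dy$daily_distance_km),
    daily_distance_sd = sd(dy$daily_distance_km),
    trips_per_day = mean(dy$n_trips),
    trips_per_day_sd = sd(dy$n_trips),
    attendance_pct = mean(dy$colony_attendance_pct),
    attendance_sd = sd(dy$colony_attendance_pct),
    perch_trip_frac = mean(tr$has_perching),
    perch_time_min = if (nrow(perching)) mean(perching$total_perch_min)
                     else NA_real_,
    perch_time_sd = if (nrow(perching) > 1) sd(perching$total_perch_min)
                    else NA_real_
  )
}

#' Match detected perch bouts against planted ground truth
#'
#' A detected bout matches a planted bout of the same individual when
#' their time windows overlap. Used for generator-validation
#' recall/precision.
#'
#' @param detected Bouts from [detect_perch_bouts()].
#' @param truth Planted bouts (`truth$perch_bouts` from the simulator).
#' @return List: `recall`, `precision`, counts.
#' @export
match_perch_bouts <- function(detected, truth) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_truth = 0L, n_detected = nrow(detected)))
  }
  overlaps <- function(a0, a1, b0, b1) a0 <= b1 & b0 <= a1
  hit_truth <- logical(nrow(truth))
  hit_det <- logical(nrow(detected))
  for (i in seq_len(nrow(detected))) {
    j <- which(truth$individual_id == detected$individual_id[i] &
                 overlaps(as.numeric(detected$start[i]),
                          as.numeric(detected$end[i]),
                          as.numeric(truth$start),
                          as.numeric(truth$end)))
    if (length(j)) {
      hit_truth[j] <- TRUE
      hit_det[i] <- TRUE
    }
  }
  list(recall = mean(hit_truth), precision = mean(hit_det),
       n_truth = nrow(truth), n_detected = nrow(detected))
}
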