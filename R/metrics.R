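#' Trip-level movement metrics
#'
#' For every complete foraging trip: (1) duration, the time between leaving
#' and returning to the anchor (h); (2) distance, the accumulated
#' great-circle distance between consecutive fixes along the trip (km); and
#' (3) the maximum distance from the breeding colony reached along the trip
#' (km). Incomplete trips are refused — their metrics would be biased and
#' the statistics layer must never see them.
#'
#' @param trips Trip rows from [segment_trips()] (complete foraging trips).
#' @param fixes The fixes tibble the trips were segmented from.
#' @param colony One-row site table for the colony.
#' @return `trips` with `duration_h`, `distance_km`, `max_distance_km`
#'   appended.
#' @export
trip_metrics <- function(trips, fixes, colony) {
  stopifnot(nrow(colony) == 1)
  if (any(!trips$complete)) {
    stop("trip_metrics requires complete trips; filter on `complete` first",
         call. = FALSE)
  }
  if (nrow(trips) == 0) {
    return(dplyr::mutate(trips, duration_h = numeric(0),
                         distance_km = numeric(0),
                         max_distance_km = numeric(0)))
  }
  d_colony <- geodesic_distance(fixes$lon, fixes$lat, colony$lon, colony$lat)
  slice_stats <- function(a, b) {
    idx <- a:b
    c(path_length(fixes$lon[idx], fixes$lat[idx]), max(d_colony[idx]))
  }
  m <- mapply(slice_stats, trips$dep_idx, trips$arr_idx)
  dplyr::mutate(trips,
    duration_h = as.numeric(.data$arrival - .data$departure,
                            units = "hours"),
    distance_km = m[1, ] / 1000,
    max_distance_km = m[2, ] / 1000
  )
}

#' Daily movement metrics
#'
#' For every complete tracking day: (1) daily distance, the accumulated
#' distance between consecutive fixes from sunrise to sunset (km); (2) the
#' number of complete foraging trips departing that day; and (3) daily
#' colony attendance, the percentage of daylight spent within the colony's
#' 50 m buffer. Attendance is interval-weighted: an inter-fix interval
#' counts fully when both endpoints are inside the buffer and half when
#' exactly one is, which is unbiased for symmetric buffer crossings.
#'
#' @param days Complete day rows from [complete_days()].
#' @param fixes Fixes tibble.
#' @param trips Segmentation output ([segment_trips()]).
#' @param colony One-row site table for the breeding colony (attendance is
#'   colony-only; roosts never count).
#' @return `days` with `daily_distance_km`, `n_trips`,
#'   `colony_attendance_pct` appended.
#' @export
daily_metrics <- function(days, fixes, trips, colony) {
  stopifnot(nrow(colony) == 1)
  if (any(!days$complete)) {
    stop("daily_metrics requires complete days; filter on `complete` first",
         call. = FALSE)
  }
  complete_trips <- dplyr::filter(trips, .data$is_trip, .data$complete)
  trip_counts <- dplyr::count(complete_trips, .data$individual_id,
                              .data$date, name = "n_trips")
  fx <- dplyr::mutate(fixes, date = as.Date(.data$timestamp, tz = "UTC"))
  at_colony <- geodesic_distance(fx$lon, fx$lat, colony$lon, colony$lat) <=
    colony$radius_m

  one_day <- function(day) {
    idx <- which(fx$individual_id == day$individual_id &
                 fx$date == day$date &
                 fx$timestamp >= day$sunrise & fx$timestamp <= day$sunset)
    dist_km <- path_length(fx$lon[idx], fx$lat[idx]) / 1000
    if (length(idx) > 1) {
      dt <- as.numeric(diff(fx$timestamp[idx]), units = "secs")
      inside <- at_colony[idx]
      credit <- (inside[-length(inside)] + inside[-1]) / 2
      att <- sum(dt * credit) / day$day_length * 100
    } else {
      att <- 0
    }
    c(dist_km, att)
  }
  m <- vapply(seq_len(nrow(days)), function(i) one_day(days[i, ]),
              numeric(2))
  days |>
    dplyr::mutate(daily_distance_km = m[1, ],
                  colony_attendance_pct = pmin(m[2, ], 100)) |>
    dplyr::left_join(trip_counts, by = c("individual_id", "date")) |>
    dplyr::mutate(n_trips = dplyr::coalesce(.data$n_trips, 0L))
}

#' Annotate trips or days with sex and phenological period
#'
#' @param x Trips or days tibble (needs `individual_id` and a date or
#'   departure column).
#' @param individuals Tibble `individual_id`, `sex` (and optionally
#'   `colony`, `year`).
#' @param breeding Breeding-record tibble; matched on
#'   `pair_id == individual_id`. A trip spanning a period boundary takes
#'   the period of its departure. Rows outside the breeding window get
#'   period `NA`.
#' @return `x` with `sex` and `period` columns.
#' @export
annotate_periods <- function(x, individuals, breeding) {
  x <- dplyr::left_join(x, individuals, by = "individual_id")
  per <- rep(NA_character_, nrow(x))
  for (i in seq_len(nrow(x))) {
    rec <- breeding[breeding$pair_id == x$individual_id[i], , drop = FALSE]
    if (nrow(rec) == 1) {
      d <- x$date[i]
      if (d >= rec$arrival && d <= rec$fledging) {
        per[i] <- as.character(assign_period(d, rec))
      }
    }
  }
  x$period <- factor(per, levels = period_levels())
  x
}
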