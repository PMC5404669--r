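#' Cadence-specific perching displacement threshold
#'
#' A perching bout is a sequence of GPS locations whose consecutive
#' displacements stay below a threshold that grows with the sampling
#' interval, because GPS spatial accuracy degrades as the fix rate drops:
#' 1 m at 1 s, 5 m at 1 min, 15 m at 3 min, 25 m at 5 min and 50 m at
#' 10 min.
#'
#' @param sampling_interval Cadence in seconds (1, 60, 180, 300 or 600).
#' @return Threshold in meters.
#' @export
perch_threshold <- function(sampling_interval) {
  map <- c(`1` = 1, `60` = 5, `180` = 15, `300` = 25, `600` = 50)
  key <- as.character(sampling_interval)
  if (any(!key %in% names(map))) {
    stop("no perching threshold defined for sampling interval ",
         paste(unique(sampling_interval[!key %in% names(map)]),
               collapse = ", "), " s", call. = FALSE)
  }
  unname(map[key])
}

#' Detect perching bouts within foraging trips
#'
#' Scans the exterior fixes of each trip (anchor-buffer fixes are colony
#' attendance, not hunting) for maximal runs of consecutive steps strictly
#' below the cadence-specific threshold. Bout duration is the time span
#' between the first and last fix of the run; bouts shorter than
#' `min_duration` (30 s) are discarded because such short stationary spells
#' cannot be told apart from hovering flight. At cadences of 1 min or more
#' any detected bout spans at least one full interval and therefore always
#' survives the 30 s filter; it only bites on 1 s data.
#'
#' @param trips Trip rows from [segment_trips()] (normally
#'   `is_trip & complete`).
#' @param fixes The fixes tibble the trips were segmented from.
#' @param min_duration Minimum bout duration in seconds (default 30).
#' @return Tibble of bouts: `trip_id`, `individual_id`, `start`, `end`,
#'   `duration_s`, `n_fixes`, `max_step_m`.
#' @export
detect_perch_bouts <- function(trips, fixes, min_duration = 30) {
  empty <- tibble::tibble(
    trip_id = character(), individual_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    duration_s = numeric(), n_fixes = integer(), max_step_m = numeric()
  )
  if (nrow(trips) == 0) return(empty)
  out <- vector("list", nrow(trips))
  for (k in seq_len(nrow(trips))) {
    tr <- trips[k, ]
    idx <- tr$first_out:tr$last_out
    if (length(idx) < 2) next
    thr <- perch_threshold(tr$sampling_interval)
    steps <- step_lengths(fixes$lon[idx], fixes$lat[idx])
    r <- rle(steps < thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (!length(sel)) next
    bouts <- lapply(sel, function(j) {
      a <- starts[j]          # first step of the run
      b <- ends[j] + 1L       # last fix of the run
      t0 <- fixes$timestamp[idx[a]]
      t1 <- fixes$timestamp[idx[b]]
      tibble::tibble(
        trip_id = tr$trip_id, individual_id = tr$individual_id,
        start = t0, end = t1,
        duration_s = as.numeric(t1 - t0, units = "secs"),
        n_fixes = b - a + 1L,
        max_step_m = max(steps[starts[j]:ends[j]])
      )
    })
    bouts <- dplyr::bind_rows(bouts)
    out[[k]] <- bouts[bouts$duration_s >= min_duration, , drop = FALSE]
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Per-trip perch-hunting summary
#'
#' @param trips Trip rows the bouts were detected on.
#' @param bouts Output of [detect_perch_bouts()].
#' @return `trips` with `n_bouts`, `total_perch_min` (sum of bout
#'   durations) and the binary `has_perching` flag (1 when at least one
#'   bout) appended.
#' @export
summarize_perching <- function(trips, bouts) {
  per_trip <- bouts |>
    dplyr::group_by(.data$trip_id) |>
    dplyr::summarise(n_bouts = dplyr::n(),
                     total_perch_min = sum(.data$duration_s) / 60,
                     .groups = "drop")
  trips |>
    dplyr::left_join(per_trip, by = "trip_id") |>
    dplyr::mutate(
      n_bouts = dplyr::coalesce(.data$n_bouts, 0L),
      total_perch_min = dplyr::coalesce(.data$total_perch_min, 0),
      has_perching = as.integer(.data$n_bouts >= 1)
    )
}
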