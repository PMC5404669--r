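#' Colony/anchor attendance mask
#'
#' A fix counts as "at" an anchor site when its great-circle distance to the
#' site is less than or equal to the site's attendance radius (50 m buffer
#' by default; the boundary itself is inside).
#'
#' @param fixes Fixes tibble.
#' @param sites Site table ([site()] / [read_sites()]); a fix is at-anchor
#'   when inside any site's buffer.
#' @return Logical vector, one element per fix.
#' @export
attendance_mask <- function(fixes, sites) {
  m <- rep(FALSE, nrow(fixes))
  for (k in seq_len(nrow(sites))) {
    d <- geodesic_distance(fixes$lon, fixes$lat, sites$lon[k], sites$lat[k])
    m <- m | (d <= sites$radius_m[k])
  }
  m
}

#' Detect foraging events in a fix window
#'
#' A foraging event is a maximal run of spatially clumped fixes with highly
#' variable instantaneous speed: every fix within `clump_radius` of the
#' window centroid, at least `min_fixes` fixes, and a coefficient of
#' variation of speed of at least `speed_cv_min`. When a ground altitude
#' reference is supplied, the window's median altitude above that reference
#' must not exceed `max_altitude_agl`; without a reference the altitude
#' criterion is skipped. The thresholds are configurable because "clumped",
#' "low" and "highly variable" are qualitative field descriptions, not
#' published cut-offs.
#'
#' @param fixes Fix window (tibble), already outside the colony buffer.
#' @param clump_radius Max distance (m) of any fix from the window centroid.
#' @param min_fixes Minimum window length.
#' @param speed_cv_min Minimum sd(speed)/mean(speed) over the window.
#' @param max_altitude_agl Max median altitude (m) above `ground_alt`.
#' @param ground_alt Ground altitude reference (m), or `NULL` to skip the
#'   altitude criterion.
#' @return Tibble of events (possibly empty): window indices, start/end
#'   times, centroid, radius, fix count, speed CV, median altitude.
#' @export
detect_foraging_events <- function(fixes, clump_radius = 100, min_fixes = 3,
                                   speed_cv_min = 0.5,
                                   max_altitude_agl = 50, ground_alt = NULL) {
  n <- nrow(fixes)
  empty <- tibble::tibble(
    start_idx = integer(), end_idx = integer(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    centroid_lon = numeric(), centroid_lat = numeric(), radius_m = numeric(),
    n_fixes = integer(), speed_cv = numeric(), median_altitude = numeric()
  )
  if (n < min_fixes) return(empty)
  out <- list()
  i <- 1L
  while (i <= n - min_fixes + 1L) {
    j <- grow_clump(fixes$lon, fixes$lat, i, clump_radius)
    if (j - i + 1L >= min_fixes) {
      w <- i:j
      sp <- fixes$speed[w]
      cv <- if (mean(sp) > 0) sd(sp) / mean(sp) else 0
      alt_ok <- is.null(ground_alt) ||
        (median(fixes$altitude[w]) - ground_alt) <= max_altitude_agl
      if (cv >= speed_cv_min && alt_ok) {
        clon <- mean(fixes$lon[w])
        clat <- mean(fixes$lat[w])
        out[[length(out) + 1L]] <- tibble::tibble(
          start_idx = i, end_idx = j,
          start = fixes$timestamp[i], end = fixes$timestamp[j],
          centroid_lon = clon, centroid_lat = clat,
          radius_m = max(geodesic_distance(fixes$lon[w], fixes$lat[w],
                                           clon, clat)),
          n_fixes = j - i + 1L,
          speed_cv = cv,
          median_altitude = median(fixes$altitude[w])
        )
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

# Longest window starting at i whose fixes all lie within `radius` of the
# running centroid. Re-checks the whole window after each extension, so a
# centroid drift that pushes an early fix out stops the growth.
grow_clump <- function(lon, lat, i, radius) {
  n <- length(lon)
  j <- i
  while (j < n) {
    w <- i:(j + 1L)
    clon <- mean(lon[w]); clat <- mean(lat[w])
    if (max(geodesic_distance(lon[w], lat[w], clon, clat)) > radius) break
    j <- j + 1L
  }
  j
}

#' Segment tracks into excursions and foraging trips
#'
#' Splits each individual's track at its anchor attendance bouts (colony
#' plus optional roosts, 50 m buffers). Each maximal run of fixes outside
#' every anchor buffer is a candidate excursion; it is a foraging trip when
#' it extends strictly beyond 300 m from the colony and contains at least
#' one detected foraging event. Excursions whose departure from or arrival
#' at an anchor was not observed (track starts or ends mid-excursion) are
#' flagged incomplete and must be excluded from statistics. Excursions
#' beyond 300 m without a foraging event are retained as non-foraging
#' excursions (`is_trip = FALSE`).
#'
#' Trip departure is the last fix inside an anchor buffer before exit and
#' arrival the first fix inside after return, which bounds trip duration
#' consistently across GPS cadences.
#'
#' @param fixes Fixes tibble (one or more individuals).
#' @param sites Anchor site table; the first row is taken as the breeding
#'   colony (used for the 300 m rule and maximum-distance metric).
#' @param trip_min_distance Trip qualification distance from the colony,
#'   default 300 m (strictly greater).
#' @param event_params Named list of overrides for
#'   [detect_foraging_events()].
#' @return Tibble with one row per excursion: indices into `fixes`
#'   (`dep_idx`, `arr_idx` include the anchor endpoint fixes; `first_out`,
#'   `last_out` the exterior fixes), departure/arrival times, date of
#'   departure, completeness, `is_trip`, maximum distance from the colony,
#'   and foraging-event count.
#' @export
segment_trips <- function(fixes, sites, trip_min_distance = 300,
                          event_params = list()) {
  stopifnot(nrow(sites) >= 1)
  colony <- sites[1, ]
  fixes <- dplyr::mutate(fixes, .row = dplyr::row_number())
  out <- fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_map(~ segment_one(.x, .y$individual_id, sites, colony,
                                   trip_min_distance, event_params)) |>
    dplyr::bind_rows()
  if (nrow(out)) {
    out$trip_id <- paste0(out$individual_id, "_", out$date, "_",
                          sequence(rle(paste(out$individual_id,
                                             out$date))$lengths))
    out
  } else {
    empty_excursions()
  }
}

empty_excursions <- function() {
  tibble::tibble(
    individual_id = character(), date = as.Date(character()),
    departure = as.POSIXct(character(), tz = "UTC"),
    arrival = as.POSIXct(character(), tz = "UTC"),
    dep_idx = integer(), arr_idx = integer(),
    first_out = integer(), last_out = integer(),
    n_fixes = integer(), sampling_interval = integer(),
    complete = logical(), max_dist_colony_m = numeric(),
    n_events = integer(), is_trip = logical(), trip_id = character()
  )
}

segment_one <- function(fx, id, sites, colony, trip_min_distance,
                        event_params) {
  n <- nrow(fx)
  at <- attendance_mask(fx, sites)
  if (n == 0 || all(at)) {
    return(tibble::tibble())
  }
  r <- rle(!at)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  d_colony <- geodesic_distance(fx$lon, fx$lat, colony$lon, colony$lat)
  res <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    complete <- s > 1L && e < n
    w <- fx[s:e, , drop = FALSE]
    ev <- do.call(detect_foraging_events, c(list(w), event_params))
    maxd <- max(d_colony[s:e])
    dep_idx <- if (s > 1L) s - 1L else s
    arr_idx <- if (e < n) e + 1L else e
    res[[k]] <- tibble::tibble(
      individual_id = id,
      date = as.Date(fx$timestamp[dep_idx], tz = "UTC"),
      departure = fx$timestamp[dep_idx],
      arrival = fx$timestamp[arr_idx],
      dep_idx = fx$.row[dep_idx], arr_idx = fx$.row[arr_idx],
      first_out = fx$.row[s], last_out = fx$.row[e],
      n_fixes = e - s + 1L,
      sampling_interval = fx$sampling_interval[s],
      complete = complete,
      max_dist_colony_m = maxd,
      n_events = nrow(ev),
      is_trip = maxd > trip_min_distance && nrow(ev) >= 1
    )
  }
  dplyr::bind_rows(res)
}

#' Identify complete tracking days
#'
#' A tracking day is complete when fixes cover the whole daylight window:
#' first fix no later than `tol` after sunrise, last fix no earlier than
#' `tol` before sunset, and no internal gap longer than `gap_factor` times
#' the sampling interval.
#'
#' @param fixes Fixes tibble.
#' @param colony One-row site table giving the coordinates at which solar
#'   times are evaluated.
#' @param tol Coverage tolerance at the day edges, seconds (default 15 min).
#' @param gap_factor Maximum internal gap as a multiple of the sampling
#'   interval (default 3).
#' @return Tibble with one row per individual x date: fix counts, coverage,
#'   solar times, `day_length` (s) and the `complete` flag.
#' @export
complete_days <- function(fixes, colony, tol = 900, gap_factor = 3) {
  stopifnot(nrow(colony) == 1)
  fixes |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$individual_id, .data$date) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      first_fix = min(.data$timestamp),
      last_fix = max(.data$timestamp),
      max_gap = if (dplyr::n() > 1)
        max(as.numeric(diff(.data$timestamp), units = "secs")) else Inf,
      sampling_interval = .data$sampling_interval[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      solar_times(.data$date, colony$lon, colony$lat)[-1],
      complete = .data$first_fix <= .data$sunrise + tol &
        .data$last_fix >= .data$sunset - tol &
        .data$max_gap <= gap_factor * .data$sampling_interval
    )
}
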