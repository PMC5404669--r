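#' Column mapping for Movebank-style fix CSVs
#'
#' Default dialect follows Movebank export headers. Any mapping with the six
#' mandatory roles can be supplied instead, or read from a YAML file with
#' [read_dialect()].
#'
#' @return Named list mapping roles (`individual_id`, `timestamp`, `lon`,
#'   `lat`, `altitude`, `speed`) to CSV column names.
#' @export
movebank_dialect <- function() {
  list(
    individual_id = "individual-local-identifier",
    timestamp = "timestamp",
    lon = "location-long",
    lat = "location-lat",
    altitude = "height-above-msl",
    speed = "ground-speed"
  )
}

#' Read a fix-dialect configuration from YAML
#'
#' @param path YAML file with a `columns:` block naming the six roles.
#' @return A dialect list as from [movebank_dialect()].
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  cols <- cfg$columns %||% cfg
  needed <- names(movebank_dialect())
  missing <- setdiff(needed, names(cols))
  if (length(missing)) {
    stop("dialect is missing roles: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols[needed]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read GPS fixes from CSV
#'
#' Reads a Movebank-style fix table, validates and orders it, and infers the
#' GPS sampling interval per individual from the modal inter-fix gap (unless
#' declared). Rows with unparseable timestamps or out-of-range coordinates
#' are skipped and counted; duplicate timestamps within an individual keep
#' the first fix. The number of skipped rows is attached as attribute
#' `n_skipped` and reported via a warning when positive.
#'
#' @param path CSV file path.
#' @param dialect Column mapping, default [movebank_dialect()].
#' @param sampling_interval Optional declared cadence in seconds (one of
#'   1, 60, 180, 300, 600); inferred per individual when `NULL`.
#' @return A tibble of fixes with columns `individual_id`, `timestamp`
#'   (POSIXct UTC), `lon`, `lat`, `altitude`, `speed`, `sampling_interval`,
#'   sorted by individual and time.
#' @export
read_fixes <- function(path, dialect = movebank_dialect(),
                       sampling_interval = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- unlist(dialect[names(movebank_dialect())])
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("fix file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(empty_fixes())
  }
  ts <- as.POSIXct(strptime(raw[[dialect$timestamp]],
                            "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  iso <- is.na(ts)
  ts[iso] <- as.POSIXct(strptime(raw[[dialect$timestamp]][iso],
                                 "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  df <- tibble::tibble(
    individual_id = raw[[dialect$individual_id]],
    timestamp = ts,
    lon = suppressWarnings(as.numeric(raw[[dialect$lon]])),
    lat = suppressWarnings(as.numeric(raw[[dialect$lat]])),
    altitude = suppressWarnings(as.numeric(raw[[dialect$altitude]])),
    speed = suppressWarnings(as.numeric(raw[[dialect$speed]]))
  )
  as_fix_table(df, sampling_interval = sampling_interval)
}

empty_fixes <- function() {
  out <- tibble::tibble(
    individual_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    lon = numeric(), lat = numeric(),
    altitude = numeric(), speed = numeric(),
    sampling_interval = integer()
  )
  attr(out, "n_skipped") <- 0L
  out
}

#' Validate and normalise a fix table
#'
#' Drops malformed rows (bad timestamp/coordinates, negative speed), sorts
#' by individual and time, removes duplicate timestamps (keeping the first),
#' and fills `sampling_interval` from the modal inter-fix gap snapped to the
#' legal set {1, 60, 180, 300, 600} s.
#'
#' @param df Data frame with fix columns.
#' @param sampling_interval Optional declared cadence (seconds).
#' @return Validated fixes tibble; attribute `n_skipped` counts dropped rows.
#' @export
as_fix_table <- function(df, sampling_interval = NULL) {
  n0 <- nrow(df)
  ok <- !is.na(df$timestamp) & !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90 &
    (is.na(df$speed) | df$speed >= 0) & !is.na(df$individual_id)
  df <- df[ok, , drop = FALSE]
  n_skipped <- n0 - nrow(df)
  df <- dplyr::arrange(df, .data$individual_id, .data$timestamp)
  dup <- duplicated(df[, c("individual_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) dropped (first fix kept)",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  if (!is.null(sampling_interval)) {
    df$sampling_interval <- as.integer(check_interval(sampling_interval))
  } else if (!"sampling_interval" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::mutate(sampling_interval = infer_interval(.data$timestamp)) |>
      dplyr::ungroup()
  }
  if (n_skipped > 0) {
    warning(n_skipped, " malformed row(s) skipped", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "n_skipped") <- as.integer(max(n_skipped, 0L))
  out
}

check_interval <- function(x) {
  if (!all(x %in% SAMPLING_INTERVALS)) {
    stop("sampling_interval must be one of ",
         paste(SAMPLING_INTERVALS, collapse = ", "), " s", call. = FALSE)
  }
  x
}

# Modal inter-fix gap snapped to the nearest legal cadence.
infer_interval <- function(timestamp) {
  if (length(timestamp) < 2) return(NA_integer_)
  gaps <- round(as.numeric(diff(timestamp), units = "secs"))
  modal <- as.numeric(names(which.max(table(gaps))))
  snapped <- SAMPLING_INTERVALS[which.min(abs(SAMPLING_INTERVALS - modal))]
  if (abs(snapped - modal) > 0.1 * snapped) {
    warning("modal inter-fix gap ", modal,
            " s is far from the legal cadences; using ", snapped, " s",
            call. = FALSE)
  }
  rep(as.integer(snapped), length(timestamp))
}

#' Write GPS fixes to CSV
#'
#' Inverse of [read_fixes()]: writes with the same dialect so that a
#' read/write round trip preserves every field for clean input.
#'
#' @param fixes Fixes tibble.
#' @param path Output CSV path.
#' @param dialect Column mapping, default [movebank_dialect()].
#' @export
write_fixes <- function(fixes, path, dialect = movebank_dialect()) {
  out <- tibble::tibble(
    a = fixes$individual_id,
    b = format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    c = fixes$lon, d = fixes$lat, e = fixes$altitude, f = fixes$speed
  )
  names(out) <- unlist(dialect[names(movebank_dialect())])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read anchor sites (colony and roosts)
#'
#' @param path CSV with columns `name,lon,lat,radius_m`; `radius_m` defaults
#'   to 50 m (the colony-attendance buffer) when absent.
#' @return Tibble of sites.
#' @export
read_sites <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    name = "c", lon = "d", lat = "d", .default = "d"), progress = FALSE)
  if (!"radius_m" %in% names(df)) df$radius_m <- 50
  df$radius_m[is.na(df$radius_m)] <- 50
  stopifnot(all(df$radius_m > 0))
  check_coords(df$lon, df$lat)
  tibble::as_tibble(df[, c("name", "lon", "lat", "radius_m")])
}

#' Construct a site table in code
#'
#' @param name Site name(s).
#' @param lon,lat Coordinates (degrees).
#' @param radius_m Attendance buffer radius, default 50 m.
#' @return Tibble of sites.
#' @export
site <- function(name, lon, lat, radius_m = 50) {
  check_coords(lon, lat)
  stopifnot(all(radius_m > 0))
  tibble::tibble(name = name, lon = lon, lat = lat, radius_m = radius_m)
}

#' Optional altitude smoothing
#'
#' GPS altitude is noisy; when a smoothing window is configured the altitude
#' column is replaced by a centred rolling median. Off by default — none of
#' the core metrics use altitude unless the optional altitude criterion of
#' the foraging-event detector is enabled.
#'
#' @param fixes Fixes tibble.
#' @param window Odd window size in fixes; `0` (default) disables smoothing.
#' @return Fixes tibble with smoothed `altitude`.
#' @export
smooth_altitude <- function(fixes, window = 0) {
  if (window <= 1) return(fixes)
  if (window %% 2 == 0) window <- window + 1
  fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(altitude = stats::runmed(.data$altitude, k = min(window,
      2 * (dplyr::n() %/% 2) - 1), endrule = "median")) |>
    dplyr::ungroup()
}
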