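#' Breeding phenological periods
#'
#' The breeding season of each pair is divided into four ordered periods
#' anchored on its laying and hatching dates: establishment (arrival at the
#' colony until courtship), courtship (the 21 days before laying of the
#' first egg), incubation (laying to hatching of the first egg) and nestling
#' (hatching of the first egg until fledging of the last chick). All
#' intervals are start-inclusive / end-exclusive, so the four periods
#' partition `[arrival, fledging]` exactly.
#'
#' @return Character vector of period levels in temporal order.
#' @export
period_levels <- function() {
  c("establishment", "courtship", "incubation", "nestling")
}

COURTSHIP_DAYS <- 21L

#' Construct breeding records
#'
#' @param pair_id Identifier of the breeding pair (matched to
#'   `individual_id` in fix tables).
#' @param arrival,laying,hatching,fledging Dates: colony arrival, laying of
#'   the first egg, hatching of the first egg, fledging of the last chick.
#' @param brood_size Brood size (single value per pair, or supply a long
#'   table via [read_breeding_records()]).
#' @return Tibble of validated breeding records.
#' @export
breeding_record <- function(pair_id, arrival, laying, hatching, fledging,
                            brood_size = NA_integer_) {
  rec <- tibble::tibble(
    pair_id = pair_id,
    arrival = as.Date(arrival), laying = as.Date(laying),
    hatching = as.Date(hatching), fledging = as.Date(fledging),
    brood_size = as.integer(brood_size)
  )
  bad <- rec$arrival > rec$laying - COURTSHIP_DAYS |
    rec$laying >= rec$hatching | rec$hatching >= rec$fledging
  if (any(bad)) {
    stop("invalid breeding record(s): need arrival <= laying - 21 d < ",
         "laying < hatching < fledging", call. = FALSE)
  }
  if (any(!is.na(rec$brood_size) & rec$brood_size < 0)) {
    stop("brood_size must be >= 0", call. = FALSE)
  }
  rec
}

#' Read breeding records from CSV
#'
#' @param path CSV with columns `pair_id,arrival,laying,hatching,fledging`
#'   and optionally `brood_size`.
#' @return Tibble of validated breeding records.
#' @export
read_breeding_records <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    pair_id = "c", arrival = "D", laying = "D", hatching = "D",
    fledging = "D", .default = "i"), progress = FALSE)
  breeding_record(df$pair_id, df$arrival, df$laying, df$hatching,
                  df$fledging,
                  if ("brood_size" %in% names(df)) df$brood_size else NA)
}

#' Assign a phenological period
#'
#' @param instant POSIXct instant(s) or Date(s).
#' @param record One breeding record (one-row tibble from
#'   [breeding_record()]).
#' @return Factor with levels [period_levels()].
#' @export
assign_period <- function(instant, record) {
  stopifnot(nrow(record) == 1)
  d <- as.Date(instant, tz = "UTC")
  if (any(d < record$arrival | d > record$fledging)) {
    stop("instant outside the breeding window [arrival, fledging]",
         call. = FALSE)
  }
  courtship_start <- record$laying - COURTSHIP_DAYS
  p <- dplyr::case_when(
    d >= record$hatching ~ "nestling",
    d >= record$laying ~ "incubation",
    d >= courtship_start ~ "courtship",
    TRUE ~ "establishment"
  )
  factor(p, levels = period_levels())
}

#' Age of the eldest chick
#'
#' Elapsed whole days since hatching of the first egg; the hatch day itself
#' is age 0.
#'
#' @param date Date(s) within the nestling period.
#' @param record One breeding record.
#' @return Integer age(s) in days.
#' @export
eldest_chick_age <- function(date, record) {
  stopifnot(nrow(record) == 1)
  d <- as.Date(date)
  if (any(d < record$hatching)) {
    stop("date before hatching: eldest chick age undefined", call. = FALSE)
  }
  as.integer(d - record$hatching)
}
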