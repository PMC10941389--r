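#' Read visit-level feeder records
#'
#' Reads a CSV/TSV file of single-space feeder visits with the columns
#' `animal_id, pen_id, room_id, breed, sire_id, age_days, intake_kg`
#' (and optionally `body_weight_kg`). The delimiter is sniffed from the
#' header line.
#'
#' @param path Path to the visit file (UTF-8, decimal point).
#' @return A tibble of visit records.
#' @export
read_visits <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  visits <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  assert_cols(visits,
              c("animal_id", "pen_id", "room_id", "breed", "sire_id",
                "age_days", "intake_kg"), "visit file")
  dplyr::mutate(visits,
                animal_id = as.character(.data$animal_id),
                age_days = as.integer(.data$age_days))
}

#' Remove implausible feeder visits
#'
#' Applies configurable plausibility rules to raw visit records: per-visit
#' intake must be non-negative and below a maximum, and the summed intake of
#' an animal-day must not exceed a daily maximum (all visits of an offending
#' day are dropped, so the day later surfaces as missing rather than as an
#' implausible total). A cleaning log with per-rule removal counts is
#' attached as the `"cleaning_log"` attribute and retrievable with
#' [cleaning_log()].
#'
#' @param visits Tibble of visit records (see [read_visits()]).
#' @param max_per_visit Maximum plausible intake per visit, kg. Default 5.
#' @param max_per_day Maximum plausible summed intake per animal-day, kg.
#'   Default 10.
#' @return The retained visits, with a `"cleaning_log"` attribute.
#' @export
clean_visits <- function(visits, max_per_visit = 5, max_per_day = 10) {
  assert_cols(visits, c("animal_id", "age_days", "intake_kg"), "visits")
  n0 <- nrow(visits)

  neg <- visits$intake_kg < 0
  visits1 <- visits[!neg, , drop = FALSE]

  big <- visits1$intake_kg > max_per_visit
  visits2 <- visits1[!big, , drop = FALSE]

  day_tot <- dplyr::summarise(
    dplyr::group_by(visits2, .data$animal_id, .data$age_days),
    total = sum(.data$intake_kg), .groups = "drop")
  bad_days <- day_tot[day_tot$total > max_per_day,
                      c("animal_id", "age_days")]
  visits3 <- dplyr::anti_join(visits2, bad_days,
                              by = c("animal_id", "age_days"))

  log <- tibble::tibble(
    rule = c("negative_intake", "per_visit_maximum", "per_day_maximum"),
    removed = c(sum(neg), sum(big), nrow(visits2) - nrow(visits3)))
  stopifnot(sum(log$removed) + nrow(visits3) == n0)
  if (nrow(visits3) == 0) warn("all visits removed by cleaning rules")
  attr(visits3, "cleaning_log") <- log
  visits3
}

#' Retrieve the cleaning log attached by a cleaning step
#' @param x An object returned by [clean_visits()] or a filtering step.
#' @return A tibble of per-rule removal counts, or `NULL`.
#' @export
cleaning_log <- function(x) attr(x, "cleaning_log")

#' Aggregate visits to daily feed consumption
#'
#' Sums per-visit intake over each animal's integer age-day to obtain daily
#' feed consumption (FCD, kg/day). Each animal's series covers every day
#' from its first to its last recorded visit; days without any visit are
#' explicit rows flagged `missing` with `fcd_kg = NA` (never zero).
#'
#' @param visits Cleaned visit records.
#' @return A tibble with one row per animal-day:
#'   `animal_id, breed, pen_id, room_id, sire_id, age_days, fcd_kg, missing`.
#' @export
aggregate_visits_to_daily <- function(visits) {
  assert_cols(visits, c("animal_id", "pen_id", "room_id", "breed", "sire_id",
                        "age_days", "intake_kg"), "visits")
  meta <- dplyr::distinct(visits, .data$animal_id, .data$breed,
                          .data$pen_id, .data$room_id, .data$sire_id)
  dup <- meta$animal_id[duplicated(meta$animal_id)]
  if (length(dup) > 0) {
    abort(sprintf("conflicting metadata for animal(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }

  daily <- dplyr::summarise(
    dplyr::group_by(visits, .data$animal_id, .data$age_days),
    fcd_kg = sum(.data$intake_kg), .groups = "drop")

  span <- dplyr::summarise(dplyr::group_by(daily, .data$animal_id),
                           first = min(.data$age_days),
                           last = max(.data$age_days), .groups = "drop")
  grid <- tidyr::unnest(
    dplyr::mutate(span,
                  age_days = purrr::map2(.data$first, .data$last, seq)),
    "age_days")[, c("animal_id", "age_days")]

  out <- dplyr::left_join(grid, daily, by = c("animal_id", "age_days"))
  out <- dplyr::left_join(out, meta, by = "animal_id")
  out <- dplyr::mutate(out, missing = is.na(.data$fcd_kg))
  dplyr::arrange(
    out[, c("animal_id", "breed", "pen_id", "room_id", "sire_id",
            "age_days", "fcd_kg", "missing")],
    .data$animal_id, .data$age_days)
}

#' Restrict daily series to an age window
#'
#' Keeps only days inside `[start_day, end_day]` (both inclusive). Each
#' retained animal's series is re-spanned from its first to its last
#' observed day inside the window; animals with no observed day in the
#' window are dropped and listed in the `"cleaning_log"` attribute.
#'
#' @param daily Daily series from [aggregate_visits_to_daily()].
#' @param start_day,end_day Inclusive window bounds in days of age
#'   (defaults 99 and 140, the mid-test period between swab collections).
#' @return The restricted daily tibble.
#' @export
restrict_period <- function(daily, start_day = 99, end_day = 140) {
  assert_cols(daily, c("animal_id", "age_days", "fcd_kg", "missing"), "daily")
  inside <- daily[daily$age_days >= start_day & daily$age_days <= end_day, ,
                  drop = FALSE]
  obs <- dplyr::filter(inside, !.data$missing)
  kept_ids <- unique(obs$animal_id)
  dropped <- setdiff(unique(daily$animal_id), kept_ids)

  span <- dplyr::summarise(dplyr::group_by(obs, .data$animal_id),
                           first = min(.data$age_days),
                           last = max(.data$age_days), .groups = "drop")
  out <- dplyr::inner_join(inside, span, by = "animal_id")
  out <- dplyr::filter(out, .data$age_days >= .data$first,
                       .data$age_days <= .data$last)
  out <- dplyr::select(out, -"first", -"last")
  attr(out, "cleaning_log") <- tibble::tibble(
    rule = "no_observation_in_window", removed_animals = list(dropped))
  out
}

#' Apply animal-level inclusion filters
#'
#' Removes animals with fewer than `min_days` observed daily records or with
#' any run of more than `max_gap` consecutive missing days inside their
#' series span. Removal reasons are recorded per animal in the
#' `"cleaning_log"` attribute.
#'
#' @param daily Period-restricted daily tibble.
#' @param min_days Minimum number of observed days; "fewer than 10" removes
#'   animals with at most 9. Default 10.
#' @param max_gap Largest tolerated run of consecutive missing days; a gap
#'   of `max_gap + 1` or more removes the animal. Default 3.
#' @return The filtered daily tibble.
#' @export
filter_animals <- function(daily, min_days = 10, max_gap = 3) {
  assert_cols(daily, c("animal_id", "age_days", "missing"), "daily")
  per <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(daily, .data$animal_id, .data$age_days),
                    .data$animal_id),
    n_obs = sum(!.data$missing),
    longest_gap = longest_true_run(.data$missing),
    .groups = "drop")
  per <- dplyr::mutate(per,
                       too_few = .data$n_obs < min_days,
                       gap_too_long = .data$longest_gap > max_gap)
  removed <- dplyr::filter(per, .data$too_few | .data$gap_too_long)
  out <- daily[!daily$animal_id %in% removed$animal_id, , drop = FALSE]
  attr(out, "cleaning_log") <- removed
  out
}

longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
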