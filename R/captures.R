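#' Assemble a capture dataset from a table of capture records
#'
#' A capture dataset bundles one row per individual capture (bat, date, roost,
#' population, sex, age class, optional reproductive status) together with the
#' capture events derived from them and, optionally, a roost registry. A
#' capture event (a "group capture") is one netting occasion of one day roost:
#' all records sharing the same `(date, roost_id)` belong to one event, and
#' two captures of the same roost on different dates are distinct events.
#'
#' @param captures A data frame with columns `bat_id`, `date` (Date or
#'   ISO-8601 string), `roost_id`, `population`, `sex` (`"female"`/`"male"`),
#'   `age_class` (`"adult"`/`"juvenile"`) and optionally `repro_status`
#'   (`"pregnant"`, `"lactating"`, `"scrotal"`, `"nonreproductive"`,
#'   `"unknown"` or missing).
#' @param roosts Optional roost registry, as returned by [read_roosts()]: a
#'   tibble with `roost_id`, `population`, `x`, `y` and a `coord_system`
#'   attribute. When supplied, every `roost_id` in `captures` must resolve in
#'   the registry and populations must agree.
#' @return An object of class `capture_dataset`: a list with tibbles
#'   `captures` (records, with `event_id` and `year` added), `events`
#'   (one row per capture event with its size) and `roosts`.
#' @export
as_capture_dataset <- function(captures, roosts = NULL) {
  captures <- tibble::as_tibble(captures)
  required <- c("bat_id", "date", "roost_id", "population", "sex", "age_class")
  missing_cols <- setdiff(required, names(captures))
  if (length(missing_cols) > 0) {
    stop("capture table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"repro_status" %in% names(captures)) captures$repro_status <- NA_character_

  captures <- captures |>
    dplyr::mutate(
      bat_id = as.character(.data$bat_id),
      roost_id = as.character(.data$roost_id),
      population = as.character(.data$population),
      sex = as.character(.data$sex),
      age_class = as.character(.data$age_class),
      repro_status = as.character(.data$repro_status)
    )
  captures$repro_status[!is.na(captures$repro_status) &
                          captures$repro_status %in% c("", "NA")] <- NA_character_

  if (!inherits(captures$date, "Date")) {
    parsed <- as.Date(captures$date, format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))
      stop("unparseable date(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
           " (expected ISO-8601 yyyy-mm-dd)", call. = FALSE)
    }
    captures$date <- parsed
  }

  bad_sex <- !captures$sex %in% c("female", "male")
  if (any(bad_sex)) {
    stop("unknown sex code(s) at row(s) ",
         paste(head(which(bad_sex), 5), collapse = ", "),
         ": ", paste(unique(captures$sex[bad_sex]), collapse = ", "), call. = FALSE)
  }
  bad_age <- !captures$age_class %in% c("adult", "juvenile")
  if (any(bad_age)) {
    stop("unknown age_class code(s) at row(s) ",
         paste(head(which(bad_age), 5), collapse = ", "),
         ": ", paste(unique(captures$age_class[bad_age]), collapse = ", "), call. = FALSE)
  }
  valid_repro <- c("pregnant", "lactating", "scrotal", "nonreproductive", "unknown")
  bad_rs <- !is.na(captures$repro_status) & !captures$repro_status %in% valid_repro
  if (any(bad_rs)) {
    stop("unknown repro_status code(s): ",
         paste(unique(captures$repro_status[bad_rs]), collapse = ", "), call. = FALSE)
  }

  # a bat appears at most once per capture event
  dup <- captures |>
    dplyr::count(.data$bat_id, .data$date, .data$roost_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("bat(s) recorded more than once in a single capture event: ",
         paste(sprintf("%s at %s on %s", dup$bat_id, dup$roost_id, dup$date),
               collapse = "; "), call. = FALSE)
  }

  # a roost belongs to exactly one population
  roost_pop <- captures |> dplyr::distinct(.data$roost_id, .data$population)
  multi <- roost_pop |> dplyr::count(.data$roost_id) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop("roost(s) assigned to more than one population: ",
         paste(multi$roost_id, collapse = ", "), call. = FALSE)
  }

  if (!is.null(roosts)) {
    unknown <- !captures$roost_id %in% roosts$roost_id
    if (any(unknown)) {
      stop("unknown roost_id(s) at row(s) ",
           paste(head(which(unknown), 5), collapse = ", "), ": ",
           paste(unique(captures$roost_id[unknown]), collapse = ", "), call. = FALSE)
    }
    reg_pop <- setNames(roosts$population, roosts$roost_id)
    mismatch <- captures$population != reg_pop[captures$roost_id]
    if (any(mismatch)) {
      stop("population disagrees with the roost registry at row(s) ",
           paste(head(which(mismatch), 5), collapse = ", "), call. = FALSE)
    }
  }

  ds <- structure(list(captures = captures, events = NULL, roosts = roosts),
                  class = "capture_dataset")
  ds <- derive_events(ds)
  ds
}

# Re-derive capture events from the records: pure function of (date, roost_id).
derive_events <- function(ds) {
  captures <- ds$captures
  events <- captures |>
    dplyr::distinct(.data$date, .data$roost_id, .data$population) |>
    dplyr::arrange(.data$date, .data$roost_id) |>
    dplyr::mutate(
      event_id = sprintf("E%04d", dplyr::row_number()),
      year = as.integer(format(.data$date, "%Y"))
    )
  captures <- captures |>
    dplyr::select(-dplyr::any_of(c("event_id", "year"))) |>
    dplyr::left_join(events |> dplyr::select("date", "roost_id", "event_id", "year"),
                     by = c("date", "roost_id"))
  sizes <- captures |> dplyr::count(.data$event_id, name = "size")
  events <- events |>
    dplyr::left_join(sizes, by = "event_id") |>
    dplyr::select("event_id", "date", "roost_id", "population", "year", "size")
  ds$captures <- captures
  ds$events <- events
  ds
}

#' Read capture records from CSV
#'
#' Expects columns `bat_id,date,roost_id,population,sex,age_class,repro_status`
#' with ISO-8601 dates; the `repro_status` column may be absent. Rows failing
#' validation (unknown roost, duplicated bat within an event, unknown sex or
#' age codes) are rejected with an informative error.
#'
#' @param path Path to a captures CSV file.
#' @param roosts Optional roost registry (object from [read_roosts()] or a
#'   path to a roosts CSV).
#' @param quiet Suppress the summary message.
#' @return A [as_capture_dataset()] object.
#' @export
read_captures <- function(path, roosts = NULL, quiet = FALSE) {
  if (is.character(roosts)) roosts <- read_roosts(roosts)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  ds <- as_capture_dataset(raw, roosts = roosts)
  if (!quiet) {
    message(sprintf(
      "read %d capture records: %d bats, %d capture events, %d roosts",
      nrow(ds$captures), dplyr::n_distinct(ds$captures$bat_id),
      nrow(ds$events), dplyr::n_distinct(ds$captures$roost_id)))
  }
  ds
}

#' Write capture records to CSV
#'
#' Emits the canonical captures dialect
#' (`bat_id,date,roost_id,population,sex,age_class,repro_status`); reading the
#' file back with [read_captures()] reproduces identical records and events.
#'
#' @param ds A `capture_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(ds, path) {
  ds$captures |>
    dplyr::select("bat_id", "date", "roost_id", "population", "sex",
                  "age_class", "repro_status") |>
    readr::write_csv(path, na = "")
  invisible(path)
}

#' Filter a capture dataset to well-sampled individuals
#'
#' Applies, in order: the population restriction, the adults-only restriction,
#' then the minimum-sightings rule. Sightings are counted as capture events of
#' the already-restricted record set, so `min_sightings = 4` with
#' `adults_only = TRUE` selects bats captured at least four times *as adults*.
#' The surviving bats' (restricted) records are returned; the operation is
#' idempotent.
#'
#' @param ds A `capture_dataset`.
#' @param adults_only Keep only records with `age_class == "adult"`.
#' @param min_sightings Minimum number of capture events per bat (>= 1).
#' @param population Optional population label to restrict to.
#' @return A filtered `capture_dataset` (empty, with a warning, if nothing
#'   survives).
#' @export
filter_captures <- function(ds, adults_only = TRUE, min_sightings = 1L,
                            population = NULL) {
  stopifnot(inherits(ds, "capture_dataset"), min_sightings >= 1)
  recs <- ds$captures
  if (!is.null(population)) recs <- recs |> dplyr::filter(.data$population %in% !!population)
  if (adults_only) recs <- recs |> dplyr::filter(.data$age_class == "adult")
  counts <- recs |>
    dplyr::distinct(.data$bat_id, .data$date, .data$roost_id) |>
    dplyr::count(.data$bat_id)
  keep <- counts$bat_id[counts$n >= min_sightings]
  recs <- recs |> dplyr::filter(.data$bat_id %in% keep)
  if (nrow(recs) == 0) warning("no capture records satisfy the filter; returning an empty dataset")
  out <- ds
  out$captures <- recs
  derive_events(out)
}

#' Number of bats seen at least N times
#'
#' Tabulates, for each threshold N from 1 to the maximum per-bat sighting
#' count, how many bats were captured in at least N capture events. The curve
#' is non-increasing and its value at N = 1 is the total number of bats.
#'
#' @param ds A `capture_dataset` (filter first if a restricted set is wanted).
#' @return A tibble with columns `n_min` and `n_bats`.
#' @export
sightings_threshold_curve <- function(ds) {
  stopifnot(inherits(ds, "capture_dataset"))
  counts <- ds$captures |> dplyr::count(.data$bat_id)
  if (nrow(counts) == 0) return(tibble::tibble(n_min = integer(), n_bats = integer()))
  tibble::tibble(
    n_min = seq_len(max(counts$n)),
    n_bats = vapply(seq_len(max(counts$n)),
                    function(k) sum(counts$n >= k), integer(1))
  )
}

#' Per-event group composition
#'
#' Summarises each capture event: size, sex counts, number of reproductive
#' (scrotal) males, and a class computed from sex alone
#' (`all-male` / `all-female` / `mixed`). Missing reproductive status is
#' tolerated and counted as unknown.
#'
#' @param ds A `capture_dataset`.
#' @return A tibble with one row per capture event.
#' @export
group_composition <- function(ds) {
  stopifnot(inherits(ds, "capture_dataset"))
  comp <- ds$captures |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_females = sum(.data$sex == "female"),
      n_males = sum(.data$sex == "male"),
      n_reproductive_males = sum(.data$sex == "male" &
                                   !is.na(.data$repro_status) &
                                   .data$repro_status == "scrotal"),
      n_repro_unknown = sum(is.na(.data$repro_status) |
                              .data$repro_status == "unknown"),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_females == 0 ~ "all-male",
      .data$n_males == 0 ~ "all-female",
      TRUE ~ "mixed"
    ))
  ds$events |>
    dplyr::select("event_id", "date", "roost_id", "population", "year") |>
    dplyr::left_join(comp, by = "event_id")
}

#' @export
print.capture_dataset <- function(x, ...) {
  cat(sprintf(
    "<capture_dataset> %d records | %d bats | %d events | %d roosts | %s populations\n",
    nrow(x$captures), dplyr::n_distinct(x$captures$bat_id), nrow(x$events),
    dplyr::n_distinct(x$captures$roost_id),
    dplyr::n_distinct(x$captures$population)))
  if (nrow(x$events) > 0) {
    cat(sprintf("  dates %s to %s | group sizes %d-%d (median %s)\n",
                min(x$events$date), max(x$events$date),
                min(x$events$size), max(x$events$size), median(x$events$size)))
  }
  invisible(x)
}

#' @export
glance.capture_dataset <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$captures),
    n_bats = dplyr::n_distinct(x$captures$bat_id),
    n_events = nrow(x$events),
    n_roosts = dplyr::n_distinct(x$captures$roost_id),
    n_populations = dplyr::n_distinct(x$captures$population),
    median_group_size = if (nrow(x$events)) median(x$events$size) else NA_real_,
    max_group_size = if (nrow(x$events)) max(x$events$size) else NA_integer_
  )
}
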