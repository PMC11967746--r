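# ehr_cohort: the central container. Three data.frames plus a reference date.

#' Construct an EHR cohort
#'
#' Bundles a person table, an event table, and an observation-period table
#' into a validated `ehr_cohort` object, the input to every filter and audit
#' operation in this package.
#'
#' @param persons data.frame with columns `person_id` (character, unique),
#'   `birth_date` (Date, may be NA), `sex` (character, may be NA), `race`
#'   (one of [race_levels()]), `ethnicity` (one of [ethnicity_levels()]),
#'   `death_date` (Date, may be NA), `address_present` (logical).
#' @param events data.frame with columns `person_id`, `event_date` (Date,
#'   non-missing), `event_kind` (one of `"diagnosis"`, `"medication"`,
#'   `"outpatient_visit"`).
#' @param observation_periods data.frame with columns `person_id`,
#'   `start_date`, `end_date` (Dates, `end_date >= start_date`).
#' @param reference_date The "time of the query" against which vital status
#'   is judged. Defaults to the latest event/observation date in the data
#'   (or today's date for an eventless cohort).
#' @return An object of class `ehr_cohort`.
#' @export
new_cohort <- function(persons, events = empty_events(),
                       observation_periods = empty_observation_periods(),
                       reference_date = NULL) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  observation_periods <- as.data.frame(observation_periods, stringsAsFactors = FALSE)

  for (col in c("birth_date", "death_date")) persons[[col]] <- as.Date(persons[[col]])
  events$event_date <- as.Date(events$event_date)
  observation_periods$start_date <- as.Date(observation_periods$start_date)
  observation_periods$end_date <- as.Date(observation_periods$end_date)
  persons$person_id <- as.character(persons$person_id)
  events$person_id <- as.character(events$person_id)
  observation_periods$person_id <- as.character(observation_periods$person_id)

  if (is.null(reference_date)) {
    candidates <- c(events$event_date, observation_periods$end_date)
    reference_date <- if (length(candidates)) max(candidates) else Sys.Date()
  }
  reference_date <- as.Date(reference_date)

  x <- structure(
    list(
      persons = persons,
      events = events,
      observation_periods = observation_periods,
      reference_date = reference_date
    ),
    class = "ehr_cohort"
  )
  validate_cohort(x)
}

#' @rdname new_cohort
#' @export
empty_events <- function() {
  data.frame(
    person_id = character(), event_date = as.Date(character()),
    event_kind = character(), stringsAsFactors = FALSE
  )
}

#' @rdname new_cohort
#' @export
empty_observation_periods <- function() {
  data.frame(
    person_id = character(), start_date = as.Date(character()),
    end_date = as.Date(character()), stringsAsFactors = FALSE
  )
}

#' Validate an EHR cohort
#'
#' Checks schema, closed race/ethnicity vocabularies, person_id uniqueness,
#' referential integrity of the event and observation-period tables, date
#' ordering (death after birth, observation end after start), and event-date
#' completeness. Returns the cohort invisibly-unchanged on success; stops
#' with a descriptive error otherwise.
#'
#' @param x An `ehr_cohort`.
#' @return `x`, invisibly validated.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "ehr_cohort"))
  p <- x$persons
  need <- c("person_id", "birth_date", "sex", "race", "ethnicity",
            "death_date", "address_present")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("person table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (tb in list(c("events", "person_id", "event_date", "event_kind"),
                  c("observation_periods", "person_id", "start_date", "end_date"))) {
    miss <- setdiff(tb[-1], names(x[[tb[1]]]))
    if (length(miss)) {
      stop(tb[1], " table is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  dup <- unique(p$person_id[duplicated(p$person_id)])
  if (length(dup)) {
    stop("duplicate person_id in person table: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  bad_race <- setdiff(unique(p$race), race_levels())
  if (length(bad_race)) {
    stop("race values outside the closed vocabulary: ",
         paste(bad_race, collapse = ", "), call. = FALSE)
  }
  bad_eth <- setdiff(unique(p$ethnicity), ethnicity_levels())
  if (length(bad_eth)) {
    stop("ethnicity values outside the closed vocabulary: ",
         paste(bad_eth, collapse = ", "), call. = FALSE)
  }
  both <- !is.na(p$birth_date) & !is.na(p$death_date)
  if (any(both & p$death_date < p$birth_date)) {
    stop("death_date precedes birth_date for: ",
         paste(utils::head(p$person_id[both & p$death_date < p$birth_date], 10),
               collapse = ", "), call. = FALSE)
  }
  for (tb in c("events", "observation_periods")) {
    dangling <- setdiff(unique(x[[tb]]$person_id), p$person_id)
    if (length(dangling)) {
      stop(tb, " table references person_id absent from person table: ",
           paste(utils::head(dangling, 10), collapse = ", "), call. = FALSE)
    }
  }
  if (anyNA(x$events$event_date)) {
    stop("events table contains missing event_date", call. = FALSE)
  }
  bad_kind <- setdiff(unique(x$events$event_kind), event_kinds())
  if (length(bad_kind)) {
    stop("unknown event_kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  op <- x$observation_periods
  if (anyNA(op$start_date) || anyNA(op$end_date)) {
    stop("observation_periods table contains missing dates", call. = FALSE)
  }
  if (any(op$end_date < op$start_date)) {
    stop("observation period with end_date before start_date for: ",
         paste(utils::head(op$person_id[op$end_date < op$start_date], 10),
               collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "<ehr_cohort> %d patients, %d events, %d observation periods\n",
    nrow(x$persons), nrow(x$events), nrow(x$observation_periods)
  ))
  cat(sprintf("  reference_date: %s\n", format(x$reference_date)))
  rc <- table(factor(x$persons$race, levels = race_levels()))
  rc <- rc[rc > 0]
  if (length(rc)) {
    cat("  race: ", paste(sprintf("%s=%d", names(rc), rc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param x An `ehr_cohort`.
#' @return Integer count of persons.
#' @export
n_patients <- function(x) nrow(x$persons)

#' Load an EHR cohort from delimited files
#'
#' Reads the three-table CSV schema (persons, events, observation periods),
#' validates it, and returns an [new_cohort()] object. Race and ethnicity
#' strings outside the closed vocabularies are mapped to `"Unknown"` and the
#' number of remapped rows reported via `message()`. With
#' `config$ukbb_mode = TRUE` the raw race column is first passed through
#' [harmonize_ukbb_race()] and ethnicity is set to `"Unknown"` (the UK
#' convention records a single combined field).
#'
#' @param person_path,events_path,obs_path Paths to the three CSV files.
#' @param config Optional list of read options: `reference_date` (override
#'   for the query date), `na_strings` (strings read as NA, default
#'   `c("", "NA")`), `ukbb_mode` (logical, default FALSE).
#' @return A validated `ehr_cohort`.
#' @export
load_cohort <- function(person_path, events_path, obs_path, config = list()) {
  na_strings <- config$na_strings %||% c("", "NA")
  read1 <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_strings,
                    colClasses = "character")
  }
  p <- read1(person_path)
  ev <- read1(events_path)
  op <- read1(obs_path)

  # a sibling cohort_meta.json (written by write_cohort) carries the query
  # date so round-trips preserve it; an explicit config value wins
  if (is.null(config$reference_date)) {
    meta_path <- file.path(dirname(person_path), "cohort_meta.json")
    if (file.exists(meta_path)) {
      meta <- jsonlite::read_json(meta_path)
      config$reference_date <- as.Date(meta$reference_date)
    }
  }

  need <- c("person_id", "birth_date", "sex", "race", "ethnicity",
            "death_date", "address_present")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("person file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  if (isTRUE(config$ukbb_mode)) {
    p$race <- harmonize_ukbb_race(p$race)
    p$ethnicity <- "Unknown"
  }
  n_bad_race <- sum(!(p$race %in% race_levels()) | is.na(p$race))
  n_bad_eth <- sum(!(p$ethnicity %in% ethnicity_levels()) | is.na(p$ethnicity))
  p$race[!(p$race %in% race_levels()) | is.na(p$race)] <- "Unknown"
  p$ethnicity[!(p$ethnicity %in% ethnicity_levels()) | is.na(p$ethnicity)] <- "Unknown"
  if (n_bad_race + n_bad_eth > 0) {
    message(sprintf(
      "load_cohort: mapped %d race and %d ethnicity value(s) outside the vocabulary to Unknown",
      n_bad_race, n_bad_eth
    ))
  }
  p$address_present <- as.logical(p$address_present)
  p$address_present[is.na(p$address_present)] <- FALSE

  new_cohort(
    persons = p, events = ev, observation_periods = op,
    reference_date = config$reference_date
  )
}

#' Write an EHR cohort to delimited files
#'
#' Writes `persons.csv`, `events.csv`, and `observation_periods.csv` under
#' `out_dir`, with ISO-8601 dates, a stable column order, and rows sorted by
#' person_id (then date), so that [load_cohort()] round-trips the cohort
#' bit-identically.
#'
#' @param cohort A validated `ehr_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  validate_cohort(cohort)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  fmt <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))

  p <- cohort$persons[order(cohort$persons$person_id), , drop = FALSE]
  p <- data.frame(
    person_id = p$person_id,
    birth_date = fmt(p$birth_date),
    sex = p$sex,
    race = p$race,
    ethnicity = p$ethnicity,
    death_date = fmt(p$death_date),
    address_present = tolower(as.character(p$address_present)),
    stringsAsFactors = FALSE
  )
  ev <- cohort$events[order(cohort$events$person_id, cohort$events$event_date,
                            cohort$events$event_kind), , drop = FALSE]
  ev <- data.frame(
    person_id = ev$person_id, event_date = fmt(ev$event_date),
    event_kind = ev$event_kind, stringsAsFactors = FALSE
  )
  op <- cohort$observation_periods[
    order(cohort$observation_periods$person_id,
          cohort$observation_periods$start_date,
          cohort$observation_periods$end_date), , drop = FALSE]
  op <- data.frame(
    person_id = op$person_id, start_date = fmt(op$start_date),
    end_date = fmt(op$end_date), stringsAsFactors = FALSE
  )

  paths <- c(
    persons = file.path(out_dir, "persons.csv"),
    events = file.path(out_dir, "events.csv"),
    observation_periods = file.path(out_dir, "observation_periods.csv")
  )
  utils::write.csv(p, paths["persons"], row.names = FALSE, na = "")
  utils::write.csv(ev, paths["events"], row.names = FALSE, na = "")
  utils::write.csv(op, paths["observation_periods"], row.names = FALSE, na = "")
  jsonlite::write_json(
    list(reference_date = format(cohort$reference_date, "%Y-%m-%d"),
         n_patients = nrow(cohort$persons)),
    file.path(out_dir, "cohort_meta.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
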