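# The 19-filter data-completeness catalogue and its predicates.
# Every filter is a pure function Cohort -> set of surviving person_ids,
# always evaluated against the full baseline cohort (never chained).

#' Event kinds recognized by the schema
#' @return Character vector: diagnosis, medication, outpatient_visit.
#' @export
event_kinds <- function() c("diagnosis", "medication", "outpatient_visit")

#' The data-completeness filter catalogue
#'
#' Nineteen commonly used completeness filters in three categories:
#' nine demographics filters (vital status at the query date, recorded age
#' and sex, six age-at-diagnosis bounds, recorded address), three
#' medical-interaction filters (at least one diagnosis, medication, or
#' outpatient visit on record), and seven observation-period filters
#' (recorded observation period of at least 1 week up to 6 years).
#'
#' @return data.frame with columns `filter_id`, `category`, `label`, and the
#'   parameter columns `bound`, `direction`, `event_kind`, `min_days`
#'   (NA where not applicable), in canonical catalogue order.
#' @examples
#' nrow(filter_catalogue())          # 19
#' table(filter_catalogue()$category)
#' @export
filter_catalogue <- function() {
  data.frame(
    filter_id = c(
      "alive", "age_sex",
      "age_ge_18", "age_le_21", "age_le_40", "age_le_65", "age_ge_65", "age_le_80",
      "has_address",
      "has_diagnosis", "has_medication", "has_outpatient_visit",
      "obs_1w", "obs_2w", "obs_1m", "obs_6m", "obs_1y", "obs_2y", "obs_6y"
    ),
    category = c(
      rep("demographics", 9L),
      rep("medical_interactions", 3L),
      rep("observation_period", 7L)
    ),
    label = c(
      "Alive", "AgeSex",
      "Age filter >=18", "Age filter <=21", "Age filter <=40",
      "Age filter <=65", "Age filter >=65", "Age filter <=80",
      "Address or zip code",
      "Diagnosis", "Medication", "Outpatient visit",
      "Observation period 1 week", "Observation period 2 weeks",
      "Observation period 1 month", "Observation period 6 months",
      "Observation period 1 year", "Observation period 2 years",
      "Observation period 6 years"
    ),
    bound = c(NA, NA, 18, 21, 40, 65, 65, 80, rep(NA, 11L)),
    direction = c(NA, NA, "at_least", "at_most", "at_most", "at_most",
                  "at_least", "at_most", rep(NA, 11L)),
    event_kind = c(rep(NA, 9L), "diagnosis", "medication", "outpatient_visit",
                   rep(NA, 7L)),
    min_days = c(rep(NA, 12L), 7, 14, 30, 182, 365, 730, 2190),
    stringsAsFactors = FALSE
  )
}

#' Patients alive at the time of the query
#'
#' Survivors have no recorded death date, or a death date strictly after the
#' cohort's `reference_date`; a death recorded on the query date itself
#' counts as deceased.
#'
#' @param cohort An `ehr_cohort`.
#' @return Character vector of surviving person_ids.
#' @export
filter_alive <- function(cohort) {
  p <- cohort$persons
  p$person_id[is.na(p$death_date) | p$death_date > cohort$reference_date]
}

#' Patients with both sex and age recorded
#'
#' Requires a non-missing birth date (the age source) and non-missing sex.
#'
#' @param cohort An `ehr_cohort`.
#' @return Character vector of surviving person_ids.
#' @export
filter_age_sex <- function(cohort) {
  p <- cohort$persons
  p$person_id[!is.na(p$birth_date) & !is.na(p$sex)]
}

#' Patients with a diagnosis at an age satisfying an inclusive bound
#'
#' Age at each diagnosis event is computed as
#' `floor((event_date - birth_date) / 365.25)` whole years; a patient
#' survives if any diagnosis age satisfies the bound (`at_least` means
#' `age >= bound`, `at_most` means `age <= bound`, both inclusive — a
#' patient diagnosed at exactly 65 survives both the >=65 and the
#' <=65 filter). Patients with a missing birth date or no diagnosis
#' events never survive.
#'
#' @param cohort An `ehr_cohort`.
#' @param bound Age bound in whole years.
#' @param direction `"at_least"` or `"at_most"`.
#' @return Character vector of surviving person_ids.
#' @export
filter_age_at_diagnosis <- function(cohort, bound, direction = c("at_least", "at_most")) {
  direction <- match.arg(direction)
  ev <- cohort$events[cohort$events$event_kind == "diagnosis", , drop = FALSE]
  if (!nrow(ev)) return(character())
  bd <- cohort$persons$birth_date[match(ev$person_id, cohort$persons$person_id)]
  age <- floor(as.numeric(ev$event_date - bd) / 365.25)
  keep <- !is.na(age) & if (direction == "at_least") age >= bound else age <= bound
  unique(ev$person_id[keep])
}

#' Patients with an address or zip code recorded
#' @param cohort An `ehr_cohort`.
#' @return Character vector of surviving person_ids.
#' @export
filter_has_address <- function(cohort) {
  p <- cohort$persons
  p$person_id[p$address_present %in% TRUE]
}

#' Patients with at least one event of a given kind
#'
#' @param cohort An `ehr_cohort`.
#' @param kind `"diagnosis"`, `"medication"`, or `"outpatient_visit"`.
#' @return Character vector of surviving person_ids.
#' @export
filter_has_event <- function(cohort, kind) {
  if (!kind %in% event_kinds()) {
    stop("unknown event kind: ", kind, call. = FALSE)
  }
  unique(cohort$events$person_id[cohort$events$event_kind == kind])
}

#' Patients with a recorded observation period of a minimum span
#'
#' A period's span is `end_date - start_date` in days; a patient survives
#' when a recorded observation period is equal to or longer than `min_days`.
#' Under the default `rule = "longest"` each period is tested on its own
#' (the longest single period decides); `rule = "summed"` adds the spans of
#' all of a patient's periods first. Patients with no observation-period
#' record never survive.
#'
#' @param cohort An `ehr_cohort`.
#' @param min_days Minimum span in days (positive integer).
#' @param rule `"longest"` (default) or `"summed"`.
#' @return Character vector of surviving person_ids.
#' @export
filter_observation_period <- function(cohort, min_days, rule = c("longest", "summed")) {
  rule <- match.arg(rule)
  if (!is.numeric(min_days) || length(min_days) != 1L || min_days <= 0) {
    stop("min_days must be a positive number", call. = FALSE)
  }
  op <- cohort$observation_periods
  if (!nrow(op)) return(character())
  span <- as.numeric(op$end_date - op$start_date)
  if (rule == "longest") {
    unique(op$person_id[span >= min_days])
  } else {
    tot <- rowsum(span, op$person_id)
    rownames(tot)[tot[, 1] >= min_days]
  }
}

#' Apply a catalogue filter by id
#'
#' Dispatches a `filter_id` from [filter_catalogue()] to the matching
#' predicate and returns the surviving patient-id set. Filters are pure:
#' the same cohort always yields the same set, and the result is always a
#' subset of the cohort's person ids.
#'
#' @param cohort An `ehr_cohort`.
#' @param filter_id One of the 19 catalogue ids.
#' @param obs_rule Multiple-observation-period rule, see
#'   [filter_observation_period()].
#' @return Character vector of surviving person_ids.
#' @export
apply_filter <- function(cohort, filter_id, obs_rule = c("longest", "summed")) {
  obs_rule <- match.arg(obs_rule)
  cat <- filter_catalogue()
  i <- match(filter_id, cat$filter_id)
  if (is.na(i)) stop("unknown filter_id: ", filter_id, call. = FALSE)
  spec <- cat[i, ]
  if (filter_id == "alive") return(filter_alive(cohort))
  if (filter_id == "age_sex") return(filter_age_sex(cohort))
  if (filter_id == "has_address") return(filter_has_address(cohort))
  if (!is.na(spec$bound)) {
    return(filter_age_at_diagnosis(cohort, spec$bound, spec$direction))
  }
  if (!is.na(spec$event_kind)) return(filter_has_event(cohort, spec$event_kind))
  filter_observation_period(cohort, spec$min_days, obs_rule)
}
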