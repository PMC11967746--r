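# Seeded synthetic EHR cohorts with group-correlated data availability.
# Stands in for restricted clinical datasets: the marginals and element
# presence rates are configurable, and a planted differential-availability
# multiplier makes ground truth recoverable.

.synth_elements <- function() {
  c("sex", "birth_date", "address", "death",
    "diagnosis", "medication", "outpatient_visit", "observation_period")
}

#' Configuration for the synthetic EHR cohort generator
#'
#' Defaults describe a large urban academic medical center: race and
#' ethnicity marginals follow the published distribution of a four-million
#' patient hospital cohort, and the per-element presence probabilities are
#' anchored to that cohort's all-group availability under the corresponding
#' single filters (about 33% of patients with a medication record, 41% with
#' a diagnosis, 73% with an outpatient visit, 56% with any observation
#' period, 45% with an address on file).
#'
#' Group-wise bias is planted on the odds scale: element presence for a
#' patient in group g is `plogis(qlogis(base) + log(multiplier_g))`, which
#' keeps probabilities in range for any baseline. `group_multipliers` is a
#' named list: names are race or ethnicity categories, values are named
#' numeric vectors over the data elements
#' (`sex, birth_date, address, death, diagnosis, medication,
#' outpatient_visit, observation_period`).
#'
#' @param n_patients Number of patients.
#' @param race_probs Named probability vector over race categories
#'   (must sum to 1).
#' @param ethnicity_probs Named probability vector over ethnicity categories.
#' @param presence_probs Named baseline presence probabilities per data
#'   element.
#' @param group_multipliers Named list of per-group odds multipliers (see
#'   above); empty list means no planted bias.
#' @param age_mean,age_sd Age at the reference date, normal truncated at 0,
#'   in years.
#' @param event_rate Mean events per patient per kind (zero-truncated
#'   Poisson, conditioned on the element being present).
#' @param obs_log_mean,obs_log_sd Log-normal parameters of observation-period
#'   duration in days.
#' @param death_prob Probability of a recorded death before the reference
#'   date (subject to the `death` element multiplier).
#' @param reference_date The query date of the generated cohort.
#' @param seed Integer seed; a fixed seed yields byte-identical cohorts.
#' @param stratified_exact If TRUE, group sizes are fixed deterministically
#'   by largest-remainder rounding of the marginals instead of multinomial
#'   draws.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_patients = 10000,
    race_probs = c(
      "American Indian and/or Alaska Native" = 5695,
      "Asian" = 205978,
      "Black or African" = 373130,
      "Native Hawaiian or Pacific Islander" = 7082,
      "White" = 1992336,
      "Unknown" = 1447086
    ) / 4031307,
    ethnicity_probs = c(
      "Hispanic or Latino" = 344708,
      "Non-Hispanic or non-Latino" = 1691775,
      "Unknown" = 1994824
    ) / 4031307,
    presence_probs = c(
      sex = 0.9995, birth_date = 0.999, address = 0.454, death = 1,
      diagnosis = 0.413, medication = 0.327, outpatient_visit = 0.733,
      observation_period = 0.556
    ),
    group_multipliers = list(),
    age_mean = 45, age_sd = 20,
    event_rate = 2,
    obs_log_mean = 7.0, obs_log_sd = 1.5,
    death_prob = 0.0444,
    reference_date = as.Date("2024-06-01"),
    seed = 1L,
    stratified_exact = FALSE) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    race_probs = race_probs,
    ethnicity_probs = ethnicity_probs,
    presence_probs = presence_probs,
    group_multipliers = group_multipliers,
    age_mean = age_mean, age_sd = age_sd,
    event_rate = event_rate,
    obs_log_mean = obs_log_mean, obs_log_sd = obs_log_sd,
    death_prob = death_prob,
    reference_date = as.Date(reference_date),
    seed = as.integer(seed),
    stratified_exact = isTRUE(stratified_exact)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param cfg A `synthetic_config`.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_patients < 0) stop("n_patients must be non-negative", call. = FALSE)
  for (nm in c("race_probs", "ethnicity_probs")) {
    p <- cfg[[nm]]
    lv <- if (nm == "race_probs") race_levels() else ethnicity_levels()
    if (is.null(names(p)) || !all(names(p) %in% lv)) {
      stop(nm, " must be named with valid categories", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be non-negative and sum to 1 (within 1e-9)", call. = FALSE)
    }
  }
  pp <- cfg$presence_probs
  miss <- setdiff(.synth_elements(), names(pp))
  if (length(miss)) {
    stop("presence_probs missing element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(pp < 0 | pp > 1)) stop("presence_probs must lie in [0, 1]", call. = FALSE)
  if (cfg$death_prob < 0 || cfg$death_prob > 1) {
    stop("death_prob must lie in [0, 1]", call. = FALSE)
  }
  for (g in names(cfg$group_multipliers)) {
    if (!g %in% c(race_levels(), ethnicity_levels())) {
      stop("group_multipliers names a group outside the vocabularies: ", g,
           call. = FALSE)
    }
    mult <- cfg$group_multipliers[[g]]
    bad <- setdiff(names(mult), .synth_elements())
    if (length(bad)) {
      stop("group_multipliers for ", g, " names unknown element(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(mult <= 0)) stop("multipliers must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# largest-remainder apportionment of n across probability vector p
.apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# per-person presence probability for an element, multipliers applied on the
# odds scale for the person's race and ethnicity group
.element_prob <- function(cfg, element, race, ethnicity) {
  base <- if (element == "death") cfg$death_prob else cfg$presence_probs[[element]]
  if (base %in% c(0, 1) || !length(cfg$group_multipliers)) {
    return(rep(base, length(race)))
  }
  lo <- rep(stats::qlogis(base), length(race))
  for (g in names(cfg$group_multipliers)) {
    mult <- cfg$group_multipliers[[g]][element]
    if (is.na(mult)) next
    hit <- race == g | ethnicity == g
    lo[hit] <- lo[hit] + log(mult)
  }
  stats::plogis(lo)
}

# zero-truncated Poisson via inverse-CDF on a uniform above P(X = 0)
.rtpois <- function(n, lambda) {
  if (n == 0) return(integer())
  u <- stats::runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic EHR cohort
#'
#' Draws `n_patients` persons with race/ethnicity from the configured
#' marginals, plants group-wise availability bias on the odds scale, and
#' builds the person, event, and observation-period tables. Event counts are
#' zero-truncated Poisson conditioned on the element being present; event
#' dates are uniform between birth (or ten years before the reference date)
#' and the reference date; observation-period durations are log-normal;
#' ages are normal truncated at zero; recorded deaths are dated uniformly
#' within ten years before the reference date (clamped to birth). The whole
#' cohort is a deterministic function of the config, including its seed.
#'
#' @param config A [synthetic_config()].
#' @return A validated `ehr_cohort`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_patients
  ref <- config$reference_date
  if (n == 0) {
    return(new_cohort(
      persons = data.frame(
        person_id = character(), birth_date = as.Date(character()),
        sex = character(), race = character(), ethnicity = character(),
        death_date = as.Date(character()), address_present = logical(),
        stringsAsFactors = FALSE
      ),
      reference_date = ref
    ))
  }

  # sub-stream 1: person table
  set.seed(config$seed %% 2147483647L)
  ids <- sprintf("P%07d", seq_len(n))
  if (config$stratified_exact) {
    race <- rep(names(config$race_probs), .apportion(n, config$race_probs))
    eth_counts <- .apportion(n, config$ethnicity_probs)
    ethnicity <- rep(names(config$ethnicity_probs), eth_counts)
    # decouple the two stratifications so cells are not degenerate
    ethnicity <- ethnicity[sample.int(n)]
  } else {
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                        prob = config$ethnicity_probs)
  }

  age <- stats::qnorm(
    stats::runif(n, stats::pnorm(0, config$age_mean, config$age_sd), 1),
    config$age_mean, config$age_sd
  )
  birth <- ref - round(age * 365.25)
  has_birth <- stats::runif(n) < .element_prob(config, "birth_date", race, ethnicity)
  birth[!has_birth] <- NA

  sex <- sample(c("F", "M"), n, replace = TRUE)
  has_sex <- stats::runif(n) < .element_prob(config, "sex", race, ethnicity)
  sex[!has_sex] <- NA

  address <- stats::runif(n) < .element_prob(config, "address", race, ethnicity)

  died <- stats::runif(n) < .element_prob(config, "death", race, ethnicity)
  death_date <- rep(as.Date(NA), n)
  death_date[died] <- ref - floor(stats::runif(sum(died), 0, 3653))
  clamp <- died & !is.na(birth) & death_date < birth
  death_date[clamp] <- birth[clamp]

  persons <- data.frame(
    person_id = ids, birth_date = birth, sex = sex, race = race,
    ethnicity = ethnicity, death_date = death_date, address_present = address,
    stringsAsFactors = FALSE
  )

  # sub-stream 2: event tables
  set.seed((config$seed + 1000003L) %% 2147483647L)
  ev_list <- list()
  window_start <- pmax(birth, ref - 3652, na.rm = TRUE)
  for (kind in event_kinds()) {
    present <- stats::runif(n) < .element_prob(config, kind, race, ethnicity)
    idx <- which(present)
    if (!length(idx)) next
    counts <- .rtpois(length(idx), config$event_rate)
    pid <- rep(ids[idx], counts)
    span <- as.numeric(ref - window_start[idx])
    offs <- floor(stats::runif(sum(counts)) * rep(span + 1, counts))
    ev_list[[kind]] <- data.frame(
      person_id = pid,
      event_date = ref - offs,
      event_kind = kind,
      stringsAsFactors = FALSE
    )
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else empty_events()

  # sub-stream 3: observation periods
  set.seed((config$seed + 2000003L) %% 2147483647L)
  has_op <- stats::runif(n) < .element_prob(config, "observation_period", race, ethnicity)
  idx <- which(has_op)
  if (length(idx)) {
    dur <- pmax(1, round(stats::rlnorm(length(idx), config$obs_log_mean,
                                       config$obs_log_sd)))
    dur <- pmin(dur, 36525)  # cap at a century
    end <- ref - floor(stats::runif(length(idx)) * 30)
    obs <- data.frame(
      person_id = ids[idx],
      start_date = end - dur,
      end_date = end,
      stringsAsFactors = FALSE
    )
  } else {
    obs <- empty_observation_periods()
  }

  new_cohort(persons = persons, events = events, observation_periods = obs,
             reference_date = ref)
}

# filter_id -> data elements its survival depends on
.filter_dependencies <- function() {
  cat <- filter_catalogue()
  deps <- list(
    alive = "death",
    age_sex = c("sex", "birth_date"),
    has_address = "address",
    has_diagnosis = "diagnosis",
    has_medication = "medication",
    has_outpatient_visit = "outpatient_visit"
  )
  for (fid in cat$filter_id[!is.na(cat$bound)]) {
    deps[[fid]] <- c("birth_date", "diagnosis")
  }
  for (fid in cat$filter_id[!is.na(cat$min_days)]) {
    deps[[fid]] <- "observation_period"
  }
  deps[cat$filter_id]
}

#' Ground truth of a planted-bias configuration
#'
#' Derives, from the configured group multipliers and the filter-to-element
#' dependency map (alive depends on death recording; age filters on birth
#' date and diagnoses; the age/sex filter on sex and birth date; the address
#' and record filters on their own element; all observation-period filters
#' on observation-period presence), the set of (group, filter) pairs whose
#' survival probability differs from baseline — the pairs a correct audit
#' should flag.
#'
#' @param config A [synthetic_config()].
#' @return data.frame with columns `group` and `filter_id` (zero rows when
#'   no bias is planted), sorted canonically.
#' @export
planted_truth <- function(config) {
  validate_synthetic_config(config)
  deps <- .filter_dependencies()
  rows <- list()
  for (g in names(config$group_multipliers)) {
    mult <- config$group_multipliers[[g]]
    biased <- names(mult)[mult != 1]
    if (!length(biased)) next
    hit <- names(deps)[vapply(deps, function(d) any(d %in% biased), logical(1))]
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, filter_id = hit, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(group = character(), filter_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, match(out$filter_id, filter_catalogue()$filter_id)), ]
  rownames(out) <- NULL
  out
}
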