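# In-code fixtures: small hand-built cohorts used across the test files.

# a person row with sensible defaults, overridable per field
person_row <- function(person_id, birth_date = "1980-01-01", sex = "F",
                       race = "White", ethnicity = "Non-Hispanic or non-Latino",
                       death_date = NA, address_present = TRUE) {
  data.frame(
    person_id = person_id,
    birth_date = as.Date(birth_date),
    sex = sex,
    race = race,
    ethnicity = ethnicity,
    death_date = as.Date(death_date),
    address_present = address_present,
    stringsAsFactors = FALSE
  )
}

event_row <- function(person_id, event_date, event_kind = "diagnosis") {
  data.frame(
    person_id = person_id, event_date = as.Date(event_date),
    event_kind = event_kind, stringsAsFactors = FALSE
  )
}

obs_row <- function(person_id, start_date, end_date) {
  data.frame(
    person_id = person_id, start_date = as.Date(start_date),
    end_date = as.Date(end_date), stringsAsFactors = FALSE
  )
}

# five complete patients that pass every catalogue filter: two diagnoses
# each (one in early adulthood for the upper age bounds, one in old age for
# the >=65 bound), plus medication, visit, and a 6-year observation period
tiny_cohort <- function(reference_date = "2024-01-01") {
  persons <- do.call(rbind, lapply(1:5, function(i) {
    person_row(sprintf("P%02d", i), birth_date = sprintf("195%d-05-01", i))
  }))
  events <- do.call(rbind, lapply(1:5, function(i) {
    rbind(
      event_row(sprintf("P%02d", i), "1972-06-01", "diagnosis"),
      event_row(sprintf("P%02d", i), "2021-06-01", "diagnosis"),
      event_row(sprintf("P%02d", i), "2020-06-02", "medication"),
      event_row(sprintf("P%02d", i), "2020-06-03", "outpatient_visit")
    )
  }))
  obs <- do.call(rbind, lapply(1:5, function(i) {
    obs_row(sprintf("P%02d", i), "2015-01-01", "2023-01-01")
  }))
  new_cohort(persons, events, obs, reference_date = reference_date)
}

# independent brute-force oracle for the binomial lower tail:
# sum_{i=0..k} C(n,i) p^i (1-p)^(n-i), accumulated in log space
binom_lower_tail_oracle <- function(k, n, p) {
  if (p == 0) return(1)
  if (p == 1) return(if (k >= n) 1 else 0)
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# null-and-planted config used by the Monte-Carlo suites: four equal race
# groups and an ethnicity split, so each analyzed group has n_per_group
# expected members
mc_config <- function(n_per_group, seed, group_multipliers = list()) {
  synthetic_config(
    n_patients = 4L * n_per_group,
    race_probs = c(
      "Asian" = 0.25, "Black or African" = 0.25,
      "White" = 0.25, "Unknown" = 0.25
    ),
    ethnicity_probs = c(
      "Hispanic or Latino" = 0.25,
      "Non-Hispanic or non-Latino" = 0.5,
      "Unknown" = 0.25
    ),
    group_multipliers = group_multipliers,
    seed = seed
  )
}
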