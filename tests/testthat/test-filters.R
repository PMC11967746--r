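# The 19-filter catalogue: per-filter semantics, boundaries, and the
# nesting/coverage properties.

test_that("catalogue has 19 uniquely named filters partitioned 9/3/7", {
  cat <- filter_catalogue()
  expect_equal(nrow(cat), 19L)
  expect_false(any(duplicated(cat$filter_id)))
  counts <- table(cat$category)
  expect_equal(unname(counts[["demographics"]]), 9L)
  expect_equal(unname(counts[["medical_interactions"]]), 3L)
  expect_equal(unname(counts[["observation_period"]]), 7L)
})

test_that("alive filter keeps the undated and post-query deaths only", {
  persons <- rbind(
    person_row("alive_nodate"),
    person_row("died_before", death_date = "2023-12-31"),
    person_row("died_on_query", death_date = "2024-01-01"),
    person_row("died_after", death_date = "2024-02-01")
  )
  co <- new_cohort(persons, reference_date = "2024-01-01")
  expect_setequal(filter_alive(co), c("alive_nodate", "died_after"))

  empty <- generate_cohort(synthetic_config(n_patients = 0, seed = 1))
  expect_length(filter_alive(empty), 0L)
})

test_that("age/sex filter is the conjunction of recorded birth date and sex", {
  persons <- rbind(
    person_row("both"),
    person_row("no_sex", sex = NA),
    person_row("no_birth", birth_date = NA),
    person_row("neither", sex = NA, birth_date = NA),
    person_row("both2"),
    person_row("no_sex2", sex = NA)
  )
  co <- new_cohort(persons, reference_date = "2024-01-01")
  # brute-force truth table over the missingness combinations
  expected <- persons$person_id[!is.na(persons$birth_date) & !is.na(persons$sex)]
  expect_setequal(filter_age_sex(co), expected)
  expect_length(filter_age_sex(co), 2L)
})

test_that("age-at-diagnosis bounds are inclusive and need a diagnosis", {
  persons <- rbind(
    person_row("young", birth_date = "2000-01-01"),
    person_row("mid", birth_date = "1970-01-01"),
    person_row("exact65", birth_date = "1950-05-01"),
    person_row("nobirth", birth_date = NA),
    person_row("nodiag", birth_date = "1980-01-01")
  )
  events <- rbind(
    event_row("young", "2018-06-01"),    # age 18
    event_row("mid", "2015-06-01"),      # age 45
    event_row("exact65", "2015-06-01"),  # age 65 (65.08 years, floored)
    event_row("nobirth", "2015-06-01")
  )
  co <- new_cohort(persons, events, reference_date = "2024-01-01")

  expect_setequal(filter_age_at_diagnosis(co, 18, "at_least"),
                  c("young", "mid", "exact65"))
  expect_setequal(filter_age_at_diagnosis(co, 21, "at_most"), "young")
  expect_setequal(filter_age_at_diagnosis(co, 40, "at_most"), "young")
  expect_setequal(filter_age_at_diagnosis(co, 80, "at_most"),
                  c("young", "mid", "exact65"))
  # inclusive boundary: age exactly 65 passes both >=65 and <=65
  expect_true("exact65" %in% filter_age_at_diagnosis(co, 65, "at_least"))
  expect_true("exact65" %in% filter_age_at_diagnosis(co, 65, "at_most"))
  # no diagnosis or no birth date never survives
  expect_false(any(c("nodiag", "nobirth") %in%
                     filter_age_at_diagnosis(co, 18, "at_least")))
  expect_error(filter_age_at_diagnosis(co, 18, "sideways"), "arg")
})

test_that("address filter counts exactly the true flags", {
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  persons <- do.call(rbind, lapply(seq_along(flags), function(i) {
    person_row(sprintf("A%d", i), address_present = flags[i])
  }))
  co <- new_cohort(persons, reference_date = "2024-01-01")
  expect_length(filter_has_address(co), sum(flags))
  expect_setequal(filter_has_address(co), persons$person_id[flags])
})

test_that("record filters require at least one event of the kind, multiplicity ignored", {
  # event multiplicity 0..5 per patient; survival depends only on >= 1
  persons <- do.call(rbind, lapply(0:5, function(k) person_row(sprintf("M%d", k))))
  events <- do.call(rbind, lapply(1:5, function(k) {
    do.call(rbind, lapply(seq_len(k), function(j) {
      event_row(sprintf("M%d", k), "2020-01-01", "medication")
    }))
  }))
  co <- new_cohort(persons, events, reference_date = "2024-01-01")
  expect_setequal(filter_has_event(co, "medication"), sprintf("M%d", 1:5))
  expect_length(filter_has_event(co, "diagnosis"), 0L)
  expect_length(filter_has_event(co, "outpatient_visit"), 0L)
  expect_error(filter_has_event(co, "lab"), "unknown event kind")
})

test_that("observation-period span is end minus start, equal-or-longer survives", {
  persons <- rbind(person_row("week"), person_row("short"), person_row("none"),
                   person_row("split"))
  obs <- rbind(
    obs_row("week", "2020-01-01", "2020-01-08"),   # exactly 7 days
    obs_row("short", "2020-01-01", "2020-01-07"),  # 6 days
    obs_row("split", "2020-01-01", "2020-04-10"),  # 100 days
    obs_row("split", "2021-01-01", "2021-10-28")   # 300 days
  )
  co <- new_cohort(persons, observation_periods = obs, reference_date = "2024-01-01")
  expect_setequal(filter_observation_period(co, 7), c("week", "split"))
  expect_false("none" %in% filter_observation_period(co, 7))
  # longest single period rule: 100 and 300 days do not add up to 365
  expect_length(filter_observation_period(co, 365, rule = "longest"), 0L)
  expect_setequal(filter_observation_period(co, 365, rule = "summed"), "split")
  expect_error(filter_observation_period(co, 0), "positive")
})

test_that("every filter returns a subset of the cohort and is pure", {
  cfg <- synthetic_config(n_patients = 500, seed = 33)
  co <- generate_cohort(cfg)
  ids <- co$persons$person_id
  for (fid in filter_catalogue()$filter_id) {
    s1 <- apply_filter(co, fid)
    s2 <- apply_filter(co, fid)
    expect_true(all(s1 %in% ids), info = fid)
    expect_identical(sort(s1), sort(s2), info = fid)
    expect_false(any(duplicated(s1)), info = fid)
  }
  expect_error(apply_filter(co, "no_such_filter"), "unknown filter_id")
})

test_that("observation-period and age filters nest, and the age coverage identity holds", {
  for (seed in c(101, 102, 103)) {
    co <- generate_cohort(synthetic_config(n_patients = 800, seed = seed))
    # obs filters nested by span
    spans <- c(7, 14, 30, 182, 365, 730, 2190)
    surv <- lapply(spans, function(d) filter_observation_period(co, d))
    for (i in seq_len(length(spans) - 1)) {
      expect_true(all(surv[[i + 1]] %in% surv[[i]]),
                  info = sprintf("seed %d span %d", seed, spans[i + 1]))
    }
    # age upper bounds nested
    ub <- lapply(c(21, 40, 65, 80), function(b) filter_age_at_diagnosis(co, b, "at_most"))
    for (i in 1:3) expect_true(all(ub[[i]] %in% ub[[i + 1]]))
    # coverage: every diagnosis age is >= 18 or <= 21, so the union is the
    # diagnosed-with-birth-date set
    ge18 <- filter_age_at_diagnosis(co, 18, "at_least")
    le21 <- filter_age_at_diagnosis(co, 21, "at_most")
    diag_birth <- intersect(
      filter_has_event(co, "diagnosis"),
      co$persons$person_id[!is.na(co$persons$birth_date)]
    )
    expect_setequal(union(ge18, le21), diag_birth)
  }
})
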