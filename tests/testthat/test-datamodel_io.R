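# Schema, validation, round-trip io, and UK-to-US race harmonization.

test_that("well-formed files load into a cohort and round-trip identically", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(
    file.path(dir, "persons.csv"),
    file.path(dir, "events.csv"),
    file.path(dir, "observation_periods.csv")
  )
  expect_equal(n_patients(back), 5L)
  expect_equal(back$reference_date, co$reference_date)

  # write -> load -> write must be byte-identical (canonical order, ISO dates)
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  for (f in c("persons.csv", "events.csv", "observation_periods.csv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("a generated cohort survives a field-by-field round trip", {
  cfg <- synthetic_config(n_patients = 1000, seed = 11)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(
    file.path(dir, "persons.csv"),
    file.path(dir, "events.csv"),
    file.path(dir, "observation_periods.csv")
  )
  ord <- function(d, cols) {
    d <- d[do.call(order, d[cols]), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back$persons, "person_id"), ord(co$persons, "person_id"))
  expect_equal(
    ord(back$events, c("person_id", "event_date", "event_kind")),
    ord(co$events, c("person_id", "event_date", "event_kind"))
  )
  expect_equal(
    ord(back$observation_periods, c("person_id", "start_date", "end_date")),
    ord(co$observation_periods, c("person_id", "start_date", "end_date"))
  )
  expect_equal(back$reference_date, co$reference_date)
})

test_that("an empty cohort writes header-only files and loads back", {
  co <- generate_cohort(synthetic_config(n_patients = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  for (f in c("persons.csv", "events.csv", "observation_periods.csv")) {
    expect_length(readLines(file.path(dir, f)), 1L)
  }
  back <- load_cohort(
    file.path(dir, "persons.csv"),
    file.path(dir, "events.csv"),
    file.path(dir, "observation_periods.csv")
  )
  expect_equal(n_patients(back), 0L)
})

test_that("schema and integrity violations are rejected with named offenders", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)

  # drop the race column
  p <- utils::read.csv(file.path(dir, "persons.csv"), colClasses = "character")
  utils::write.csv(p[setdiff(names(p), "race")],
                   file.path(dir, "persons_norace.csv"), row.names = FALSE)
  expect_error(
    load_cohort(file.path(dir, "persons_norace.csv"),
                file.path(dir, "events.csv"),
                file.path(dir, "observation_periods.csv")),
    "race"
  )

  # event table referencing a person absent from the person table
  ev <- utils::read.csv(file.path(dir, "events.csv"), colClasses = "character")
  ev$person_id[1] <- "P99"
  utils::write.csv(ev, file.path(dir, "events_bad.csv"), row.names = FALSE)
  expect_error(
    load_cohort(file.path(dir, "persons.csv"),
                file.path(dir, "events_bad.csv"),
                file.path(dir, "observation_periods.csv")),
    "P99"
  )

  # duplicated person_id
  p2 <- utils::read.csv(file.path(dir, "persons.csv"), colClasses = "character")
  p2$person_id[2] <- p2$person_id[1]
  utils::write.csv(p2, file.path(dir, "persons_dup.csv"), row.names = FALSE)
  expect_error(
    load_cohort(file.path(dir, "persons_dup.csv"),
                file.path(dir, "events.csv"),
                file.path(dir, "observation_periods.csv")),
    "duplicate"
  )
})

test_that("out-of-vocabulary race and ethnicity strings map to Unknown with a message", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  p <- utils::read.csv(file.path(dir, "persons.csv"), colClasses = "character")
  p$race[1] <- "Martian"
  p$ethnicity[2] <- ""
  utils::write.csv(p, file.path(dir, "persons.csv"), row.names = FALSE)
  expect_message(
    back <- load_cohort(file.path(dir, "persons.csv"),
                        file.path(dir, "events.csv"),
                        file.path(dir, "observation_periods.csv")),
    "Unknown"
  )
  b <- back$persons[order(back$persons$person_id), ]
  expect_equal(b$race[1], "Unknown")
  expect_equal(b$ethnicity[2], "Unknown")
})

test_that("UK ethnic-background labels harmonize per the government grouping", {
  expect_equal(harmonize_ukbb_race("Caribbean"), "Black or African")
  expect_equal(harmonize_ukbb_race("white and Asian"), "Mixed")
  expect_equal(harmonize_ukbb_race("prefer not to answer"), "Unknown")
  expect_equal(harmonize_ukbb_race("Chinese"), "Asian")
  expect_equal(harmonize_ukbb_race("other ethnic group"), "Other")
  expect_equal(harmonize_ukbb_race("British"), "White")

  # case/whitespace-insensitive and total
  expect_equal(harmonize_ukbb_race("  BLACK or black BRITISH "), "Black or African")
  expect_warning(out <- harmonize_ukbb_race("klingon"), "Unknown")
  expect_equal(out, "Unknown")

  # idempotent on its own outputs
  uk <- c("Caribbean", "Bangladeshi", "Irish", "mixed", "do not know",
          "other ethnic group", "any other white background")
  once <- harmonize_ukbb_race(uk)
  expect_equal(harmonize_ukbb_race(once), once)
  expect_true(all(once %in% race_levels()))
})

test_that("ukbb_mode harmonizes race on load and sets ethnicity Unknown", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  p <- utils::read.csv(file.path(dir, "persons.csv"), colClasses = "character")
  p$race <- c("British", "Caribbean", "Pakistani", "white and Black African",
              "prefer not to answer")
  utils::write.csv(p, file.path(dir, "persons.csv"), row.names = FALSE)
  back <- load_cohort(file.path(dir, "persons.csv"),
                      file.path(dir, "events.csv"),
                      file.path(dir, "observation_periods.csv"),
                      config = list(ukbb_mode = TRUE))
  b <- back$persons[order(back$persons$person_id), ]
  expect_equal(b$race, c("White", "Black or African", "Asian", "Mixed", "Unknown"))
  expect_true(all(b$ethnicity == "Unknown"))
})

test_that("invariant violations inside the tables are caught", {
  expect_error(
    new_cohort(person_row("A", birth_date = "2000-01-01", death_date = "1990-01-01")),
    "death_date"
  )
  expect_error(
    new_cohort(person_row("A"), observation_periods = obs_row("A", "2020-02-01", "2020-01-01")),
    "end_date"
  )
  expect_error(
    new_cohort(rbind(person_row("A"), person_row("A"))),
    "duplicate"
  )
})
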