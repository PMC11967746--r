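# Drop-off curve data and publication-style output tables.

#' Build drop-off curve data from an availability table
#'
#' For each grouping, orders the filters by descending all-group remaining
#' percentage (ties broken by catalogue order) and lays out each group's
#' remaining percentage along that order — the data behind the usual
#' availability drop-off plot. Values are taken verbatim from the
#' availability table; the curve applies no interpolation or smoothing, and
#' the filters remain non-cumulative.
#'
#' @param table Availability table from [run_audit()].
#' @return A `dropoff_curve` list with one element per grouping present
#'   (`race`, `ethnicity`), each holding `filter_order` (character vector)
#'   and `series` (named list mapping group — including `all` — to the
#'   percentage at each filter, in `filter_order`).
#' @export
build_dropoff <- function(table) {
  allrows <- table[table$grouping == "all", , drop = FALSE]
  if (!nrow(allrows)) {
    stop("availability table has no 'all' group rows", call. = FALSE)
  }
  ord <- order(-allrows$remaining_pct,
               match(allrows$filter_id, filter_catalogue()$filter_id))
  filter_order <- allrows$filter_id[ord]

  out <- list()
  for (grouping in c("race", "ethnicity")) {
    sub <- table[table$grouping == grouping, , drop = FALSE]
    if (!nrow(sub)) next
    series <- list(all = allrows$remaining_pct[ord])
    for (g in unique(sub$group)) {
      gg <- sub[sub$group == g, , drop = FALSE]
      series[[g]] <- gg$remaining_pct[match(filter_order, gg$filter_id)]
    }
    out[[grouping]] <- list(filter_order = filter_order, series = series)
  }
  structure(out, class = "dropoff_curve")
}

#' Write audit and bias-test outputs to a directory
#'
#' Emits the long availability table (`availability.csv`), the wide
#' race and ethnicity layouts (`availability_wide_race.csv`,
#' `availability_wide_ethnicity.csv`), the bias-test table
#' (`bias_tests.csv`, p-values in scientific notation at six significant
#' digits), the drop-off curve (`dropoff.json`), and a cohort summary
#' (`summary.json`).
#'
#' @param table Availability table from [run_audit()].
#' @param tests Optional bias-test table from [run_bias_tests()].
#' @param out_dir Output directory (created if absent).
#' @param cohort Optional `ehr_cohort`, for the summary metadata.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(table, tests = NULL, out_dir, cohort = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()

  p <- file.path(out_dir, "availability.csv")
  tab <- as.data.frame(table)
  tab$remaining_pct <- sprintf("%.2f", tab$remaining_pct)
  utils::write.csv(tab, p, row.names = FALSE)
  paths <- c(paths, p)

  for (grouping in c("race", "ethnicity")) {
    if (!any(table$grouping == grouping)) next
    p <- file.path(out_dir, sprintf("availability_wide_%s.csv", grouping))
    wide <- availability_wide(table, grouping)
    pctcols <- grepl("_pct$", names(wide))
    wide[pctcols] <- lapply(wide[pctcols], function(x) sprintf("%.2f", x))
    utils::write.csv(wide, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(tests)) {
    p <- file.path(out_dir, "bias_tests.csv")
    tt <- as.data.frame(tests)
    fmt_p <- function(x) ifelse(is.na(x), "", formatC(x, format = "e", digits = 5))
    tt$p_raw <- fmt_p(tt$p_raw)
    tt$p_adj <- fmt_p(tt$p_adj)
    tt$observed_prop <- ifelse(is.na(tt$observed_prop), "",
                               formatC(tt$observed_prop, format = "e", digits = 5))
    tt$expected_prop <- ifelse(is.na(tt$expected_prop), "",
                               formatC(tt$expected_prop, format = "e", digits = 5))
    utils::write.csv(tt, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "dropoff.json")
  jsonlite::write_json(unclass(build_dropoff(table)), p,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)

  summ <- list(
    n_filters = length(unique(table$filter_id)),
    groups = lapply(
      split(table[table$filter_id == table$filter_id[1], , drop = FALSE],
            table$grouping[table$filter_id == table$filter_id[1]]),
      function(d) stats::setNames(as.list(d$baseline_n), d$group)
    )
  )
  if (!is.null(cohort)) {
    summ$n_patients <- n_patients(cohort)
    summ$reference_date <- format(cohort$reference_date, "%Y-%m-%d")
  }
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)

  invisible(paths)
}
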