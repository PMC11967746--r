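# Non-cumulative availability audit: each filter is applied to the full
# baseline cohort on its own, and remaining counts are tabulated per race
# group, per ethnicity group, and for the "all" baseline.

#' Percentage of baseline remaining, at print precision
#'
#' `100 * remaining_n / baseline_n`, rounded to two decimals with ties going
#' half away from zero — the convention used for all reported availability
#' percentages.
#'
#' @param remaining_n Count of patients surviving a filter (vectorized).
#' @param baseline_n Count of patients before filtering.
#' @return Numeric percentage(s) in `[0, 100]`, two-decimal precision.
#' @examples
#' percent_remaining(1992336, 4031307)  # 49.42
#' @export
percent_remaining <- function(remaining_n, baseline_n) {
  if (any(baseline_n == 0)) {
    stop("baseline_n must be positive (undefined denominator)", call. = FALSE)
  }
  if (any(remaining_n < 0 | remaining_n > baseline_n)) {
    stop("remaining_n must lie in [0, baseline_n]", call. = FALSE)
  }
  x <- 100 * remaining_n / baseline_n
  # round half away from zero (base round() is half-to-even)
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

#' Audit per-group data availability under each filter
#'
#' Applies each catalogue filter independently to the full cohort — filters
#' are never chained, so every row reads against the same baseline — and
#' tabulates, for every race group, every ethnicity group, and the `all`
#' group (every patient, including Unknown/Other/Mixed), the number and
#' percentage of patients remaining.
#'
#' @param cohort An `ehr_cohort`.
#' @param specs Filter ids to audit; defaults to the full 19-filter
#'   catalogue. May also be the data.frame returned by [filter_catalogue()]
#'   (its `filter_id` column is used).
#' @param obs_rule Multiple-observation-period rule, see
#'   [filter_observation_period()].
#' @return An availability table: data.frame with columns `grouping`
#'   (`"all"`, `"race"`, `"ethnicity"`), `group`, `filter_id`, `baseline_n`,
#'   `remaining_n`, `remaining_pct`, in canonical (grouping, group, filter)
#'   order. Groups with `baseline_n = 0` are omitted.
#' @export
run_audit <- function(cohort, specs = filter_catalogue(), obs_rule = c("longest", "summed")) {
  obs_rule <- match.arg(obs_rule)
  validate_cohort(cohort)
  if (is.data.frame(specs)) specs <- specs$filter_id
  if (!length(specs)) stop("specs must name at least one filter", call. = FALSE)
  unknown <- setdiff(specs, filter_catalogue()$filter_id)
  if (length(unknown)) {
    stop("unknown filter_id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  p <- cohort$persons
  race <- factor(p$race, levels = race_levels())
  eth <- factor(p$ethnicity, levels = ethnicity_levels())
  base_race <- table(race)
  base_eth <- table(eth)
  n_all <- nrow(p)

  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    fid <- specs[k]
    surv <- apply_filter(cohort, fid, obs_rule)
    in_surv <- p$person_id %in% surv
    rem_race <- table(race[in_surv])
    rem_eth <- table(eth[in_surv])
    rows[[k]] <- rbind(
      data.frame(
        grouping = "all", group = "all", filter_id = fid,
        baseline_n = n_all, remaining_n = sum(in_surv),
        stringsAsFactors = FALSE
      ),
      data.frame(
        grouping = "race", group = names(base_race), filter_id = fid,
        baseline_n = as.integer(base_race), remaining_n = as.integer(rem_race),
        stringsAsFactors = FALSE
      ),
      data.frame(
        grouping = "ethnicity", group = names(base_eth), filter_id = fid,
        baseline_n = as.integer(base_eth), remaining_n = as.integer(rem_eth),
        stringsAsFactors = FALSE
      )
    )
  }
  out <- do.call(rbind, rows)
  out <- out[out$baseline_n > 0, , drop = FALSE]
  out$remaining_pct <- percent_remaining(out$remaining_n, out$baseline_n)

  # canonical order: grouping, group (vocabulary order), catalogue filter order
  grp_order <- c("all", race_levels(), ethnicity_levels())
  out <- out[order(
    match(out$grouping, c("all", "race", "ethnicity")),
    match(out$group, grp_order),
    match(out$filter_id, filter_catalogue()$filter_id)
  ), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("availability_table", "data.frame")
  out
}

#' Reshape an availability table to the wide publication layout
#'
#' One row per filter, one `<group> (n)` / `<group> (%)` column pair per
#' group, mirroring the printed percentage-remaining tables.
#'
#' @param table An availability table from [run_audit()].
#' @param grouping `"race"` or `"ethnicity"`; the `all` column is always
#'   included first.
#' @return A wide data.frame, filters as rows.
#' @export
availability_wide <- function(table, grouping = c("race", "ethnicity")) {
  grouping <- match.arg(grouping)
  sub <- table[table$grouping %in% c("all", grouping), , drop = FALSE]
  groups <- unique(sub$group)
  fids <- unique(sub$filter_id)
  out <- data.frame(filter_id = fids, stringsAsFactors = FALSE)
  for (g in groups) {
    gg <- sub[sub$group == g, , drop = FALSE]
    i <- match(fids, gg$filter_id)
    out[[paste0(g, "_n")]] <- gg$remaining_n[i]
    out[[paste0(g, "_pct")]] <- gg$remaining_pct[i]
  }
  out
}
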