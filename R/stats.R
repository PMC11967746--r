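# Binomial observed-vs-expected bias test with Bonferroni correction.
#
# For a group g and baseline group w (White by default for race), a filter's
# survivors define an observed proportion k_g / (k_g + k_w); the pre-filter
# group sizes define the expected proportion n_g / (n_g + n_w). A low
# one-sided (less) binomial p-value flags the group as disproportionately
# excluded by that filter relative to the baseline.

#' Observed proportion of a group among filter survivors
#'
#' The group's share among survivors of the group plus the baseline group:
#' `filtered_group_n / (filtered_group_n + filtered_baseline_n)`.
#'
#' @param filtered_group_n Group survivors of the filter.
#' @param filtered_baseline_n Baseline-group survivors of the filter.
#' @return Proportion in `[0, 1]`; `NA` when both counts are zero (the test
#'   is undefined, not an error).
#' @export
observed_proportion <- function(filtered_group_n, filtered_baseline_n) {
  tot <- filtered_group_n + filtered_baseline_n
  ifelse(tot > 0, filtered_group_n / tot, NA_real_)
}

#' Expected proportion of a group before filtering
#'
#' The group's pre-filter share of the group plus the baseline group:
#' `group_total_n / (group_total_n + baseline_total_n)`.
#'
#' @param group_total_n Pre-filter group size.
#' @param baseline_total_n Pre-filter baseline-group size.
#' @return Proportion in `[0, 1]`; `NA` when both totals are zero.
#' @export
expected_proportion <- function(group_total_n, baseline_total_n) {
  tot <- group_total_n + baseline_total_n
  ifelse(tot > 0, group_total_n / tot, NA_real_)
}

#' Binomial test of a group's representation among filter survivors
#'
#' Treats the `filtered_group_n` group members among the
#' `filtered_group_n + filtered_baseline_n` survivors as binomial draws at
#' the pre-filter success probability `expected_prop`, and returns the tail
#' p-value. The default alternative `"less"` asks whether the group is
#' under-represented among survivors — i.e. more affected by the filter than
#' the baseline group. `"two_sided"` uses the doubled smaller tail, capped
#' at 1.
#'
#' The cumulative probability is computed exactly (via the binomial CDF) up
#' to `max_exact` trials; above that a normal approximation with continuity
#' correction is used.
#'
#' @param filtered_group_n Group survivors (successes).
#' @param filtered_baseline_n Baseline-group survivors.
#' @param expected_prop Null success probability in `[0, 1]`.
#' @param alternative `"less"` (default) or `"two_sided"`.
#' @param max_exact Trials threshold above which the normal approximation is
#'   used (default 1e7).
#' @return p-value in `(0, 1]`, or `NA` when there are zero trials.
#' @export
binomial_bias_test <- function(filtered_group_n, filtered_baseline_n,
                               expected_prop,
                               alternative = c("less", "two_sided"),
                               max_exact = 1e7) {
  alternative <- match.arg(alternative)
  if (is.na(expected_prop) || expected_prop < 0 || expected_prop > 1) {
    stop("expected_prop must lie in [0, 1]", call. = FALSE)
  }
  k <- filtered_group_n
  n <- filtered_group_n + filtered_baseline_n
  if (n == 0) return(NA_real_)

  lower <- .binom_cdf(k, n, expected_prop, max_exact)
  if (alternative == "less") return(lower)
  upper <- if (k == 0) 1 else 1 - .binom_cdf(k - 1, n, expected_prop, max_exact)
  min(1, 2 * min(lower, upper))
}

# P(X <= k) for X ~ Binomial(n, p); exact for n <= max_exact, else normal
# approximation with continuity correction.
.binom_cdf <- function(k, n, p, max_exact) {
  if (p == 0) return(1)
  if (p == 1) return(if (k >= n) 1 else 0)
  if (n <= max_exact) {
    stats::pbinom(k, n, p)
  } else {
    stats::pnorm((k + 0.5 - n * p) / sqrt(n * p * (1 - p)))
  }
}

#' Bonferroni adjustment with an explicit family size
#'
#' Maps each raw p-value to `min(1, m * p)`, preserving order. The family
#' size `m` is passed explicitly because one audit run emits tests across
#' both groupings and all filters; `m` may exceed `length(p_values)` when a
#' subset is adjusted against the full family.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]` (NA passed
#'   through).
#' @param m Family size, at least 1 and at least the number of tests.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("family size m must be a number >= 1", call. = FALSE)
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < sum(ok)) {
    stop("family size m must be at least the number of tests", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Run the bias tests for every non-baseline group and filter
#'
#' For each filter in an availability table and each race group other than
#' `baseline_race` (and each ethnicity group other than
#' `baseline_ethnicity`), computes the observed and expected proportions
#' against the baseline group, the binomial p-value, and its Bonferroni
#' adjustment over the whole family of tests emitted for the cohort.
#' Baseline groups themselves are never tested. Tests with zero survivors in
#' both the group and the baseline are reported as not-applicable (`NA`
#' p-values) and excluded from the family size `m`.
#'
#' @param table Availability table from [run_audit()].
#' @param baseline_race Race baseline group (default `"White"`).
#' @param baseline_ethnicity Ethnicity baseline group (default
#'   `"Non-Hispanic or non-Latino"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param alternative Test sidedness, see [binomial_bias_test()].
#' @param max_exact Exact-computation threshold, see [binomial_bias_test()].
#' @return data.frame with one row per (grouping, group, filter): the four
#'   counts, `observed_prop`, `expected_prop`, `p_raw`, `p_adj`, `m`, and
#'   `significant` (`p_adj < alpha`).
#' @export
run_bias_tests <- function(table,
                           baseline_race = "White",
                           baseline_ethnicity = "Non-Hispanic or non-Latino",
                           alpha = 0.05,
                           alternative = c("less", "two_sided"),
                           max_exact = 1e7) {
  alternative <- match.arg(alternative)
  baselines <- c(race = baseline_race, ethnicity = baseline_ethnicity)

  rows <- list()
  for (grouping in c("race", "ethnicity")) {
    sub <- table[table$grouping == grouping, , drop = FALSE]
    if (!nrow(sub)) next
    bl <- baselines[[grouping]]
    blsub <- sub[sub$group == bl, , drop = FALSE]
    if (!nrow(blsub)) {
      stop(sprintf("baseline %s group '%s' absent from the availability table",
                   grouping, bl), call. = FALSE)
    }
    for (g in setdiff(unique(sub$group), bl)) {
      gsub <- sub[sub$group == g, , drop = FALSE]
      i <- match(gsub$filter_id, blsub$filter_id)
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = grouping, group = g, filter_id = gsub$filter_id,
        filtered_group_n = gsub$remaining_n,
        filtered_baseline_n = blsub$remaining_n[i],
        group_total_n = gsub$baseline_n,
        baseline_total_n = blsub$baseline_n[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    stop("availability table contains no race or ethnicity rows", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$observed_prop <- observed_proportion(out$filtered_group_n, out$filtered_baseline_n)
  out$expected_prop <- expected_proportion(out$group_total_n, out$baseline_total_n)
  out$p_raw <- mapply(function(k, b, e) {
    if (is.na(e) || (k + b) == 0) NA_real_
    else binomial_bias_test(k, b, e, alternative, max_exact)
  }, out$filtered_group_n, out$filtered_baseline_n, out$expected_prop)

  m <- sum(!is.na(out$p_raw))
  out$p_adj <- bonferroni_adjust(out$p_raw, max(m, 1L))
  out$m <- m
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  class(out) <- c("bias_test_result", "data.frame")
  out
}
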