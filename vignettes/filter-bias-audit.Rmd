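---
title: "Auditing race and ethnicity bias of EHR data-completeness filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing race and ethnicity bias of EHR data-completeness filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortbias)
```

## The problem

Observational research on electronic health records (EHRs) almost always
starts by filtering the raw patient population for "complete" data:
patients with a recorded sex and age, a known address, at least one
diagnosis, medication, or outpatient visit, or a minimum observation
period. These completeness filters are sensible individually, but the
availability of each data element is not uniform across the population.
Patients with less access to, or less frequent contact with, the health
system — disproportionately members of minoritized racial and ethnic
groups — carry sparser records, so a completeness filter can silently and
systematically shift the racial and ethnic composition of the study
cohort before any analysis begins.

`cohortbias` implements the audit that makes this shift visible and
testable:

1. apply each filter in a fixed 19-filter catalogue to the **full**
   cohort, one at a time (never chained);
2. tabulate, per self-reported race group, per ethnicity group, and for
   the `all` baseline (every patient, including Unknown/Other/Mixed), the
   number and percentage of patients remaining;
3. test, for every non-baseline group and every filter, whether the group
   is under-represented among the filter's survivors relative to a
   baseline group, with an exact binomial test and Bonferroni correction.

Because real multi-million-patient EHR extracts are governed by IRB and
data-access restrictions, the package also ships a seeded synthetic
cohort generator with *planted*, recoverable group-wise availability
bias, so the whole pipeline can be validated against known ground truth.

## The filter catalogue

The 19 filters fall into three categories (9 demographics, 3 medical
interactions, 7 observation periods):

```{r}
filter_catalogue()[, c("filter_id", "category", "label")]
```

Three semantic choices deserve explanation, because the audit's counts
depend on them:

* **Age arithmetic.** Age at a diagnosis is
  `floor((event_date - birth_date) / 365.25)` whole years. This is
  deterministic, leap-year-robust, and locale-independent. All six age
  bounds are inclusive: a patient diagnosed at exactly 65 satisfies both
  the `>=65` and the `<=65` filter. A patient with no diagnosis, or with
  a missing birth date, never survives an age filter — missingness is the
  phenomenon under study, so it excludes rather than errors.
* **Vital status.** "Alive at the time of the query" requires the death
  date to be strictly after the cohort's `reference_date`; a death
  recorded on the query date counts as deceased, since a recorded death
  at query time is evidence of non-survival.
* **Observation periods.** The calendar labels are fixed day counts
  (week = 7, 2 weeks = 14, month = 30, 6 months = 182, year = 365,
  2 years = 730, 6 years = 2190), a span is `end_date - start_date` in
  days, and "equal or longer" is inclusive (a 2020-01-01 to 2020-01-08
  period passes the 1-week filter). When a patient has several periods,
  the default tests the *longest single period*; summing all periods is
  available via `obs_rule = "summed"` because both conventions exist in
  practice and published descriptions rarely say which was used.

Useful consequences of these definitions, which the test suite checks as
properties: observation-period filters are nested by span, the age
upper-bound filters are nested by bound, and the union of the `>=18` and
`<=21` survivors is exactly the set of diagnosed patients with a birth
date (every integer age is `>=18` or `<=21`).

## The audit and the bias statistic

`run_audit()` evaluates every filter against the full baseline and
reports `remaining_n` and
`remaining_pct = 100 * remaining_n / baseline_n`, rounded to two decimals
with ties going half away from zero (the convention of published
demographic tables). Counts are additive by construction: within any
filter, the race-group remaining counts sum to the `all` remaining count,
and likewise for ethnicity.

For a group $g$ with pre-filter size $n_g$ and a baseline group $w$
(White by default for race, non-Hispanic/non-Latino for ethnicity), let
$k_g$ and $k_w$ be the numbers of survivors of a filter. The audit
compares

$$
\hat p_{\mathrm{obs}} = \frac{k_g}{k_g + k_w}
\qquad\text{against}\qquad
p_{\mathrm{exp}} = \frac{n_g}{n_g + n_w},
$$

treating $k_g$ as a binomial draw with $k_g + k_w$ trials at success
probability $p_{\mathrm{exp}}$. The default alternative is one-sided
(`less`): a small p-value means the group is under-represented among the
survivors, i.e. *more affected by the filter* than the baseline group.
The two-sided variant (doubled smaller tail, capped at 1) is available
via `alternative = "two_sided"`, since sidedness is a reporting choice.

Under the null of equal survival probability, the conditional law of
$k_g$ given $k_g + k_w$ is hypergeometric, whose variance is smaller than
the binomial's; the binomial reference is therefore slightly
conservative, which the type-I-error simulations below confirm.

Numerical choices:

* The binomial tail is computed through the exact CDF (`pbinom`, an
  incomplete-beta evaluation that is stable in the far tail) up to a
  configurable `max_exact = 1e7` trials; beyond that a normal
  approximation with continuity correction takes over. Group sizes in the
  millions are thus still handled exactly by default.
* Degenerate tests (zero survivors in group *and* baseline) are reported
  as not-applicable (`NA`) rather than crashing, and are excluded from
  the correction family.
* Bonferroni uses an explicit family size `m` — all applicable tests
  emitted for one cohort run, both groupings times all filters — and maps
  each p to `min(1, m * p)`. The family is per cohort because that is the
  set of simultaneous claims one audit report makes.
* `alpha = 0.05` by default; `significant` means `p_adj < alpha`.

## What the synthetic generator emulates

`synthetic_config()` describes a cohort by race/ethnicity marginals, a
baseline presence probability per data element (sex, birth date, address,
death recording, diagnosis, medication, outpatient visit, observation
period), event-count and duration distributions, and optional per-group
odds multipliers. The defaults portray a large urban academic medical
center: the race and ethnicity marginals follow the published
demographics of a four-million-patient hospital cohort (49.4% White,
9.3% Black or African, 5.1% Asian, 35.9% Unknown race; 49.5% unknown
ethnicity), and the element presence rates are anchored to that cohort's
published all-group availability under the corresponding single filters
(medication 33%, diagnosis 41%, outpatient visit 73%, any observation
period 56%, address 45%, alive 95.6%).

Generation details, each chosen once and kept:

* **Bias injection is logit-additive.** Element presence for a patient in
  group $g$ is $\operatorname{logit}^{-1}(\operatorname{logit}(p_0) +
  \log m_g)$. An odds multiplier keeps probabilities in $(0,1)$ for any
  baseline, and makes the planted effect size a log-odds — the natural
  scale for the binomial test that must recover it.
* Ages are normal (mean 45, sd 20) truncated at 0; birth dates are
  derived from age at the reference date. Recorded deaths (4.44% by
  default) are dated uniformly within ten years before the reference
  date, clamped to the birth date.
* Event counts are zero-truncated Poisson (mean 2) *conditioned on the
  element being present*, so presence probability and intensity are
  controlled separately; event dates are uniform between birth (or ten
  years before the reference date) and the reference date.
* Observation-period durations are log-normal (`log-mean 7.0`,
  `log-sd 1.5` days), calibrated so that roughly a third of period
  holders retain a 6-year period — the long-tailed drop-off seen in
  published availability tables.
* Reproducibility: one seed per cohort, with fixed-offset sub-streams for
  the person, event, and observation-period tables. The same config is
  byte-identical across runs; `stratified_exact = TRUE` additionally pins
  group sizes by largest-remainder rounding.

`planted_truth()` converts a configuration into the set of (group,
filter) pairs whose survival genuinely differs from baseline, through the
dependency map: `alive` depends on death recording; the age filters on
birth date *and* diagnoses; `age_sex` on sex and birth date; the address
and record filters on their own element; and all seven observation-period
filters on observation-period presence. A multiplier on `medication`
plants exactly one pair; one on `observation_period` plants seven.

What the generator does **not** emulate — and therefore what passing
tests do and do not show: there are no coded vocabularies, no disease
trajectories, no visit-type ontology, no correlation between elements
beyond group membership, and missingness depends on race/ethnicity only
through the planted multipliers (missing at random within group). A clean
bill of health on synthetic data validates the *pipeline arithmetic and
inference*, not any claim about a particular health system's data.

## Validation design and problem sizes

The test suite validates the pipeline at these sizes, chosen to make
Monte-Carlo error negligible relative to the tolerances being checked:

* binomial p-values against an independent log-space PMF-enumeration
  oracle on 500 random cases with up to 1,000 trials (max deviation
  below 1e-12);
* additivity and non-cumulativity on 200 random 1,000-patient cohorts;
* nesting and coverage identities on 2,000-patient cohorts;
* type-I error on 200 null replicates with 5,000 expected patients per
  analyzed group (four race groups, two non-baseline ethnicity groups):
  the post-Bonferroni significant fraction stays within three binomial
  standard errors of the nominal 0.05 (empirically it is near zero, as
  expected from a conservative test under family-wise correction);
* planted-bias recovery at log-odds −0.7 on one group's medication and
  observation-period elements, 10,000 patients per group, 50 replicates:
  flagged pairs match the planted truth with sensitivity and specificity
  at or above 0.95 (empirically 1.0);
* byte-identical outputs across repeated pipeline runs with one seed.

`scripts/acceptance.R` re-runs the same battery end to end (with the
Monte-Carlo pieces at 100 null and 20 recovery replicates, sizes recorded
in its output) and writes every quantity to JSON.

## Known limitations

* The audit treats race and ethnicity as independent, separately analyzed
  dimensions; intersectional cells are out of scope.
* The UK-to-US category harmonization implements one published grouping
  recommendation; other mappings (notably for "Chinese", grouped under
  Asian here) exist.
* The binomial test conditions on pre-filter group sizes as fixed
  constants; it quantifies differential exclusion, not its causes.
* Percentages are reported at two decimals; downstream consumers needing
  full precision should use `remaining_n / baseline_n` directly.
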