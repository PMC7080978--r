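---
title: "Disproportionality screening of spontaneous reports: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigisignal)
```

## The problem

Spontaneous adverse-event reporting systems collect individual case safety
reports (ICSRs) linking one or more drugs to one or more suspected
reactions, coded as preferred terms (PTs). They have no denominator: nobody
knows how many patients took the drug without an event being reported. The
workhorse analysis is therefore *disproportionality*: compare how often an
event is reported **with** the drug of interest against how often it is
reported with **everything else in the same database**. vigisignal
implements that screen end to end for the hard case that motivated it — a
rare, route-specific exposure (intravitreal anti-VEGF drugs) and
age-associated neurodegenerative events — where three design features
dominate the answer: route filtering, event-set definition (PT vs
standardized query), and age restriction of the comparator.

## Model and estimators

For a drug D, an event definition E and a stratum cohort of N reports, each
report falls in exactly one cell of

|            | event | no event |
|------------|-------|----------|
| exposed    | a     | b        |
| unexposed  | c     | d        |

- **PRR** = [a/(a+b)] / [c/(c+d)], the ratio of event-reporting proportions.
  Its Wald interval is computed on the log scale with standard error
  √(1/a − 1/(a+b) + 1/c − 1/(c+d)).
- **ROR** = ad/bc with log-scale standard error √(1/a + 1/b + 1/c + 1/d).
  For rare exposure and events ROR ≥ PRR exactly when PRR ≥ 1 (the odds
  ratio inflates the risk-ratio scale), so the two agree in direction; this
  identity is property-tested on 10,000 random tables.
- **IC** = log₂((a + ½)/(E + ½)) with E = (a+b)(a+c)/N, a Bayesian
  shrinkage form of log₂(observed/expected): finite even at a = 0 and pulled
  toward 0 for sparse cells. Its lower 95% credibility bound uses the
  closed-form approximation IC − 3.3(a+½)^−½ − 2(a+½)^−3/2; an exact
  Gamma(a+½, E+½) quantile is available via `ic_estimate(..., "gamma")`
  (the two agree to < 0.1 bits for cells ≥ 20, also property-tested).

**Decision rule.** A pair is estimated only when a ≥ `min_cases` (default 3);
a *signal of disproportionate reporting* requires a ≥ 3 **and** PRR lower
bound > 1 (strictly). ROR and IC are reported as confirmatory measures and
do not gate the flag. A signal is a hypothesis about reporting, not a causal
claim.

**Degenerate tables.** a = 0 or c = 0 make the PRR undefined; such rows are
reported `computed = FALSE` with a reason, shown as `NA` — never silently
dropped (a zero comparator count with non-zero exposure cases is itself
informative). A zero cell in b or d only disables the ROR; no continuity
corrections are applied anywhere, matching the `NA` convention of published
screening tables. IC is always finite by construction.

## Cohorts, comparators and strata

- **Exposure** requires a drug record with role `suspected` (configurable to
  `any`), a generic-name match (case-insensitive, no salt/brand resolution)
  and the requested route. Reports whose only matching record has route
  `unreported` are excluded from the exposed margin — an unreported route
  cannot establish route-specific exposure — but remain in the comparator,
  as they do in the source databases.
- **The comparator** is all other reports of the stratum cohort, including
  reports of the other study drugs (a flag removes the class for sensitivity
  analyses).
- **Strata are self-contained**: an age-restricted analysis recomputes all
  margins, including the expected count E, within the restricted cohort.
  This is the whole point of the ≥ 65 re-analysis: an event whose background
  reporting rises with age must beat the *elderly* background to flag.
- **Missing age excludes** a report from every age-restricted stratum
  (membership cannot be verified); bands are closed intervals, `65–74` via
  `max_age = 74` and `≥ 75` via `min_age = 75`, disjoint and exhaustive
  over ≥ 65.
- **Period filtering** uses the report (receipt) date by default, since
  databases are extracted by reporting period; onset-based filtering is a
  config option.

## Case grading

For flagged pairs only, the pipeline grades the underlying case series:

- **Completeness** is a multiplicative score over ten documentation
  dimensions; the default penalties (0.5 time-to-onset; 0.3 indication and
  outcome; 0.1 each for age, sex, dose, country, primary reporter, report
  type, comment) follow the published completeness-scoring method — the
  magnitudes are not stated in the motivating study itself and are
  config-overridable. A score > 0.8 counts as well documented. Time-to-onset
  counts as documented only when some drug start date *and* some reaction
  onset date are day-precise; partial dates (`"2013"`, `"2013-05"`) are
  accepted on input but are imprecise here.
- **Causality** uses a first-match rule chain over structured inputs
  (temporal plausibility, alternative explanations, dechallenge,
  rechallenge, information sufficiency) yielding the six standard
  categories. The chain is total and order-fixed; it is tested exhaustively
  against an independent rule table on all 768 enum combinations. When run
  inside the pipeline the inputs are *derived* conservatively from
  structured fields (timing from the date pair; alternative explanations
  always `unknown`, since no narrative is available), so pipeline output
  concentrates in `possible`/`unassessable` — matching how little a
  structured-only assessment can claim.
- **Time to onset** is (earliest day-precise matching onset) − (earliest
  day-precise start of the matching suspected drug), in years of 365.25
  days; mean and n−1 SD over estimable cases. A report-date fallback for
  missing onsets exists but is off by default, because receipt date is a
  biased proxy for onset.

## The synthetic database

Real global report databases are access-restricted, so the package's
generator is a first-class module, not a fixture. Per report it samples age
(mixture: a proportion ≥ 65, default 0.20, uniform within 18–64 / 65–90),
sex, a period-uniform report date, suspected drugs by marginal probability
(optionally multiplied for elderly patients — the age-confounding lever),
and each event PT independently with probability
baseline × age-multiplier^((age−60)/10) × RRR when a planted drug is on the
report (capped at 1 with a warning). Background drug/PT pools guarantee the
≥ 1 drug, ≥ 1 reaction invariants. Drug start dates precede onsets by an
exponential lag (mean 1.5 y); field-level missingness (defaults: age 15%,
sex 10%, outcome 30%, indication 40%, start date 35% absent + 15%
year-precision, onset 20%) is applied *after* generation, so the hidden
truth remains consistent — which is what makes age-restricted re-analysis
of generated data meaningful.

`expected_cells()` returns the exact expected 2×2 cells implied by a config
(summing over the discrete age distribution and the presence patterns of
planted drugs, honouring the route-unreported leak into the comparator) and
is the independent oracle for all recovery tests.

What the generator does **not** emulate: duplicate reports, reporting
cultures by country, drug ontologies, within-report PT correlation (unless
the explicit co-occurrence knob is used), secular reporting trends. A green
recovery test therefore establishes estimator and pipeline correctness
under the stated generative model — not robustness to real-world reporting
artefacts.

### Default rates and calibration worlds

The demo config mirrors the structure of the motivating study — exposure
mainly in the elderly, events rising with age, a planted RRR — at rates
scaled up from the real world (exposure there is ~0.04% of reports) so a
20,000-report tutorial database is informative. Two further stated worlds
are fixed a priori in the acceptance suite:

- **Recovery calibration**: n = 200,000, exposure 8%, event baseline 6%,
  RRR 3, no age effect. Sized so the planted cell expects ≈ 2,900 cases,
  making the 5% relative-error tolerance ≈ 2.6 sampling SDs — the tolerance
  is achievable by design rather than by seed selection.
- **Confounding demonstration**: exposure 0.4% (×10 in the elderly), event
  baseline 1.2% rising ×2.2 per decade over 60, RRR = 1, n = 50,000. Sized
  so the elderly stratum expects ≈ 15 cases; with fewer than 3 the
  restricted estimate would be `NA` and the demonstration vacuous. The
  all-ages analysis flags a spurious signal, the restricted one removes it.
- **Null calibration**: 6 unplanted pairs × 20 fixed seeds at n = 50,000
  (scaled down from 200,000 to keep the suite inside its time budget); the
  pooled flag rate must stay below 5%, consistent with the one-sided 2.5%
  asymptotic level of the lower-bound rule plus the discreteness of the
  3-case gate.

## Numerical and formatting choices

- z = 1.959964 (two-sided 95%) everywhere; configurable.
- Human-readable percentages and estimates are rounded **half away from
  zero** to 2 decimals. Published tables often mix truncation and 1- or
  2-decimal rounding; we standardize rather than reproduce each variant
  (CSV outputs keep full precision).
- Report-level dates must be full ISO-8601; drug-start and onset dates may
  be partial (year or month), which affects only time-to-onset estimability
  and the completeness score.
- Deterministic ordering of output tables (drug, then SMQ-level before
  PT-level events, then strata) and a config-hash manifest make re-runs
  byte-identical.
- The generator uses one vectorized seeded stream rather than per-report
  substreams: R has no cheap splittable RNG, and for a fixed config the
  vectorized draw order is itself deterministic, which achieves the same
  reproducibility guarantee.

## Open design points, resolved

- **Suspected vs concomitant exposure**: the motivating study does not say
  whether its drug selection required the suspected role; we require
  `suspected` (the usual convention for attribution) and expose
  `role = "any"`.
- **Comparator within the elderly stratum**: restricted analyses recompute
  the comparator inside the stratum, which is the only reading under which
  restriction reduces age confounding.
- **Privacy masking** of small case-level tables (≤ 10 cases) exists as an
  off-by-default flag: synthetic data needs no masking, real data does.

## Limitations

Disproportionality cannot estimate incidence or risk; it is sensitive to
reporting artefacts (stimulated reporting, masking by other strong signals)
that the generator does not model. No multiplicity adjustment is applied —
deliberately, as in the motivating screen — so family-wise error grows with
the number of pairs screened. The bundled term dictionary is illustrative,
not licensed MedDRA content; real analyses must supply their own PT→SMQ
table.
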