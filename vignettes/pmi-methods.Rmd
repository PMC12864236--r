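---
title: "Severity-weighted complication burden: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-weighted complication burden: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmindex)
```

## The problem

Surgical trials usually report how *often* each postoperative complication
occurred, but rarely how *severe* the complications were in a form that can
be compared across procedures. The postoperative morbidity index (PMI)
addresses this by weighting each complication with a severity weight from
the six-grade Accordion scale (1 = minor bedside intervention, 2 =
pharmacological treatment, 3 = invasive procedure without general
anaesthesia, 4 = operation under general anaesthesia, 5 = organ-system
failure, 6 = death) and averaging the burden over treated patients. The
motivating application is the comparison of two minimally invasive surgical
therapies for benign prostatic hyperplasia — water-vapour ablation (Rezum,
n = 136) and the prostatic urethral lift (Urolift, n = 140) — from their
pivotal randomized trials, over a short (3-month) and a long (5-year)
horizon.

## The model

### Severity weights

The default weight vector is the published ACS-NSQIP Accordion set

| grade | 1 | 2 | 3 | 4 | 5 | 6 |
|-------|---|---|---|---|---|---|
| weight | 0.110 | 0.260 | 0.370 | 0.600 | 0.790 | 1.000 |

Any user table can be supplied through `accordion_weights()` provided it is
strictly increasing and anchored at 1 for postoperative death; that anchor
is what gives the PMI its interpretation (0 = no complications, 1 = every
patient died). We validated this default by checking that it reproduces the
published 5-year PMIs of both arms exactly: with rates $r = (0.110, 0.044)$
at grades $(2, 4)$, $0.110 \times 0.260 + 0.044 \times 0.600 = 0.055$; the
other arm gives $0.165$ the same way.

### Point PMI

With aggregate data — per-complication event rates $r_i$ and typical grades
$g_i$ — the fitted quantity is

$$\mathrm{PMI} = \sum_i r_i \, w(g_i),$$

implemented as `pmi(arm)` (`mode = "sum_all"`). This is the arithmetic used
in published aggregate analyses, and it is *not* intrinsically bounded by 1
because one patient may suffer several complications; the package warns,
but deliberately does not cap, when the sum exceeds 1. The bounded textbook
variant, in which each patient contributes only their most severe
complication's weight, is available as `mode = "max_per_patient"` and needs
patient-level data (from the synthetic generator, or any source in the same
long format). On identical patient-level data the per-patient-max value can
never exceed the summed value, a property the test suite checks. The
tension between the 0–1 reading of the scale and the unbounded summing rule
is surfaced rather than resolved: both modes are first-class.

### Cumulative incidence and union bounds

`cumulative_incidence()` sums the rates over a horizon under the
distinct-patient convention used for published 5-year retreatment and
implant-removal rates, capping at 1 with a warning as a guard against
misuse. When only marginal short-term rates are published, the proportion
of patients with *at least one* complication is not identified; the
inclusion–exclusion extremes are `union_bounds()` (lower: total overlap,
`max(r)`; upper: disjoint events, `min(1, sum(r))`) and
`union_independent()` returns the independence value $1 - \prod_i (1-r_i)$,
which always lies between the bounds and serves as the mode of the
triangular rate model below. The bounds are verified in the tests against
an exhaustive search over all joint patient assignments at small $n$.

## Uncertainty propagation

`simulate()` on a fitted `pmi` object draws a Monte Carlo PMI distribution
(default 1000 iterations, mirroring the source analysis):

* **Event counts.** Each complication's 5-year count is drawn from
  $\mathrm{Binomial}(n, c_i/n)$ where $c_i$ is the integer count recovered
  from the printed one-decimal percentage by `rate_to_count()`. Using the
  recovered count rather than the rounded percent avoids double rounding;
  for all five published long-term rates the recovery round-trips exactly.
* **Grade uncertainty.** Each complication's severity weight is drawn from
  a triangular distribution whose vertices are the weights of the minimum,
  typical, and maximum plausible grades. Sampling in *weight space* rather
  than grade space matters: weights enter the PMI product directly, and
  rounding a continuous grade draw back to an integer would pile mass onto
  the middle grade. When no range was assigned the three vertices coincide
  and the draw is the typical weight, deterministically.
* **Short horizon.** The default keeps the same per-complication binomial
  model, which preserves the point PMI as the draw mean. The alternative
  reading — a triangular distribution over the *union* rate bounded by the
  inclusion–exclusion extremes with mode at the independence value —
  is provided as `rate_model = "triangular_union"`; its draw is the union
  rate times the rate-weighted mean severity weight.
* **Intervals and comparison.** `credible_interval()` is the equal-tailed
  percentile interval (R's default type-7 quantile interpolation; the tests
  pin this against an independent order-statistic oracle). `compare_pmi()`
  simulates each arm on its own stream (`seed` and `seed + 1`), pairs draws
  by iteration index, and reports the difference summary plus the fraction
  of iterations favouring the first arm, counting exact ties as half an
  iteration so identical arms score exactly 0.5. Pairing by index with
  independent streams matches an analysis that simulates each treatment
  separately and then differences.

The triangular sampler is an inverse-CDF implementation written here
(`rtri()`/`qtri()`/`ptri()`) since no installed distribution covers it; it
admits the degenerate cases $a=m$, $m=b$ and $a=m=b$.

All randomness is seed-controlled through a scoped RNG: any function given
a `seed` runs on a temporary stream and restores the caller's RNG state,
so identical configurations give bit-identical draw vectors.

## Inter-rater reliability

Complication grading is subjective, so the workflow assumes two raters
grade every complication and an adjudicator settles disagreements
(`adjudicate()` takes the common grade, else the adjudicator's). `icc()`
reports the intraclass correlation from the two-way ANOVA mean squares.
The default form is ICC(2,1) — two-way random effects, absolute agreement,
single rater — the most common choice when two interchangeable raters grade
all items and systematic offsets should count against agreement; the
consistency and average-rater forms are available via `form`. Band labels
use the conventional cutpoints (poor < 0.50, moderate 0.50–0.75, good
0.75–0.90, excellent > 0.90). A grade matrix with no variance at all leaves
the coefficient undefined (0/0 in the mean-square ratio); the package
returns `NA` with a warning rather than inventing a value.

## The synthetic trial generator

`generate_trial()` produces patient-level two-arm data with exactly the
structure the aggregate analysis assumes, so every pipeline stage is
testable without external data:

* per-complication Bernoulli events at configured rates;
* an optional shared-frailty overlap model — a per-patient
  $\mathrm{N}(0, \sigma)$ shift on the log-odds of *every* complication —
  giving one-parameter control over the within-patient event clustering
  that motivates the inclusion–exclusion treatment ($\sigma = 0$ reduces to
  independence, matched-seed identical);
* per-event grades with probability mass 0.8 (configurable) on the typical
  grade and the remainder split evenly between the minimum and maximum
  plausible grades — the simplest family matching a (min, typical, max)
  elicitation;
* `simulate_raters()` adds per-rater noise: with the configured
  probability a rater reports an adjacent grade (one step either way,
  clamped to the 1–6 scale), and the adjudicator reports the truth.

`aggregate_patients()` maps the patient level back to the aggregate table
shape (observed rate, modal grade as typical, observed extremes as the
range), closing the loop: the parameter-recovery tests generate $10^4$
patients, aggregate, refit, and require the configured expected PMI back
within three Monte Carlo standard errors.

What the generator does *not* emulate: time-to-event structure (a 5-year
rate is a single Bernoulli, not a hazard), covariates, informative
censoring, or correlated grading errors between raters. Passing tests
therefore show the estimator chain is self-consistent under the stated
sampling model, not that real trials satisfy that model.

## Numerical choices and problem sizes

* Counts recover from percents by nearest-integer rounding, ties half away
  from zero; the stored "exact" proportion follows whichever field the
  source supplied (printed percent, or count/n).
* Modal-grade ties in aggregation resolve to the smallest grade,
  deterministically.
* Credible levels must lie strictly in (0, 1); empty draw vectors are an
  error, a constant vector yields a degenerate interval.
* Default iterations are 1000, matching the source analysis; the oracle
  and convergence tests use $10^4$ draws, and the exhaustive union oracle
  runs at $n \le 6$ patients where full enumeration is cheap. These sizes
  keep every distributional check within three standard errors of its
  closed form while the whole suite runs in seconds.

## Known limitations

* The published short-term complication list lives in a supplement not
  shipped here; `inst/extdata/shortterm_synthetic.csv` is a clearly
  labelled *synthetic partial* stand-in holding only the four short-term
  complications whose rates appear in the main results text, with grade
  ranges chosen once on clinical grounds (all four are described as grade
  1–2 events). Analyses of the short horizon with this file exercise the
  machinery but do not reproduce the published short-term PMIs — with only
  these four rates that is arithmetically impossible under the summed PMI.
* The published per-complication minimum/maximum plausible grades are not
  printed, so published credible-interval endpoints can be bracketed (the
  tests require containment of the point PMI and widths within a factor of
  two of the published widths under any grade-range assignment consistent
  with the typical grades) but not matched exactly.
* The published grading ICC cannot be recomputed because the per-rater
  grade assignments are unpublished; the reliability module is instead
  validated against ANOVA oracles and a monotone noise-degradation
  property on synthetic raters.
* Annual (1–4 year) incidence breakdowns are out of scope: their inputs
  are not published.

## A worked example

```{r example, eval = FALSE}
tab <- system.file("extdata", "longterm_results.csv", package = "pmindex")
sizes <- system.file("extdata", "arm_sizes.json", package = "pmindex")
arms <- read_complication_table(tab, sizes)

fit_r <- pmi(arms$Rezum)
fit_u <- pmi(arms$Urolift)
summary(fit_u)

cumulative_incidence(arms$Rezum)    # 0.154
cumulative_incidence(arms$Urolift)  # 0.336

cmp <- compare_pmi(fit_r, fit_u, nsim = 1000, seed = 1)
cmp
plot(cmp)
```
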