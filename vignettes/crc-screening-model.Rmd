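---
title: "Methods: a cohort decision model of CRC screening disruption and FIT expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cohort decision model of CRC screening disruption and FIT expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The model and its assumptions

`crcscreen` is a deterministic cohort model of average-risk US colorectal
cancer (CRC) screening over a three-year horizon. Each model year an annual
cohort of `B` would-be screeners is split by an uptake schedule into a
colonoscopy arm, a FIT arm and an unscreened arm. The model tracks one
outcome chain per arm:

* **Colonoscopy**: a prevalent cancer is screen-detected with probability
  equal to the test's sensitivity; a colonoscopy is its own diagnostic
  follow-up, so adherence is 1.
* **FIT**: a prevalent cancer is screen-detected only if the test is
  positive (probability = sensitivity) *and* the person completes the
  diagnostic colonoscopy (probability = adherence), so the effective
  detection probability is `sensitivity x adherence`. The FIT positivity
  rate — the marginal probability of a positive result across all FIT
  screeners — does not enter case detection; it drives the
  diagnostic-colonoscopy demand that the model reports separately.
* **Symptomatic presentation**: cancers the screening process leaves
  undiagnosed (colonoscopy false negatives, FIT false negatives,
  FIT-positive non-adherers, and all prevalent cancers among the
  unscreened) present clinically within the horizon with probability
  `q_undiagnosed`, applied uniformly across those groups because nothing in
  the inputs distinguishes their presentation rates.
* **Stage at diagnosis**: screen-detected cases draw from their modality's
  stage distribution, symptom-detected cases from the more advanced
  clinical distribution. Stage shift is captured entirely by these three
  static distributions; there is no within-horizon progression.

Annual cohorts are disjoint: nobody screens twice, and undiagnosed persons
do not carry over into the next year's cohort. All counts are kept as real
numbers internally; only rendered tables round (half away from zero) to
whole persons, and scenario comparisons are computed on unrounded values and
rounded afterwards.

## Parameters

| Parameter | Default | 95% CI | Units / meaning |
|---|---|---|---|
| Colonoscopy sensitivity | 0.95 | 0.90–1.00 | P(detect \| cancer) |
| CRC prevalence | 0.008 | 0.007–0.009 | per screener-year |
| FIT sensitivity | 0.79 | 0.69–0.85 | P(positive \| cancer) |
| FIT positivity | 0.07 | 0.063–0.077 | marginal P(positive) |
| Diagnostic adherence | 0.65 | 0.52–0.78 | P(colonoscopy \| FIT+) |
| Annual screeners `B` | 1,563,556 | — | persons/year |
| Horizon | 3 | — | years |
| Baseline mix | 0.85 / 0.15 | — | colonoscopy / FIT |
| `q_undiagnosed` | calibrated | — | P(symptomatic \| undiagnosed) |

Two readings of prevalence circulate for this model family: 0.8% and 0.08%.
The package defaults to 0.8% because it is the only reading consistent with
the reported case scale (≈34,000 cases among ≈4.7M screened implies a rate
near 0.7%); `default_parameters(prevalence_low_reading = TRUE)` selects the
other. Stage distributions — colonoscopy (34/36/19/11), FIT
(36.7/34.7/21.7/6.9), clinical (18/34/23/25), in percent for stages I–IV —
are published without CIs and therefore receive degenerate uncertainty
ranges, which keeps the sensitivity module's treatment of parameters
uniform (degenerate ranges simply contribute zero swing and zero variance).

### Calibration of `q_undiagnosed`

The symptomatic pathway is linear in `q`, so calibration is closed-form:
`q = target / pool`, where the pool is the undiagnosed-cancer count implied
by the calibration schedule. The default target is the baseline scenario's
576 symptom-detected cases, giving `q ≈ 0.133`. `q` is calibrated once on
the baseline and reused unchanged for every counterfactual scenario — the
counterfactuals must not be recalibrated to themselves, or the quantity
being compared would change between arms. Results are clamped to `[0, 1]`
with a warning if the target exceeds the pool.

## Uptake schedules

The five canonical schedules store the published per-year percentages
verbatim and are the ones used for every published-scenario run. Because
those rows are printed rounded to whole percent, a yearly row may sum to
99–101%; schedules accept sums in `[0.99, 1.01]` and the engine recomputes
the unscreened arm as `1 − colonoscopy − FIT` (snapping values below 1e−9
to exact zero) so persons are conserved while the printed screening columns
are preserved.

Two generative tools build *new* scenarios rather than reproduce the
canonical ones. `schedule_from_profile()` converts a monthly dispersion
profile — ordered segments of (duration, volume multiplier), e.g. 3 months
normal, 3 suspended, 9 at 50%, 21 at 75% — into yearly uptake by
duration-weighted averaging within calendar years (months 1–12, 13–24,
25–36; segments may straddle years and are split by month). A
`fit_multiplier_override` lets FIT deviate from the shared profile, which is
needed to express scenarios whose FIT uptake stays flat while colonoscopy
recovers. `apply_fit_expansion()` moves a fixed completion rate (default
22.5%, a median organised-outreach FIT completion figure) of the unscreened
pool into FIT, conserving totals and never touching colonoscopy. No single
(profile, rule) pair reproduces every published uptake cell — the published
FIT columns for the expansion scenarios follow arithmetic that is not
recoverable from the stated rules — which is exactly why the canonical
schedules are stored verbatim and the generative tools are kept separate.

## The microsimulation oracle

`simulate_cohort()` is an individual-level Monte-Carlo implementation of the
same statistical structure: per person, a categorical modality draw, a
Bernoulli cancer draw, Bernoulli test/adherence draws, a Bernoulli
symptomatic draw for undiagnosed cancers, and a categorical stage draw per
detection route. Counts are scaled by `B / n_persons_per_year` so replicate
means estimate the cohort engine's totals, with Monte-Carlo standard errors
from the replicate spread. Each replicate runs on seed
`seed + replicate − 1`, making any replicate individually reproducible.

One quantity is derived rather than supplied: the FIT false-positive rate
among cancer-free screeners is `(positivity − prevalence × sensitivity) /
(1 − prevalence)`, which makes the simulated marginal positivity match the
configured 7%; configurations implying a rate outside `[0, 1]` are rejected.

The validation suite checks that every cohort outcome lies within 3
Monte-Carlo standard errors of the replicate mean at 200,000 persons/year
and 50 replicates, across 20 seeds with a ≥95% pass requirement — sizes
chosen to make the 3-SE bands a few hundredths of the quantities being
checked while the whole check stays in the minutes range on one CPU. The
simulator emulates the cohort model's *assumed* structure, not reality: it
shares the engine's disjoint annual cohorts, static stage distributions,
uniform `q` and single prevalence, so agreement between the two validates
the deterministic arithmetic and nothing more — it is no evidence about
real screening populations, repeat-screening dynamics or stage progression.

## Sensitivity analysis

`one_way_sensitivity()` sets each parameter to its CI bounds in turn
(tornado order: descending swing, ties broken alphabetically), holding `q`
fixed by default; re-calibration per perturbed run is available by flag
since both conventions appear in practice. `probabilistic_sensitivity()`
draws every CI-bearing proportion from a beta distribution fitted
numerically so its 2.5th/97.5th percentiles reproduce the published CI;
betas are natural for probabilities and need no truncation. Where a CI
bound sits on the boundary of `[0, 1]` (colonoscopy sensitivity, 0.90–1.00)
no proper beta attains the bound as a quantile, so the fit instead pins the
beta mean to the point estimate and matches the interior quantile — the
package's own choice, documented here because any boundary convention is
somewhat arbitrary. Stage proportions are not varied (degenerate ranges).
The published analysis names its CI ranges but reports no propagation of
them, so this whole module is an extension.

## Numerical choices

* Closed-form calibration (no iteration); tolerance questions do not arise.
* Beta fits: interior CIs by Nelder-Mead least squares on the two quantile
  errors (moment-matched start, relative tolerance 1e−14), accepted only if
  the residual quantile error is below 1% of the CI width; boundary CIs by
  `uniroot` on the log shape total (tolerance 1e−12).
* Degenerate inputs: empty unscreened pools make FIT expansion a no-op;
  zero reference outcomes yield `NA` percent differences (never `Inf`);
  an all-unscreened schedule with `q = 0` produces zero cases.
* Homogeneity: all outcomes are exactly degree-1 homogeneous in `B`, tested
  to relative error 1e−12.

## Reproduction tolerances and known limitations

The published inputs are printed rounded — uptake to whole percent, test
characteristics to one decimal — and the symptomatic pathway is calibrated,
so reproduction of previously reported outputs is tested at: screened
counts ±2%, case counts ±6% (±8% for the scenario-1 case shortfall, which
compounds the calibrated pathway), proportions ±1.5 percentage points, with
the baseline screened total exact. Within those bands the model reproduces
the baseline (exactly), the scenario-vs-baseline screened shortfalls and
the baseline early-stage share.

Differences *between* counterfactual scenarios are harder: subtracting two
totals, each carrying ~1% input rounding error, amplifies the relative
error of the difference several-fold, and the screened gains of the FIT
-expansion scenarios computed from the printed percentages fall 2–5% short
of the previously reported gains. The incremental-diagnoses comparison
(scenario 4 vs 2) is structurally bounded as well: with `q` calibrated to
the baseline and the unscreened included in the symptomatic pool, the case
increment is algebraically `ΔFIT_screen × (1 − q)`, so it sits ~16% below
the previously reported figure, and the early-stage share of the increment
runs correspondingly high, because the reported symptom-detected column is
not generated by any constant `q` over a pool recoverable from the printed
inputs. The test suite asserts these comparisons at the stated bands and
they fail honestly there; the package reports what the printed inputs
imply rather than adjusting toward previously reported differences.

Beyond reproduction: the model has no natural history (no
adenoma–carcinoma progression, no stage drift with delay), no repeat
screening or carry-over of undiagnosed persons, one shared prevalence for
both modalities' cohorts, a uniform symptomatic-presentation fraction, and
no mortality, survival or cost outputs. It is a scenario-comparison
framework, not a forecasting tool.
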