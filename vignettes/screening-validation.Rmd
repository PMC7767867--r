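---
title: "Validating an IGF1-based ROP screening rule: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an IGF1-based ROP screening rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropscreen)
```

## The problem

Retinopathy of prematurity (ROP) arises in two phases: an arrest of retinal
vascularisation after pre-term birth, then — in a subset of infants — an
abnormal vasoproliferative phase driven by VEGF acting together with
insulin-like growth factor 1 (IGF1). Low serum IGF1 in the third week of
life marks infants whose retinal vascularisation is stalling; a steep rise
in IGF1 between weeks 3 and 5 is associated with progression to the
proliferative form. This package implements and stress-tests a two-tier
screening rule built on those observations:

1. **Mandatory tier** — infants below 30 + 0 weeks of gestation *and/or*
   below 1,250 g receive standard serial eye examinations regardless of
   biomarkers (an extended variant restricts this to 28 + 0 weeks / 1,100 g).
2. **Probability triage** — all other enrolled infants are screened
   serially only when their model-predicted ROP probability *exceeds* 30%;
   low-risk infants instead receive a single confirmatory exam at 40 weeks
   postmenstrual age.

## The risk model

The triage probability is logistic in exactly the two predictors the rule
names:

$$P(\mathrm{ROP}) = \mathrm{logit}^{-1}\!\left(\beta_0 + \beta_1\,
\mathrm{IGF1}_{3w} + \beta_2\, \mathrm{sepsis}_{\le 3w}\right)$$

with IGF1 in ng/ml and sepsis a given 0/1 flag. `fit_logistic()` maximises
the likelihood by iteratively reweighted least squares from an all-zero
start, with a 1e-8 ridge on the weighted normal equations and step-halving
whenever a full Newton step would reduce the log-likelihood, so the
likelihood trace is monotone by construction. Convergence is a maximum
absolute coefficient update below 1e-8 within 100 iterations.
(Quasi-)complete separation is reported through the `separation` and
`converged` flags — detected as a non-converged fit whose fitted
probabilities already classify the outcome perfectly — rather than returned
as silently diverged coefficients.

### The reconstructed reference parameter set

The original probability-curve coefficients were never published; what is
known is the behaviour of the rule (20.9% of the prospective validation
cohort exceeded the 30% cut-off) and the single-biomarker discriminator
(IGF1 < 30 ng/ml). The package therefore ships a **reconstructed, clearly
non-published** reference model, built by `calibrate_rop_model()`:

- slopes fixed at $\beta_1 = -0.15$ per ng/ml and $\beta_2 = 1.5$
  (sepsis odds ratio ≈ 4.5), chosen once so that for a non-septic infant
  the 30%-probability boundary sits near the 30 ng/ml mark;
- the intercept solved numerically (`uniroot` on the analytic mixture
  distribution of the linear predictor implied by the cohort parameters)
  so the *expected* high-risk fraction of a calibrated cohort is 20.9%.

With the default cohort parameters this gives $\beta_0 \approx 3.96$, i.e.
a non-septic boundary at IGF1 ≈ 30.0 ng/ml — consistent with the published
cut-off without having been fitted to it. Because the calibration targets
the *classification* rate, not the incidence, the simulated cohort's ROP
incidence (≈17%) is higher than the 2% seen in the real validation cohort;
the published accuracy metrics are therefore reproduced from the printed
2×2 counts, never from simulation.

## What the cohort generator states — and what it does not

`generate_cohort()` draws, per infant:

| quantity | law | default | source of the default |
|---|---|---|---|
| latent risk stratum | Bernoulli | P(high) = 0.209 | 32/153 high-risk in the prospective cohort |
| gestational age | uniform on range | 30–32 wk | enrolment window |
| birth weight | uniform on range, weight 0.3 on the GA position | 1,250–1,500 g | enrolment window; mild positive GA–weight coupling |
| week-3 IGF1 | normal truncated at 1 ng/ml | mean 51 (low) / 30.48 (high) ng/ml, sd 15 | published stratum means; sd not printed, 15 ng/ml is a realistic serum IGF1 spread at this age |
| sepsis ≤ 3 wk | Bernoulli by stratum | 6.6% / 15.6% | published stratum prevalences |
| ROP | Bernoulli with p from the risk model | reference model | generative truth = the triage model |
| proliferative &#124; ROP | Bernoulli | 0.2 | the validation cohort had *no* proliferative cases; configurable so all grades occur |
| week-3→5 % increase | normal by grade, truncated so week-5 IGF1 > 0 | means 14.10 / 21.47 / 28.97%, sd 30 | published grade means; sd back-derived from the printed proliferative CI (−1.18, 59.13), which is symmetric about 28.97 and matches sd ≈ 30 for a proliferative group of about six infants |

One RNG seed enters per run; per-stage sub-seeds are drawn up front, so
adding draws inside one stage never perturbs another stage's stream, and
identical parameters give bit-identical cohorts.

The latent `high_risk_frac` mixing fraction is a field the published
group-conditional means force on the generator: group-conditional moments
only pin down a mixture once its weights are stated.

**What a green test does *not* establish.** The generator emulates the
published *marginal/stratum structure*, not patient-level reality: GA and
weight are independent of the latent stratum (the real high-risk group was
lighter and younger), IGF1 is symmetric-truncated-normal rather than
skewed, covariates such as oxygen exposure are absent, and outcomes are
drawn *from the same model family that is later fitted*, so parameter
recovery demonstrates correctness of the fitting code, not clinical
validity of the rule. Table-level per-variable means and p-values are
calibration inputs, never test targets.

## Decision-rule semantics

All boundary readings follow the printed symbols and are frozen in tests:

- mandatory tier: GA `<` 30 + 0 weeks **or** weight `<` 1,250 g (strict;
  "and/or" = inclusive-or); extended variant `<` 28 + 0 / `<` 1,100 g;
- probability triage: screened iff probability `>` 0.30 (strict
  "exceeds"); an infant at exactly 0.30 is low-risk — the boundary test
  constructs a model whose predicted probability is exactly 0.30 in double
  precision;
- AAP baseline: weight `≤` 1,500 g or GA `≤` 30 weeks (non-strict, per the
  printed "≤"), plus (1,500, 2,000] g with GA > 30 and an unstable course,
  the latter collapsed to one binary input because no operational
  definition is given;
- gestational ages given as `W+D` convert as W + D/7.

On the enrolment population (weights ≤ 1,500 g) every infant screened by
the two-tier rule is also screened by the AAP baseline, making the rule a
pure restriction; the extended variant's mandatory tier is a subset of the
validated variant's.

## Diagnostic metrics

`summarize_table()` computes sensitivity tp/(tp+fn), specificity
tn/(tn+fp), PPV tp/(tp+fp) and NPV tn/(tn+fn) from the 2×2 table of
*triaged* (non-mandatory) infants — mandatory-tier infants are excluded
because the validation concerns only the probability triage. The published
tables report no interval estimates; the package adds exact
Clopper–Pearson 95% intervals (appropriate at small counts and at the
NPV = 100% boundary) as a supplement, never as a comparison target.
Display rounding is half-up to one decimal in percent (9.375% → 9.4%),
matching the published convention. One printed value does not reproduce
from its own counts: retrospective specificity is printed as 77.1% while
151/196 = 77.04% → 77.0%; the package reports the counts-derived value and
documents the discrepancy.

## Trajectory statistics and tests

The percentage increase is 100·(IGF1₅w − IGF1₃w)/IGF1₃w (may be negative).
Per grade, `summarize_by_grade()` reports the mean with a symmetric
t-interval — the printed proliferative CI is symmetric about its mean,
consistent with this construction — and quartiles by linear interpolation;
grades with fewer than two complete trajectories are marked unavailable
rather than summarised.

`compare_groups(mode = "auto")` gates on per-group Shapiro–Wilk normality
at α = 0.05 (the published analysis chose t vs Mann–Whitney "according to
whether variables were normalised", without stating the gate): both normal
→ Welch t (group sizes are unequal throughout; Student's pooled t remains
available), otherwise Mann–Whitney U. For groups above Shapiro–Wilk's
n = 5000 limit the gate uses 5,000 evenly spaced order statistics. The
Mann–Whitney path is exact whenever the smaller group has ≤ 8
observations: without ties via the exact Wilcoxon null distribution
(identical to full enumeration), with ties by enumerating all
`choose(n, n_a)` assignments while that is feasible (≤ 2e5 combinations;
beyond that the tie-corrected normal approximation is used with a note).
Larger samples use the tie- and continuity-corrected normal approximation.
χ² is Pearson by default with Yates correction behind a flag, and the
one-way ANOVA returns F = 0, p = 1 when all group means coincide,
including the fully degenerate all-identical case. The χ² variant and
t-test flavour behind the published per-variable p-values are unknown and
deliberately not asserted as targets.

## Numerical choices

- IRLS: zero start, 1e-8 ridge, step-halving, tolerance 1e-8 on coefficient
  updates, cap 100 iterations.
- ROC: thresholds at all distinct scores, ties grouped at one threshold,
  AUC by trapezoid — algebraically identical (to machine precision) to the
  pairwise Mann–Whitney statistic including tie credit of ½.
- Truncated normal draws by inverse-CDF so a single uniform stream drives
  each stage; the week-5 truncation at −100% is negligible at the default
  means and sd (≈4 sd away).
- Exact complementarity of the screened/excluded fractions is guaranteed
  by computing both from the same integer counts before any rounding.
- CSV round-trips are bit-exact: numerics are written with 17 significant
  digits and parsed with `strtod` (correctly rounded), not a fast
  approximate parser.

## Known limitations

- The reconstructed reference model reproduces the rule's *behaviour*
  (high-risk fraction, boundary location), not the unpublished original
  coefficients; nothing here certifies the clinical rule itself.
- The historical incidence series and the 87.7% "discriminative efficacy"
  of the bare IGF1 < 30 ng/ml cut-off (an index whose definition — AUC or
  otherwise — is not stated) are not reproducible without the raw cohort
  and are not targets; the simulated AUC of the bare cut-off depends
  entirely on the assumed IGF1 spread.
- Sepsis enters as a given flag; its diagnostic criteria are out of scope,
  as are treatment decisions and exam scheduling beyond the binary screen
  indication and the single 40-week low-risk exam.
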