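---
title: "Carotid plaque phenotypes and cardiovascular risk reclassification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carotid plaque phenotypes and cardiovascular risk reclassification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioreclass)
```

## The scientific problem

Carotid atherosclerotic plaque, visible on a routine ultrasound, is a
marker of subclinical atherosclerosis. Guideline risk tools such as the
Pooled Cohort Equations (PCE) predict 10-year atherosclerotic
cardiovascular disease risk from demographics and blood-based risk
factors, but they carry no information about plaque that is already
present. The question this package operationalizes is: if an automated
detector tells us whether a participant has carotid plaque (and how many),
how much does that knowledge improve risk prediction and risk-category
assignment for major adverse cardiovascular events (MACE: myocardial
infarction, stroke, or cardiovascular death)?

Population cohorts with both imaging and outcomes are access-restricted,
so every stage of the pipeline is exercised against a synthetic cohort
whose statistical structure matches what the downstream methods assume.
The synthetic generator is first-class, tested code — not a test fixture.

## The synthetic cohort generator

`cohort_params()` / `generate_cohort()` emulate a population imaging
cohort of ~19,500 late-middle-aged volunteers:

* **Covariate marginals.** Age 64.6 (SD 7.6) years, SBP 138.6 (17.94)
  mmHg, total cholesterol 5.72 (1.09) mmol/L, HDL 1.48 (0.37) mmol/L, LDL
  3.58 (0.83) mmol/L; 50.8% female, 3.6% current smokers, 5.5% diabetes,
  23.7% statin use, 24.7% antihypertensive use, 7.1% prior CVD; race
  groups 97.1% white, with small black and other fractions. Covariates
  are drawn independently: only marginal summaries are available for the
  emulated cohort, so no covariance structure is claimed. A cohort whose
  covariates are independent is *easier* for every downstream method than
  a real cohort; passing tests therefore demonstrate correctness of the
  estimators, not robustness to confounded real data.
* **Plaque model.** Presence follows a logistic model whose coefficients
  encode the qualitative risk-factor associations (older age, male sex,
  smoking, higher SBP and LDL, statin use, prior CVD increase the odds).
  The intercept (-5.346) was calibrated once, at the default covariate
  distribution, so that overall prevalence is 45%. Among plaque-positive
  participants the count is 1, 2 or 3 with probabilities 0.689 / 0.242 /
  0.069, reproducing cumulative prevalences of 45% (at least one), 14%
  (at least two) and 3.1% (at least three).
* **Outcome model.** MACE times are exponential — a constant baseline
  hazard — under proportional hazards, with covariates centered at their
  means so the baseline rate (2.9e-4 events/person-month, calibrated to
  ~2.2% observed events) is the rate of a typical participant. The Cox
  estimands downstream depend only on the proportionality of hazards, and
  no baseline shape information is available for the emulated cohort, so
  the simplest shape is used. Plaque enters either as a presence term or
  as two count-level terms (one plaque; two or more), with default log
  hazard ratios log(1.30) and log(1.62).
* **Censoring.** Each participant has an administrative censoring time
  drawn uniformly on (30, 80] months, giving a median follow-up of 55
  months on a 1–80 month observed range. Death from non-cardiovascular
  causes is folded into this single censoring stream rather than modeled
  as a competing risk; the downstream methods all treat non-CVD death as
  censoring, so the simplification is consistent with how the estimates
  are interpreted.
* **Event taxonomy.** Events are labeled myocardial infarction, stroke or
  cardiovascular death with probabilities 0.453 / 0.400 / 0.147, matching
  the component mix of the emulated endpoint.

`generate_detection_fixtures()` produces paired ground-truth and
predicted bounding boxes on a 480 x 448 pixel ultrasound crop canvas:
predictions are jittered copies of true boxes thinned by a false-negative
rate, plus Poisson spurious boxes. The default rates (miss probability
0.28, 0.155 spurious boxes/image) were chosen to land near the detection
operating point the evaluation module is designed to measure (precision
and recall near 70%).

## Detection evaluation

Boxes are half-open axis-aligned pixel rectangles, origin top-left, so
areas need no +1 correction and the YOLO-text round-trip is exact.
Matching is COCO-style: predictions above the confidence threshold
(default 13%) are processed in descending confidence, each taking its
highest-IoU unmatched ground-truth box at IoU >= 0.5. Greedy
confidence-ordered matching is the detector-evaluation standard; a test
verifies it agrees with exhaustive optimal assignment over 1,000 random
small instances. Average precision uses all-point interpolation (the
running-maximum precision envelope); framework defaults differ here
(some use 101-point interpolation), which is worth remembering when
comparing absolute AP values across toolchains. The confidence-threshold
tuner maximizes the unweighted mean of image-level accuracy, sensitivity
and specificity — "balancing" the three without a stated formula is
interpreted as equal weights — with ties resolved toward the lower
threshold (more sensitive operating point). Per-individual phenotypes
select one image per artery, preferring plaque-positive images with a
seeded random choice among several, and sum the two arteries' box counts.

## PCE scoring, eligibility, recalibration

The PCE coefficients (four sex-by-race-group strata, natural-log terms)
are shipped as a readable CSV with an md5 checksum verified at load,
because a transcribed guideline table should be auditable rather than
buried in code. Unknown or other ethnicity is scored with the white/other
equations. Eligibility is the closed-interval filter: age 40–79, total
cholesterol 130–320 mg/dL, HDL 20–100 mg/dL, SBP 90–200 mmHg; lipids in
mmol/L are converted at 38.67 mg/dL per mmol/L.

Because cohorts differ from the PCE derivation populations, the score is
recalibrated before use: a Cox model stratified by sex with the PCE log
hazard as its single covariate — specifically the *centered* linear
predictor `lp - mean_lp(stratum)`, the log relative hazard that enters
the PCE risk formula. Centering matters: the raw linear predictors of
different race-group equations sit ~116 units apart, an offset that is
meaningless across equations and would otherwise swamp the within-sex
slope — Breslow baseline
cumulative hazard per stratum, and absolute risk
`1 - exp(-H0(t0) exp(beta * lp))` at the horizon. Using the linear
predictor as a *covariate* rather than an offset makes the calibration
slope `beta` an explicit, reported diagnostic (a perfectly transportable
score gives slope 1). The default horizon is 80 months — the maximum
follow-up — although the risk-category threshold applied later (7.5%) is
defined for 10-year risk; this mismatch is reproduced deliberately, and
the horizon is configurable.

## Calibration assessment

The Greenwood–Nam–D'Agostino (GND) test groups participants into deciles
of predicted risk, estimates each group's observed risk as 1 - KM(t0)
with its Greenwood variance, and sums the standardized squared
discrepancies. Groups with fewer than 5 horizon events merge into their
upper neighbor. Because the predictions are externally supplied — nothing
is estimated from the grouped data — the statistic is referred to a
chi-square with one degree of freedom per group; a 500-replicate null
simulation in the test suite confirms the nominal type-I error at this
reference (a g-1 reference over-rejects). With a constant predictor the
decile cut degenerates; groups then fall back to equal-size rank chunks
so the statistic remains defined.

The integrated calibration index (ICI) is the mean absolute difference
between predicted risk and a smoothed observed-risk curve. Observed risk
per participant is a jackknife pseudo-observation of the event
probability at the horizon (computed analytically from risk-set counts,
`km_pseudo()`, verified against the brute-force leave-one-out jackknife),
smoothed against predicted risk with degree-1 loess (span 0.75). The
smoother choice is a pragmatic default: any local-linear smoother gives
the same consistency behavior, and the additive-miscalibration test
(ICI of a +0.05-shifted predictor is 0.05) pins the scale.

## Folding a marker into an absolute risk: the multiplication factor

Given a marker with levels k (reference first), level prevalences `p_k`
and hazard ratios `HR_k` (reference 1), the prevalence-weighted mean
relative risk is `[r] = sum_k p_k HR_k` (binary case
`p HR + (1 - p)`), and a baseline risk updates as

    R(k) = R_bl * HR_k / [r].

The printed source equation block for this method is typographically
garbled; this form is the unique reading consistent with its
multiplication-factor line `MF(+) = HR/[r]` and with exact conservation
of the population mean risk, `sum_k p_k R(k) = R_bl`, which the test
suite checks to machine precision. The multi-level generalization takes
`[r]` over all levels. Updated risks above 1 are capped with a warning
(conservation then no longer holds — the cap is a guard, not part of the
model). In the pipeline, prevalences are estimated per sex from the
PCE-eligible sub-cohort and hazard ratios from a Cox model on that
sub-cohort adjusted for sex, age, HDL and total cholesterol,
antihypertensive use, current smoking, SBP and statin use; estimating on
the eligible sub-cohort (rather than everyone) matches the population in
which the updated score is applied.

## Reclassification and discrimination under censoring

Participants are cases if they have an event by the horizon. For the
categorical table (7.5% threshold by default) two control conventions are
offered. Under `censored = "exclude"` controls are participants event-free
*at the horizon*, and those censored earlier carry no status and are
excluded with a logged count — the strict time-to-event convention. Under
`censored = "as_control"` every non-case is a control: this is the
binary-outcome convention of the classical reclassification-table tools,
and it is what published tables whose case/control totals exhaust the
whole cohort use, so the pipeline applies it when it reproduces a
published-style table. With per-person administrative censoring and a
horizon at the maximum follow-up, the strict convention would exclude
nearly all controls, which is why the distinction matters.
Categorical NRI is `(up_cases - down_cases)/n_cases +
(down_controls - up_controls)/n_controls`, with a percentile bootstrap CI
from multinomial resampling of the table cells.

The category-free NRI avoids thresholds: movement is any risk increase
or decrease, event probabilities within the up/down/unchanged groups are
estimated by 1 - KM(t0), and the group shares combine by Bayes' rule to
give `[P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)]`
in [-2, 2]. Without censoring this reduces exactly to the classical
binary formula (tested). Its CI uses the bootstrap standard error with a
normal approximation (1,000 resamples by default); the categorical NRI
uses percentile intervals — matching how each is conventionally reported.
The IDI is the difference in discrimination slopes, with fully observed
participants contributing as cases/controls and participants censored
before the horizon contributing fractionally through their conditional
KM event probability `1 - S(t0)/S(c_i)`; uncensored data again reduce to
the classical formula. A KM-based rather than
inverse-probability-of-censoring-weighted estimator was chosen for both
because it reduces exactly in the uncensored limit and requires no
censoring model.

Discrimination uses Harrell's C (ties count 1/2) via
`survival::concordance`, with paired individual-level bootstrap for the
C-difference between nested models.

## Survival primitives and delegation

Kaplan–Meier curves, log-rank tests, Cox partial-likelihood fits (Efron
ties — the common default; the tie-handling choice is otherwise
unconstrained here) and concordance are delegated to the `survival`
package behind thin wrappers that fix the contracts (months as the time
unit, right-continuous step lookup, named coefficient output).
Proportional-hazards diagnostics (scaled Schoenfeld residuals) are out of
scope. Time is measured in months throughout.

## Mendelian randomization estimators

For two-sample summary-statistics MR, each variant contributes a Wald
ratio `beta_out / beta_exp` with first-order delta-method standard error
`se_out / |beta_exp|` (exposure-side uncertainty ignored in the weights —
the conventional default). IVW is the inverse-variance weighted mean;
random effects inflate the SE by `max(1, sqrt(Q/(k-1)))` and never
deflate it. MR-Egger regresses outcome on exposure betas with a free
intercept after orienting exposure betas positive (the orientation
convention is documented because implementations differ), using
multiplicative random effects with no underdispersion. The weighted
median interpolates the inverse-variance-weighted median of ratios with
a parametric-bootstrap SE. Estimates for binary exposures are rescaled
per two-fold prevalence increment by multiplying by log 2 = 0.693.
Instruments are assumed independent — clumping for linkage
disequilibrium is an upstream, external step. All estimators are
invariant to joint sign flips of a variant's exposure/outcome betas
(tested).

## The pipeline, seeds and problem sizes

`run_pipeline()` chains synthesize → score → recalibrate → estimate
marker specs → update risks → calibration + reclassification +
discrimination → report bundle, with one global seed fanned out to
per-stage child seeds (`child_seed()`) so stages are reproducible when
run standalone; two runs with the same config produce byte-identical
numeric artifacts. The effective horizon is capped at the longest
observed follow-up in the eligible sub-cohort, since a baseline hazard
cannot be evaluated beyond the data.

Problem sizes used by the test suite were chosen to make the statistical
assertions sharp at desk scale: parameter-recovery checks use 200,000
synthetic participants (3-standard-error bands around the generating
hazard ratios), null-calibration checks use 500 simulation replicates
with binomial tolerance, and pipeline smoke tests use cohorts of a few
thousand with reduced bootstrap counts. Cohort-scale published
quantities that depend on the real data (absolute C-indices,
cohort cfNRI values, GWAS loci, MR estimates for specific exposures) are
not reproducible from synthetic marginals and are covered instead by the
exact-arithmetic and property-based checks above.

## Known limitations

* Independent covariate marginals understate the collinearity of real
  risk factors; recovered coefficients are therefore cleaner than they
  would be in practice.
* The exponential baseline hazard cannot exhibit the late acceleration of
  real cardiovascular hazards; only proportional-hazards summaries should
  be read off the synthetic cohort.
* The ICI smoother (loess, span 0.75) is one of several reasonable
  choices; absolute ICI values from different smoothers are not
  interchangeable, though orderings are stable.
* The categorical-table exclusion of early-censored participants and the
  KM-based cfNRI/IDI estimators are conventions; alternatives
  (IPCW-weighted estimators) would give slightly different numbers under
  heavy censoring.
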