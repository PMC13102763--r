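---
title: "From vital-sign trajectories to blood gas target ranges: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vital-sign trajectories to blood gas target ranges: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajtargets)
```

## The analysis this package implements

Critically ill patients — here motivated by sepsis with thrombocytopenia —
arrive in the ICU with heterogeneous physiology, and the *shape* of their
early vital-sign course carries prognostic information that a single
admission snapshot does not. `trajtargets` implements a three-stage
"trajectory-to-targets" analysis:

1. **Phenotype** patients by the joint trajectories of six vital-sign
   channels (HR, RR, SBP, DBP, MAP, SpO2) over the first 12 ICU hours,
   using group-based multi-trajectory modeling (GBMTM) — a finite mixture
   of polynomial regressions fitted by EM.
2. **Quantify risk** of the resulting subgroups with Cox
   proportional-hazards contrasts (crude, and two nested covariate sets)
   and covariate-adjusted survival curves.
3. **Derive targets**: within the highest-risk subgroup, model the
   dose–response of each blood gas parameter against ICU mortality with
   restricted cubic splines, then extract from random-forest partial
   dependence the contiguous value range with the lowest predicted risk —
   the "safe zone".

Because the motivating clinical data are credentialed and not
redistributable, the package ships a synthetic-cohort generator whose
latent structure is known exactly. Every stage is validated against that
ground truth; the generator is first-class, tested code.

## The trajectory model

Let $y_{ivt}$ be subject $i$'s standardized value of channel $v$ at hourly
bin $t \in \{0,\dots,11\}$. Conditional on latent group $g$,

$$y_{ivt} \mid g \sim \mathcal N\!\Big(\textstyle\sum_{p=0}^{P_{gv}}
\beta_{gvp}\, c(t)^p,\ \sigma_{gv}^2\Big),$$

with channels and hours conditionally independent given the group (the
standard multi-trajectory formulation; no within-subject residual
correlation), mixing proportions $\pi_g$, and $c(t) = t - 5.5$ the hour
index centered at the window midpoint for numerical conditioning. Fitted
curves are reported on the raw-hour axis, and in native units via the
inverse of the Z-score standardization.

The EM fit computes posteriors $w_{ig}$ in log space with a log-sum-exp
guard; the M-step is per-(group, channel) weighted least squares with
subject weights, a residual-variance update floored at $10^{-6}$ to
prevent degenerate spikes, and $\pi_g = \bar w_{\cdot g}$. Because every
subject shares the same time design, the weighted least squares reduces to
ordinary least squares on the weighted mean profile, which makes the fit
fast and exactly reproducible. Initialization is k-means on the flattened
72-dimensional grids; additional starts perturb the k-means centers with
Gaussian noise, all seed-controlled. The observed-data log-likelihood is
non-decreasing along the trace (an invariant the tests exercise), and the
best of `n_starts` runs is kept.

**Model selection.** Candidate group counts 1–6 are compared by BIC
($-2\ell + k\log N$, $N$ = subjects), with eligibility requiring relative
entropy $> 0.7$ (for $K \ge 2$) and every modal group share $\ge 5\%$;
ties prefer the smaller $K$. Relative entropy is
$1 - \sum_{ig} (-w_{ig}\log w_{ig})/(N\log K)$; for $K = 1$ it is defined
as 1 (classification is vacuous). Polynomial orders start cubic and are
pruned per (group, channel) by backward elimination: the highest-order
coefficient with Wald $p \ge 0.05$ (from the weighted-least-squares
covariance of the final M-step) is decremented and the model refitted, at
most 10 rounds, never below linear. Per-(group, channel) pruning is the
more general reading of per-trajectory elimination and nests a shared-order
scheme. Classification adequacy is reported as AvePP (mean posterior among
modally assigned subjects, adequate above 0.7) and OCC (posterior odds of
correct assignment over prior odds, adequate above 5).

## Survival contrasts

Cluster membership (modal assignment) enters a Cox model as indicator
contrasts against the reference cluster — the one with the *lowest* ICU
mortality, mirroring the low-risk reference convention. Three covariate
sets are reported: crude; Model 1 (age, sex); Model 2 (Model 1 + SOFA,
APS-III, invasive ventilation, CRRT, RRT), at the ICU, 28-, 90- and
365-day horizons. Ties are handled by the Efron method: the synthetic
outcomes are day-resolution, so ties are ubiquitous and Efron is less
biased than Breslow (the method is switchable). Fitting is delegated to
`survival::coxph`; an independent brute-force partial-likelihood grid
search backs it in the tests.

Covariate-adjusted survival curves use the corrected-group-prognosis
method: fit Cox with cluster indicators plus age, sex and race, then for
each cluster average the predicted curve over the *full* cohort's
covariate distribution with that cluster forced on. "Stratified by age,
sex, and race" is read as covariate adjustment (continuous age) rather
than stratified baseline hazards. Pointwise bands come from a seeded
nonparametric bootstrap (200 resamples by default, configurable).

The ICU-mortality time axis is days from ICU admission to ICU death,
censored at ICU discharge.

## Dose–response and safe zones

Within the high-risk cluster (highest modal-assignment ICU mortality —
chosen by observed mortality, not by the Cox point estimate, to avoid
circularity), each blood gas parameter is modeled two ways:

- **Restricted cubic splines** in a Cox model of ICU mortality adjusted
  for age, sex and SOFA. The basis follows the Harrell convention — linear
  term plus $k-2$ truncated-cubic terms that vanish below the first knot
  and are linear beyond the last — with 4 knots at the (0.05, 0.35, 0.65,
  0.95) quantiles by default (3 or 5 knots available). The hazard-ratio
  curve is $\exp\{\hat f(x) - \hat f(x_{\mathrm{ref}})\}$ with
  delta-method bands, anchored at the within-cluster median. Nonlinearity
  is a joint Wald test of the $k-2$ nonlinear coefficients; no
  multiplicity correction across the six parameters by default (matching
  per-parameter presentation; a Bonferroni switch exists).
- **Random forests** (one per parameter, clinical covariates plus that
  parameter — reconciling the univariate presentation with
  covariate-informed prediction): probability forests tuned by seeded
  five-fold cross-validation maximizing AUROC. Partial dependence
  $\mathrm{PD}(x) = N^{-1}\sum_i \hat f(x, z_i)$ is evaluated on a
  50-point grid clipped to the within-cluster 1st–99th percentiles (so
  outliers cannot drive extrapolated zones).

The **safe zone** is operationalized as: with
$\tau = \mathrm{PD}_{\min} + \delta\,(\mathrm{PD}_{\max} -
\mathrm{PD}_{\min})$, the maximal contiguous grid run containing the
global PD minimizer (leftmost on ties) with $\mathrm{PD} \le \tau$. The
fraction $\delta = 0.2$ defines "lowest range of predicted risk"; it is a
first-class knob recorded in every report, and zone width is monotone in
it. Zones are descriptive model summaries, hypothesis-generating rather
than causal targets.

## What the synthetic generator emulates

`default_scenario()` encodes the study conditions: three latent groups
mixed 24/35/41 percent, with mean trajectories reproducing the qualitative
cluster signatures — group 1 hypertensive (SBP ≈ 165 mmHg, elevated
DBP/MAP), group 2 hyperdynamic and hypoxic (HR ≈ 118, RR ≈ 30, SpO2 ≈ 89,
with a 1.5-fold hazard), group 3 hypotensive with high SpO2 (the low-risk
reference). Residual SDs (HR 6, RR 2.5, SBP 8, DBP 6, MAP 6, SpO2 1.5)
give every pair of groups at least 2 residual SDs of separation in some
channel at the window midpoint. Raw vitals are emitted at 2–4 jittered
observations per hour (the sampling frequency of bedside monitors before
hourly averaging is not standardized; this default is configurable), so
hourly aggregation is non-trivial; emitted values saturate at the
plausibility bounds (SpO2 caps at 100%).

Outcomes follow one latent mechanism per horizon family:

- A latent **Weibull** death time (shape 1.1, scale 700 days) with
  proportional hazards in the group effect drives the 28/90/365-day
  outcomes, so the configured hazard ratio (1.5 for the high-risk group)
  is the exact estimand. Weibull sampling is inverse-CDF, giving
  closed-form, seedable draws. Censoring is administrative at the horizon
  plus a 10% uniform early-censoring fraction. The covariate log-hazards
  default to zero so that the group contrast is exact at every adjustment
  level; they are configurable for confounding studies.
- The **ICU stay** is a pair of competing exponential risks sharing the
  same latent uniform: death with hazard $\lambda\,e^{\mathrm{lp}}$ and
  discharge with hazard $\lambda$ (mean stay 7 days). This makes the ICU
  death probability *exactly* logistic in
  $\mathrm{lp} = \alpha + \theta_g + \beta_a(\text{age}-65) +
  \beta_s(\text{SOFA}-6) + \sum_p s_p d_p(x_p)$, and the cause-specific
  death hazard exactly proportional — the structure the spline and
  safe-zone stages estimate. The gas excess $d_p$ is zero inside each
  parameter's low-risk interval $[a_p, b_p]$ (default mean ± 1.2 SD) and
  grows linearly with the distance outside it in SD units (slopes
  0.7–0.9 per SD on the logit, i.e. roughly a doubling of odds 1 SD
  beyond the interval — clinically plausible for lactate- or pH-sized
  derangements).

Blood gas values are contaminated normals (3% inflated-SD component,
matching the heavy tails of real laboratory values), independent across
parameters so that per-parameter safe-zone truth stays well-defined.
Missingness is injected per subject-channel-hour cell (default 3%), plus
a 2% fraction of subjects receiving one run of ≥ 5 consecutive missing
hours (which the preprocessing rules must exclude); 0.5% of observations
are replaced by implausible outliers. Truth labels live in a separate
sidecar structure and are never joined into analysis inputs.

What the generator does **not** emulate: the marginal distributions of any
real ICU population (age mixes, comorbidity prevalence), correlated blood
gas panels, informative missingness, or treatment feedback. Passing tests
therefore demonstrate that the *machinery* recovers known structure under
realistic noise — not that real data meet the model's assumptions.

## Preprocessing protocol and its conventions

The order is fixed: plausibility filter → winsorization → hourly
aggregation → imputation/exclusion → standardization.

- **Plausibility** bounds are inclusive and config-overridable; defaults
  follow common critical-care QC practice: HR [20, 250] bpm, RR [4, 60]
  /min, SBP [40, 300], DBP [20, 200], MAP [30, 250] mmHg, SpO2 [50, 100]%.
- **Winsorization** at the 1st/99th percentiles is applied to *raw
  observations* per channel, before hourly averaging, so a single
  artifactual spike cannot contaminate an hourly mean (applying it to
  hourly means instead is a documented sensitivity choice). The quantile
  convention is linear interpolation between order statistics, stated
  explicitly because the clipped values depend on it: on the grid
  0..100 the result is exactly [1, 99]. Re-applying the stage with its
  stored bounds is exactly idempotent (recomputing quantiles on clipped
  continuous data can shift the interpolated cutpoints marginally, so the
  bounds are part of the stage's output).
- **Aggregation** uses half-open bins $[h, h+1)$; hour 0 is admission.
- **Imputation** rule priority, where the written protocol is ambiguous:
  interior gaps of 1–2 h with observed neighbors on both sides are
  linearly interpolated; longer interior runs (3–4 h) and trailing runs
  carry the last observation forward; leading runs carry the first
  observation *backward* (LOCF cannot fill hour 0; the symmetric rule is
  the natural completion). Any run of *more than 4* consecutive missing
  hours on *any* channel excludes the subject (the conservative
  any-channel reading), reason-coded `long_gap`; a channel never observed
  codes `empty_channel`. Observed cells are never altered.
- **Standardization** pools mean and SD per channel over all retained
  subject-hours; parameters are returned for inverse transforms.

Cohort-table variables with more than 30% missingness (strict) are dropped
by a column filter with protected identifier/outcome columns.

## Numerical and design choices

- All randomness flows from one root seed through a documented per-stage
  derivation (`derive_seeds`), so a full pipeline run is byte-identical
  under a fixed seed; forests run single-threaded for determinism.
- EM convergence is $|\Delta\ell| <$ `tol` (default $10^{-6}$) or 200
  iterations; a vanishing component weight ($\sum_i w_{ig} < 10^{-6}$)
  aborts with advice to reduce $K$; non-convergence returns a flagged fit
  with a warning.
- Modal-assignment ties go to the lowest group index; safe-zone minimizer
  ties go leftmost; tuning-grid AUROC ties keep the first grid row.
- Flat PD profiles return the full grid span with a warning; `delta = 0`
  collapses the zone onto the minimizer.
- The consensus-clustering variant sometimes described alongside
  BIC-based selection is not implemented; selection follows the
  BIC/entropy/minimum-share rule exactly.

## Problem sizes used in validation

The shipped validation suite exercises: likelihood ascent over 50 random
draws; 20-seed trajectory recovery at $n = 600$ (label accuracy,
mixing recovery, BIC-chosen $K$, adequacy thresholds); 100-case
brute-force equivalence for the diagnostics; hand-computed preprocessing
oracles; a 200-replicate hazard-ratio recovery study at $n = 2000$
(bias and CI coverage); nonlinearity-test calibration under linear truth
(1,000 simulations, $n = 800$) and power under a strong U-shape (200
simulations, $n = 1000$); 20-seed safe-zone recovery at $n = 2000$
against the generative intervals (median Jaccard overlap); and full
byte-level pipeline reproducibility. These sizes were chosen so the whole
suite runs comfortably on a single CPU while keeping every check
statistically meaningful.

## Known limitations

- Pooled winsorization interacts with trajectory shape: clipping a
  *trending* channel at fixed cohort-wide percentiles removes more mass at
  the hours where the trajectory is most extreme, which can bend a truly
  linear group trajectory slightly and lead backward elimination to retain
  a low-order curvature term. This is a property of the preprocessing
  protocol itself, worth a sensitivity analysis when order parsimony
  matters.
- Conditional independence across channels given group ignores residual
  within-subject correlation; strongly correlated channels (SBP/MAP) can
  make posteriors overconfident.
- Safe zones inherit the random forest's smoothing: very sparse tails can
  stretch a zone toward regions with little data, which the percentile
  clipping only partly mitigates.
- The Wald nonlinearity test is asymptotic; at small within-cluster event
  counts its size can drift.
- No multiple imputation, no time-varying covariates, no competing-risks
  decomposition beyond the ICU discharge mechanism, and no causal claims:
  zones are descriptive summaries of a predictive model.
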