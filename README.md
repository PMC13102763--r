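# trajtargets

Early-ICU phenotyping from vital-sign trajectories, and model-derived blood
gas target ranges for the high-risk phenotype.

## What this solves, and for whom

Critically ill patients — the motivating population is sepsis with
thrombocytopenia — are physiologically heterogeneous, and the *shape* of
their first hours of vital signs carries prognostic information that an
admission snapshot misses. For biostatisticians and intensive-care
researchers working with longitudinal EHR extracts, `trajtargets`
implements a complete "trajectory-to-targets" analysis:

1. **Trajectory phenotyping.** Group-based multi-trajectory modeling
   (GBMTM): a finite mixture of polynomial regressions fitted jointly over
   six vital-sign channels (HR, RR, SBP, DBP, MAP, SpO2) aggregated hourly
   over the first 12 ICU hours and Z-score standardized,

   y<sub>ivt</sub> | group g ~ N( Σ<sub>p</sub> β<sub>gvp</sub> c(t)<sup>p</sup>, σ²<sub>gv</sub> ),

   estimated by EM with log-sum-exp-guarded posteriors w<sub>ig</sub>,
   mixing proportions π<sub>g</sub>, k-means-based multi-start, BIC/AIC
   model selection with entropy (> 0.7) and minimum group share (≥ 5%)
   eligibility, backward elimination of polynomial orders, and
   AvePP / OCC classification diagnostics.
2. **Subgroup mortality risk.** Cox proportional-hazards contrasts of the
   clusters against the lowest-risk reference (crude; age + sex; plus
   SOFA, APS-III, ventilation, CRRT, RRT) at the ICU, 28-, 90- and 365-day
   horizons, with Efron ties; covariate-adjusted survival curves by
   corrected group prognosis with bootstrap bands.
3. **Dose–response and safe zones.** Within the highest-ICU-mortality
   cluster: restricted cubic spline (Harrell basis) Cox models of each
   blood gas parameter (pH, PO2, PCO2, lactate, base excess, total CO2)
   with a joint Wald nonlinearity test; random-forest mortality models
   (5-fold CV tuned) whose univariate partial dependence yields the
   "safe zone" — the contiguous value range containing the risk minimizer
   with PD ≤ PDmin + δ·(PDmax − PDmin), δ = 0.2.

Because the motivating data are access-restricted, the package includes a
seeded synthetic-cohort generator with exactly known latent structure
(three trajectory groups, group-proportional Weibull hazards, exactly
logistic ICU mortality with U-shaped blood gas excess risk, missingness
and outlier injection). Every stage is validated against that ground
truth. See the methods vignette
(`vignettes/trajectory-to-targets.Rmd`) for models, conventions and
limitations.

## Worked example

```r
library(trajtargets)

cfg   <- default_scenario(n_subjects = 400, seed = 7)  # 3 latent groups, 24/35/41%
sim   <- simulate_cohort(cfg)                          # vitals + cohort + truth sidecar
grids <- preprocess_vitals(sim$vitals)                 # filter, winsorize, bin, impute, scale
fit   <- gbmtm(grids, K = 3, seed = 7)                 # EM multi-trajectory fit
summary(fit)
```

```
Group-based multi-trajectory model (3 groups, 6 channels, 12 hourly bins)
  log-likelihood 6114.52 on 92 parameters (N = 400)
  BIC -11677.8  AIC -12045.0  converged after 3 iterations
  mixing proportions: 0.287 0.407 0.305
  relative entropy 1.000
 group  share AvePP OCC
     1 0.2875     1 Inf
     2 0.4075     1 Inf
     3 0.3050     1 Inf
```

The three groups are recovered crisply (entropy 1.0; every AvePP = 1, so
the odds of correct classification are unbounded), with mixing close to
the generator's 0.24/0.35/0.41. `plot(fit)` draws the fitted group-mean
trajectories per channel in native units;
`predict(fit, type = "trajectory")` returns them as an array.

The full pipeline — selection over K, order pruning, Cox contrasts,
adjusted curves, splines, forests, zones — is one call:

```r
res <- run_trajectory_pipeline(default_scenario(n_subjects = 400), seed = 7,
                               K_range = 1:4, n_starts = 2, boot = 20,
                               rf_spec = risk_model_spec(trees = 200, min_node = 20))
res
```

```
trajectory-to-targets pipeline run
  subjects: 400 input, 392 retained, 8 excluded
  chosen K = 3; high-risk cluster 3 (reference 1)
  safe zones:
     ph 7.40–7.50
     po2 76.31–118.86
     pco2 24.46–50.20
     lactate 0.27–1.45
     base_excess -8.25–-1.70
     total_co2 23.44–25.93
```

Eight subjects were excluded by the >4-consecutive-missing-hours rule; the
selection table (`res$selection`) shows the BIC drop from K = 2 to K = 3
and the eligibility diagnostics; the crude 365-day contrast for the
high-risk cluster is HR 1.60 (1.12, 2.28) against its reference
(`res$cox[["365_crude"]]`). At this deliberately small n the safe zones
are noisy; at n = 2000 their median Jaccard overlap with the generator's
true low-risk intervals exceeds 0.7 (the validation suite checks this).
`pipeline_report(res)` renders a markdown summary with every adequacy
threshold, and passing `out_dir =` writes all stage tables plus a
reproducibility manifest.

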