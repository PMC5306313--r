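# cttasurv

Filtration-histogram CT texture analysis (CTTA) with survival
stratification, for imaging researchers who want to ask whether lesion
heterogeneity on routine low-dose CT predicts progression-free survival
(PFS) — on its own and jointly with interim FDG-PET (iPET) status — in
lymphoma-style cohorts.

## What it computes

**Texture.** A lesion is a 2-D HU grid `a(x,y)` with pixel spacing in mm
and a binary ROI `R` (n pixels), automatically refined by removing gas
pixels below −50 HU. The image is band-pass filtered with a
Laplacian-of-Gaussian kernel at spatial scale filters (SSF) of 2–6 mm
feature radius (σ = SSF/√2, zero-sum kernel, mirror boundary; SSF = 0 is
the unfiltered control), and the in-mask histogram is summarized by the
bias-corrected sample excess kurtosis

    k = n(n+1) Σ (a − ā)⁴ / [(n−1)(n−2)(n−3) sd⁴] − 3(n−1)² / [(n−2)(n−3)]

which is affine-invariant, ≈0 for Gaussian histograms, and inversely
related to the number of features the filter highlights.

**Cohort.** Up to five most FDG-avid lesions per patient are averaged into
patient-level markers; the best scale is picked by Mann–Whitney separation
of progressed vs non-progressed patients (exact enumeration with ties for
small groups, tie-corrected normal approximation otherwise).

**Survival.** Each of seven markers (iPET, CTTA kurtosis, SUVmax, type,
stage, treatment, bulk) is dichotomized at its optimized Kaplan–Meier
threshold (minimum log-rank p over candidate splits) with restricted mean
survival per group; the family is corrected by the Benjamini–Hochberg
step-up at FDR 0.05 (critical values i·q/m); significant markers enter a
Cox model with pairwise interactions and backward elimination; and the
CTTA×iPET product defines three risk tiers — iPET−/low-kurtosis (lower),
iPET−/high-kurtosis (intermediate), iPET+ (higher) — whose contrast is
reported as a hazard ratio with 95% CI.

A synthetic module generates blob phantoms and whole seeded cohorts
(latent texture classes, iPET status, exponential tier hazards, 10–62
month administrative censoring), so the entire pipeline runs and is tested
without any clinical data. See the methods vignette
(`vignettes/filtration-histogram-ctta.Rmd`) for the model, conventions and
limitations.

## Worked example

```r
library(cttasurv)

co  <- generate_cohort(cohort_spec(n_patients = 45, imaging = "phantom",
                                   seed = 9))
run <- run_pipeline(cohort = co, out_dir = "demo_out")
print(run)
```

```
cttasurv pipeline run (45 patients)
best texture scale: SSF=6 mm (Mann-Whitney p=0.0124)

Univariate optimized KM + Benjamini-Hochberg:
         label threshold n_above n_below mean_surv_above mean_surv_below
   iPET status      0.50       7      30            20.0            48.7
 CTTA kurtosis      2.17      27      18            36.0            45.7
        SUVmax     22.23      17      28            33.9            48.2
 Bulk (pixels)  11030.00       7      38            52.4            40.6
         Stage      1.50      42       3            44.5            26.4
 Lymphoma type      0.50      24      21            41.2            42.4
     Treatment      0.50      38       7            42.9            41.8
 p_logrank bh_critical significant
   0.00342     0.00714        TRUE
   0.01200     0.01429        TRUE
   0.06759     0.02143       FALSE
   0.13794     0.02857       FALSE
   0.21015     0.03571       FALSE
   0.52615     0.04286       FALSE
   0.67665     0.05000       FALSE

Cox proportional-hazards fit: n = 37, events = 11, loglik = -27.80
...
Final model:
                  term log_hr hazard_ratio ci95_low ci95_high  p_wald
 ipet_high_x_ctta_high   1.62         5.05     1.52      16.8 0.00824

CTTA x iPET tier contrast: HR = 5.1 (95% CI 1.5-16.8, p = 0.00824)

Risk tiers (restricted mean PFS):
  lower        n = 15, mean PFS 48.9 months
  intermediate n = 15, mean PFS 39.3 months
  higher       n =  7, mean PFS 20.0 months
```

Reading this: only iPET and the CTTA kurtosis survive the BH correction
(their raw p fall under the rank-wise critical values 0.007 and 0.014);
backward elimination leaves the CTTA×iPET interaction as the sole
predictor (here the iPET main effect is exactly aliased with the product
because every iPET-positive patient has high kurtosis, and the aliasing is
resolved in favour of the interaction); and the three tiers show strictly
ordered restricted mean PFS. Patients without an iPET result (8 here) are
excluded from iPET-dependent models and tiers, but kept everywhere else.

The same analysis is scriptable from the shell:

```sh
Rscript inst/cli/cttasurv.R simulate --out demo_cohort --seed 9
Rscript inst/cli/cttasurv.R run --lesions demo_cohort/lesions.csv \
    --clinical demo_cohort/clinical.csv --out demo_out
```

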