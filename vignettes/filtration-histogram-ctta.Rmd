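---
title: "Filtration-histogram CT texture analysis and survival stratification with cttasurv"
author: "cttasurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram CT texture analysis and survival stratification with cttasurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cttasurv)
```

## The problem

Low-dose CT acquired as part of routine FDG-PET-CT carries quantifiable
information about tumour heterogeneity that visual reading discards. In
lymphoma, interim PET (iPET) after 2-4 chemotherapy cycles is the established
early prognostic marker for progression-free survival (PFS), but most
iPET-negative patients are left in a single "good prognosis" bucket even
though some of them relapse. `cttasurv` implements a complete
filtration-histogram CT texture analysis (CTTA) pipeline that (i) quantifies
lesion heterogeneity as excess kurtosis after Laplacian-of-Gaussian (LoG)
band-pass filtration at named spatial scales, (ii) aggregates lesion
measurements to patient-level markers, and (iii) asks whether the texture
marker risk-stratifies patients — on its own and jointly with iPET — using
optimized Kaplan-Meier thresholds, false-discovery-rate control and Cox
modelling with a CTTA-by-iPET interaction.

No patient images ship with the package. Instead, a first-class synthetic
module generates blob phantoms and whole simulated cohorts with the
statistical structure the analysis assumes, so every stage is exercised
end-to-end by the test suite.

## The texture statistic

A lesion is a 2-D grid of attenuation values $a(x,y)$ in Hounsfield units
(HU) on the axial slice with the largest lesion cross-section, with an
isotropic in-plane pixel spacing in mm, plus a binary region of interest
(ROI) $R$ with $n$ pixels. Freehand ROIs routinely clip bowel gas or air;
the pipeline therefore refines every ROI by removing pixels below
$-50$ HU (`auto_contour()`, threshold configurable), and all statistics use
the refined mask. Applying the refinement twice changes nothing
(idempotence), and a fully excluded ROI is reported as unanalyzable rather
than silently producing numbers.

Heterogeneity at a *spatial scale* is measured in two steps:

1. **Filtration.** The whole image is convolved with a 2-D LoG kernel tuned
   to highlight blob-like features of a nominal radius (the *spatial scale
   filter*, SSF): fine $\approx 2$ mm, medium $3$-$5$ mm, coarse $\approx 6$
   mm; scale 0 denotes the unfiltered control. Filtering the full grid and
   only then sampling in-mask pixels lets peri-lesional context contribute
   to the convolution, as it does in practice.
2. **Histogram analysis.** The in-mask values are summarized by the
   bias-corrected sample excess kurtosis
   $$k \;=\; \frac{n(n+1)\sum_{(x,y)\in R}\bigl[a(x,y)-\bar a\bigr]^4}
   {(n-1)(n-2)(n-3)\,sd^4} \;-\; \frac{3(n-1)^2}{(n-2)(n-3)},$$
   with $\bar a$ and $sd$ the sample mean and standard deviation over $R$.
   $k$ is zero in expectation for Gaussian data, positive for spiky
   heavy-tailed histograms, negative for flat ones, and invariant under
   affine intensity maps $a \mapsto \alpha a + \beta$. The denominators
   require $n \ge 4$ and $sd > 0$; smaller or constant histograms raise
   classed conditions, and `compute_texture_profile()` records such scales
   as missing instead of aborting the lesion.

Mechanistically, kurtosis after filtration is inversely related to the
number of objects the filter highlights, and increases with their contrast:
a lesion with a few large high-contrast features is "spikier" at the
matching scale than one with many small faint features. The test suite
verifies this monotone relationship on matched phantoms (Spearman
correlation of kurtosis with blob count over 3-48 blobs is negative with
$p < 0.01$).

### Mapping the scale to a kernel

The scale is published as a feature *radius* in mm, not a Gaussian width, so
a convention is needed. We set $\sigma_\text{mm} = \text{SSF}/\sqrt{2}$,
which places the LoG zero-crossing circle exactly at the nominal radius and
maximizes the response to a Gaussian blob of that nominal size;
$\sigma_\text{px} = \sigma_\text{mm}/\text{spacing}$. The kernel is
truncated at $4\sigma$ (odd support), recentred so its entries sum to
exactly zero — making the filter exactly DC-invariant, which the tests
assert both as a kernel property and as a null response to constant images —
and applied with mirror (reflective) boundary padding so image borders do
not inflate tail pixels. Convolution is computed by FFT on the padded grid,
which is exactly linear convolution with that boundary rule; a dense
quadruple-loop convolution serves as the independent oracle in the tests.
A scale finer than one pixel is refused (`scale-too-fine`), and a kernel
larger than the image is an error rather than an approximation.

Two caveats are deliberate. The $\sigma \leftrightarrow$ SSF convention of
the proprietary tool that popularized this analysis is unpublished, so
numerical equality with it is not claimed — the convention here is stated,
configurable (`trunc_sigmas`, erosion radius), and fixed by tests. And
whether the unfiltered control should use the gas-refined mask or the raw
ROI is ambiguous in the field; the refined mask is used everywhere for
consistency.

Filtered responses whose spread is numerically zero (below $10^{-9}$ of the
raw ROI contrast, far beneath CT quantization) are treated as degenerate
histograms, so a constant lesion reports every scale missing instead of
analysing floating-point residue.

## From lesions to patients

Patients present multiple lesions; up to five per patient are used,
selected as the most FDG-avid (highest lesion SUVmax), with SUV ties at the
cap broken toward the lexicographically smaller lesion id so selection is
deterministic. The patient-level marker at each scale is the arithmetic
mean over the used lesions, computed over available cases when a scale is
missing in some lesion; SUVmax is averaged the same way and tumour bulk is
the summed lesion area in pixels. `build_patient_markers()` emits one row
per patient.

The best texture scale is chosen by a Mann-Whitney comparison of each
scale's patient values between progressed and non-progressed patients,
taking the scale with the smallest two-sided p (ties toward the smaller
scale). `mann_whitney()` uses midranks for ties; for groups of at most 8 it
enumerates all group assignments exactly (ties included), otherwise it uses
the normal approximation with tie-corrected variance and no continuity
correction. Both paths are exposed for testing; the exact path is checked
against an independent enumeration oracle and the asymptotic path against
`stats::wilcox.test(exact = FALSE, correct = FALSE)`. Its type-I error at
$\alpha = 0.05$ is verified to sit within 1.5 percentage points of nominal
over 10,000 null pairs at $n = 15/15$.

## Survival stratification

Seven markers form the univariate family: iPET status, the selected CTTA
kurtosis, SUVmax, lymphoma type, stage, treatment regime and bulk. Each is
dichotomized at its *optimized Kaplan-Meier* threshold: candidates are the
midpoints between consecutive distinct marker values, each split must leave
at least `min_group` patients per side, and the threshold minimizing the
two-group log-rank p is chosen (ties toward the smaller threshold; the
dichotomy is "above threshold" versus "at or below"). Mean survival per
group is reported as the restricted mean — the area under the Kaplan-Meier
curve up to the largest observed time in that group — which is how clinical
tables usually report "mean survival in months".

Minimum-p searching is intentionally anti-conservative: under a global null
its rejection rate at nominal 0.05 is far above 0.05, a property the test
suite measures over 1,000 null simulations rather than hides. Two controls
address it. Across the marker family, the Benjamini-Hochberg step-up
procedure holds the false discovery rate at $q = 0.05$: the critical value
at rank $i$ of $m$ is $iq/m$ (for $m = 7$: 0.007, 0.014, 0.021, 0.029,
0.036, 0.043, 0.050 at 3 decimals) and all hypotheses up to the largest
rank with $p_{(i)} \le iq/m$ are rejected. Within a marker, the default
`min_group = 3` suits pilot-sized cohorts (about 7% of 45 patients); for
larger cohorts we recommend — and the package's own large-simulation
analyses use — a proportional floor of 10% of patients per side, the usual
constraint for minimum-p threshold searches, because with a fixed floor of
3 the search at $n = 150$ can latch onto extreme splits of a handful of
early progressors. P-values quoted below a reporting limit (e.g. "<0.001")
enter the correction at half the bound.

Markers surviving the correction enter a Cox proportional-hazards model
(partial likelihood, Efron tie handling by default with Breslow as an
option), dichotomized at their thresholds, together with their pairwise
product terms. Backward elimination removes the largest Wald $p \ge 0.05$
term and refits until all remaining terms are significant; the full model
is always reported alongside the reduced one. Three numerical policies
matter here:

* constant columns are dropped with a flag;
* exactly aliased columns are resolved *in favour of the interaction term*.
  This situation is not hypothetical: when every iPET-positive patient has
  high kurtosis — the configuration the three-tier model describes — the
  CTTA-by-iPET product column exactly duplicates the iPET column. The two
  parametrizations have identical likelihoods, so keeping the interaction is
  a relabelling, and it matches how the surviving predictor is reported
  clinically;
* monotone likelihood (e.g. a zero-event cell) is flagged as an unstable
  fit; during elimination such terms carry Wald $p \approx 1$ and exit
  first, which is the desired behaviour.

Because the headline of the analysis is the joint CTTA/iPET structure, the
pipeline always also fits the *tier contrast*: the product term alone,
i.e. the hazard of the (CTTA-high, iPET-positive) cell against everyone
else. This is the reduced model in which the interaction is the sole
surviving predictor, and it is the number to quote for the three-tier
stratification:

* iPET-negative, low kurtosis: **lower risk**;
* iPET-negative, high kurtosis: **intermediate risk**;
* iPET-positive (any kurtosis): **higher risk**.

Patients without an iPET result are kept for all texture-only analyses and
excluded (with a log line) from iPET-dependent models and tier assignment.

## What the synthetic data emulate — and what they do not

`generate_phantom()` renders a soft-tissue disc (default 40 HU background
on a 64-80 pixel grid at 0.98 mm spacing, the in-plane resolution of a
512-pixel, 400-mm field of view) containing Gaussian-profile blobs with
controllable count, nominal radius, signed contrast, plus white noise and
an optional sub-$-50$ HU gas pocket. Gaussian bumps rather than hard discs
keep the LoG response smooth and analytically predictable; a blob of
nominal radius $r$ mm has profile width $\sigma_b = r/\sqrt 2$, so the SSF
$= r$ filter matches it best. Blob centres are placed by rejection sampling
with a minimum separation of one blob diameter; an impossible packing
raises `overcrowded-spec` after bounded retries. A fixed seed gives
bit-identical phantoms.

`generate_cohort()` draws whole cohorts: lymphoma subtype (Hodgkin fraction
18/45), an underlying iPET status (positive with probability 7/37 among
measured, missing with probability 8/45), a latent texture class, 1-5
lesions per patient with subtype-dependent lognormal SUVmax (medians
qualitatively 13 vs 21 for Hodgkin vs non-Hodgkin; no distributional
fidelity claimed), and PFS from an exponential hazard set by the
(iPET, class) tier, censored administratively at a uniform 10-62 month
follow-up. The tier hazards default to 40-month progression probabilities
of 0.02 / 0.30 / 0.70 for lower / intermediate / higher. The lower tier is
deliberately *near*-zero rather than exactly zero: observing no relapses in
a small lower-risk group is entirely consistent with a small positive
hazard, and an exactly zero hazard makes any log-hazard model degenerate.
The latent class is high-kurtosis with probability 16/30 in iPET-negative
patients and 1 in iPET-positive ones, encoding the clinical observation
that interim-positive patients carry the highest pre-treatment kurtosis —
this is what makes the product term the natural surviving predictor.

Two imaging modes trade realism for speed. In `imaging = "phantom"` every
lesion is rendered and measured through the full texture stack (few large
high-contrast blobs for the high-kurtosis class, many small faint ones for
the low class), so a cohort run exercises every module; this is the default
and is used at the pilot scale ($n = 45$). In `imaging = "marker"`,
per-lesion kurtosis is drawn directly from class-conditional normals
calibrated so that the separation is strongest at SSF = 5 mm (class means
$-0.16$ vs $2.18$, per-lesion sd 0.9) and weaker elsewhere; this fast path
powers the larger simulation studies ($n = 150$, dozens to hundreds of
replicates).

The simulators emulate the *statistical* structure the analysis assumes and
nothing more. They do not model CT physics (beam hardening, correlated
reconstruction noise, slice-averaging), 3-D lesion geometry, PET images, or
reader variability in ROI placement. Passing tests therefore demonstrate
that the pipeline's machinery is correct and recovers known structure at
realistic sizes — not that the clinical effect sizes would replicate on any
particular scanner or population.

## Problem sizes used by the test suite

All stochastic checks fix their seeds. The main studies are: kurtosis
oracle agreement on 100 random samples ($n \in [4, 500]$); filter oracle
agreement on full grids; the blob-count mechanism on 100 matched phantom
pairs (3 vs 30 blobs) and a 50-phantom monotonicity study; cutpoint
recovery on 100 two-cluster cohorts ($n = 60$, four-fold hazard, ~20%
censoring); Cox interaction recovery over 200 replicates at $n = 300$
(~30% censoring) with null CI coverage over 200 replicates at $n = 200$;
Mann-Whitney null calibration over 10,000 pairs; the minimum-p
anti-conservatism study over 1,000 null cohorts; and 40 end-to-end
three-tier cohorts at $n = 150$ checking strictly ordered tier restricted
means and an adverse (HR > 1, $p < 0.05$) tier contrast.

## Worked example

```{r example, eval = FALSE}
library(cttasurv)

co  <- generate_cohort(cohort_spec(n_patients = 45, imaging = "phantom",
                                   seed = 9))
run <- run_pipeline(cohort = co, out_dir = "demo_out")
print(run)
plot(run)   # per-tier Kaplan-Meier curves
```

The run writes `patient_markers.csv`, `scale_selection.csv`,
`markers_survival.csv` (the seven-marker table with thresholds, restricted
means, raw and BH-corrected decisions), `cox_full.csv` / `cox_final.csv` /
`cox_tier_contrast.csv`, `tiers.csv`, `km_curves.csv`, a `MANIFEST.txt`
with per-stage status and a `run_log.txt` echoing the configuration. The
same pipeline is available from the shell via the shipped subcommand script
(`inst/cli/cttasurv.R`: `simulate`, `texture`, `cohort`, `survival`,
`run`), with exit codes 0 / 2 / 3 / 4 for success, configuration, I/O and
statistical-stage failures.

## Known limitations

* 2-D analysis of the single largest-cross-section slice; no 3-D texture.
* Kurtosis is the only histogram statistic; mean, entropy, skewness and
  positive-pixel variants are out of scope.
* The optimal-cutpoint p-value is anti-conservative by construction; only
  the family-level BH decision and the Cox models are interpretable as
  hypothesis tests.
* CTTA enters the Cox model dichotomized at its optimized threshold (the
  tier definition requires a binary texture state); a continuous coding is
  not provided.
* Pilot-scale cohorts ($n \approx 45$, ~10 events) produce unstable full
  Cox models when several markers pass screening — the package reports
  them with warnings rather than suppressing them, and the reduced model
  and tier contrast are the interpretable outputs.
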