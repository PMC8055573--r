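---
title: "The Hypertrophic Index pipeline: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hypertrophic Index pipeline: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the statistic

Neonatal rat cardiomyocytes react to the alpha-adrenergic agonist
phenylephrine (PE) with hypertrophic growth. When the culture medium
contains plasma from a patient, circulating factors can attenuate that
growth response; the degree of attenuation is a functional read-out of the
plasma, not of any single analyte. `hypindex` implements the full analysis
chain for such an assay: cells are seeded on 96-well plates, treated with
5% or 20% patient plasma with and without PE (50 µM), fixed, stained
(desmin for the cell body, DAPI for the nucleus), segmented, and measured.
Each condition is run in quadruplicate wells in three independent
experiments; fetal calf serum (FCS) wells on every plate anchor the
normalization.

The central statistic is the **Hypertrophic Index (HI)**. After per-plate
normalization (FCS mean = 100) and experiment-wise averaging of the
unstimulated wells to a reference $U_e$, every PE well of normalized size
$S$ contributes

$$HI_{linear} = \frac{S - U_e}{U_e}, \qquad
  HI_{log} = \frac{\ln S - \ln U_e}{\ln U_e}.$$

The log scale is the analysis scale; the linear scale is kept for display.
A patient's HI is the median of their well-wise values (up to 12 per plasma
concentration). Prognostic use then proceeds by dichotomizing patients at
the cutoff that minimizes the Wald p-value of a Cox proportional-hazards
model across all achievable splits, with a cluster-robust variance when the
scan runs on well-level rows.

## Order of operations in the HI

Both normalization and log transformation are part of the published
procedure, but their order is not stated. We normalize to
percent-of-FCS **first** and take logarithms second. On the percent scale
$\ln U_e \approx \ln 100 \approx 4.6$, safely away from zero, so the ratio
of logs is numerically stable; on a fraction-of-FCS scale $\ln U_e$ would
hover near 0 and the ratio would blow up. The percent-scale convention also
produces log-mode HI magnitudes (a few percent) on the same order as the
published cutoff scale, whereas linear-display values sit near 30--40%.
The base of the logarithm cancels in the ratio, which the test suite
asserts to $10^{-12}$. Both conventions stay isolated behind the
`mode` argument of `well_hi()`.

PE wells are compared against the experiment-level mean of the unstimulated
wells rather than paired well-to-well: wells are not paired within an
experiment, and this convention yields exactly "up to 12" well-wise values
per sample and plasma concentration (3 experiments × 4 PE wells).

## Quality control

Cells must satisfy two vitality criteria: a cell/nucleus area ratio of at
least 1.5 (inclusive) and an adequate DAPI intensity. "Adequate" is not
quantified in the source procedure, so the default is plate-local and
robust: the median ± 3 × MAD of intensities in the plate's FCS control
wells, overridable by absolute bounds. Filtering is pure flagging — rows
are never removed, measurements never altered — and wells retaining fewer
than 30 cells (`min_cells_per_well`; the well mean becomes unstable below
roughly that count) are dropped with a logged reason. Wells aggregate by
the arithmetic mean; the source describes aggregation "per well" without
naming a statistic, and downstream estimates are means.

## The synthetic cohort

No measurement or patient data from the original study are deposited, so
the package carries a first-class generator that emulates the study
conditions end to end. Its defaults are fixed to the study design and are
not tuning knobs:

* **Groups** ATTRv-CA/ATTRv-PN/ATTRwt/Ctrl of sizes 36/23/30/16 (n = 105).
* **Latent response** `latent_hi`: each patient's relative PE growth under
  5% plasma, normal around group means 0.32/0.36/0.28/0.39 (SD 0.06),
  calibrated so linear-display HI group means land near the reported
  39/36/32/28%. Under 20% plasma the effect is attenuated by a factor 0.45,
  reflecting the blunted response at the higher concentration.
* **Plates**: one plate per (experiment, plasma concentration, batch of ≤ 8
  samples), four FCS wells on every plate; per-plate multiplicative scale
  factor log-normal with SD 0.1. Plate maps are not published; this layout
  keeps the "per plate" normalization meaningful with a stable control
  mean.
* **Cells**: Poisson(400) measured cells per well, log-normal areas
  (sdlog 0.4) around the condition median; viable cells have cell/nucleus
  ratios bounded above 1.6 and uniform DAPI intensities in [800, 1200];
  a `dead_fraction` (default 0.1) of cells receives a ratio < 1.5 with
  probability 0.7 and/or an out-of-range intensity with probability 0.5
  (at least one defect is guaranteed, so every injected low-quality cell is
  filterable).
* **Outcomes**: death/transplantation (HTX) and decompensation (DMP) as
  independent exponentials sharing a proportional-hazards multiplier —
  patients with `latent_hi` below the generative threshold (default: the
  cohort's 30th percentile, matching the realized 30/75 low/high split)
  carry `1/0.24` times the hazard of high responders. The composite MACE
  is the first of the two. The total high-group hazard 0.0115/month with an
  HTX share of 0.3, exponential dropout at 0.045/month and administrative
  censoring at 24 months give about 25 composite events among 105
  patients and a median follow-up near 15 months, the published follow-up
  conditions.
* **Biomarkers**: the published cohort table mixes dispersion conventions,
  so the generator uses the printed ± as a standard error for age
  (converted via $\sqrt{n}$), as a standard deviation for GFR, and
  log-normal draws with the printed mean as median for the skewed markers
  cTnT and NTproBNP. Only marginal positivity and group ordering matter
  downstream.

A single integer seed drives everything; stage seeds are derived
deterministically, and identical (config, seed) pairs reproduce
byte-identical tables. Random draws are written as scaled standard normals
so that configurations differing only in a dispersion parameter (e.g.
`plate_effect_sd = 0` vs. `> 0`) consume identical random-number streams —
this makes the plate-normalization test exact rather than Monte-Carlo.

What the generator does **not** emulate: imaging artefacts, spatial
within-plate gradients, segmentation errors correlated with cell size,
inter-laboratory baseline differences, competing risks between endpoints,
and staggered study entry. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the assumed
data-generating process, not the clinical validity of the assay.

## Cutpoint selection and its caveat

`scan_cutoffs()` visits every achievable dichotomy once: candidates are
midpoints between consecutive distinct observed values. The default
well-level mode replicates each patient's outcome across their well-wise
HI values and clusters the sandwich variance by patient, so the Wald test
respects within-patient correlation; the patient-level mode (medians, one
row per patient) is exposed for sensitivity analysis. Candidates isolating
fewer than `min_group_frac` (default 0.1) of patients are inadmissible —
boundary splits produce unstable fits — and non-convergent fits are
flagged and excluded. Ties in the minimal p go to the smaller cutoff.

Because the cutoff is chosen to minimize p, the minimized p-value is
anti-conservative under the null. The acceptance suite quantifies this:
with a true hazard ratio of 1, the scan rejects at 0.05 in roughly 30% of
simulated cohorts. The selected cutoff must therefore be treated as
exploratory; no multiplicity correction is applied, matching the source
procedure, and the calibration study documents the consequence.

Two calibration studies characterize the scan under the generative model,
both run with administrative censoring only (the outcome model's stated
censoring mechanism; dropout is an add-on for follow-up realism) and both
scanning the latent HI at patient level, which is the scale on which the
generative threshold is defined: with a strong effect (HR 0.1, threshold at
the 30th latent percentile, n = 105) the selected cutoff lands within one
grid step of the candidate realizing the true partition in roughly 75-80%
of cohorts. With measurement noise on top of the latent value, or under
heavy censoring, localization degrades quickly — a known property of
minimum-p cutpoint estimation that users should expect with real data.

## Survival analysis conventions

Cox models use the Efron tie approximation (the default of standard
survival software and the better approximation under ties). Hazard ratios
are reported with 95% CIs; Wald p-values (cluster-robust when requested)
accompany every fit and likelihood-ratio p-values are attached to
Kaplan-Meier comparisons. Median follow-up uses the reverse Kaplan-Meier
estimator (censoring treated as the event). The GFR adjustment of NTproBNP,
`measured / exp(1.892 - 0.025 × GFR)`, has its fixed point at
GFR = 75.68 ml/min and increases with GFR. cTnT positivity is strict
(`> 50 pg/ml`; ng/l inputs are unit-identical and normalized on load).
Age-band NTproBNP cutoffs are deliberately not defaulted — the published
bands are cited but not printed — and must be configured before NTproBNP
subcohorting.

Group comparisons of well-level measurements use a linear mixed model with
a patient random intercept (REML, via `nlme`), reported as model-based
group means ± SE with Wald contrasts against the control group. If every
patient contributes a single well the random intercept is unidentifiable
and the fit falls back to fixed effects with a warning. Cohort
characteristics are tested by Pearson chi-squared (no continuity
correction) or one-way ANOVA.

## Numerical and degenerate-input choices

* Classification at the cutoff is inclusive: `patient_hi >= cutoff` is
  "high". Patients with missing HI are reported unclassifiable, never
  dropped silently.
* A plate without retained FCS wells, a well id missing from the layout,
  a constant covariate, and an empty candidate grid are hard errors naming
  the offending plate/id/feature.
* Non-positive cell areas are flagged with a logged reason rather than
  removed, so row counts are stable across the QC stage.
* Problem sizes in the test and acceptance suites (e.g. 200-cohort
  coverage, 100-replicate recovery, 400-simulation null calibration,
  reduced plate layouts for unit tests) were chosen as the smallest sizes
  at which the Monte-Carlo error is negligible relative to the asserted
  bounds.

## Limitations

The pipeline reproduces the analysis machinery, not the study's data. The
published headline values (2.9% cutoff, specific hazard ratios, group HI
estimates) arose from an undeposited cohort; on synthetic cohorts the
pipeline produces values of the same order under the encoded design, and
the package's guarantees are the property-based ones: oracle equivalence of
the scan, partial-likelihood agreement of the Cox fits, CI coverage,
cutpoint recovery under strong effects, and honest documentation of the
anti-conservative minimized p.
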