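# hypindex

A functional-biomarker analysis pipeline for plasma-treated cardiomyocyte
assays. Neonatal rat cardiomyocytes are cultured with patient plasma (5% or
20% v/v), with and without phenylephrine (PE, 50 µM), and their
hypertrophic growth response is quantified by automated microscopy. The
attenuation of that response carries prognostic information for patients
with transthyretin amyloidosis (ATTR): the weaker the PE response a
patient's plasma permits, the higher the risk of death, heart
transplantation or cardiac decompensation.

`hypindex` implements the complete statistical chain for this assay, for
biostatisticians and assay developers who need a tested, reproducible
reference implementation:

* **Single-cell QC** — vitality filtering on the cell/nucleus area ratio
  (≥ 1.5, inclusive) and adequate nuclear-stain (DAPI) intensity, with
  per-plate robust default bounds derived from FCS control wells.
* **Per-plate normalization** — well mean areas expressed as a percentage
  of the plate's fetal-calf-serum control mean (FCS ≙ 100).
* **The Hypertrophic Index (HI)** — for each PE-stimulated well of
  normalized size *S* against the experiment's unstimulated reference
  *U*: `(S − U)/U` on the linear (display) scale and
  `(ln S − ln U)/ln U` on the log (analysis) scale; the patient value is
  the median of up to 12 well-wise values.
* **Optimal-cutpoint stratification** — every achievable dichotomy of the
  cohort is scanned; each candidate cutoff is scored by the two-sided Wald
  p-value of a Cox proportional-hazards model (cluster-robust sandwich
  variance grouped by patient when scanning well-level rows); the cutoff
  minimizing p splits patients into high/low HI groups. The minimized p is
  anti-conservative under the null — the package quantifies this rather
  than hiding it.
* **Survival analysis** — univariate and multivariate Cox models (Efron
  ties, Wald and likelihood-ratio tests), Kaplan–Meier curves,
  reverse-Kaplan–Meier median follow-up, GFR-adjusted NTproBNP
  (`measured / exp(1.892 − 0.025·GFR)`) and biomarker-defined subcohorts
  (cTnT > 50 pg/ml, age-band NTproBNP cutoffs).
* **Group statistics** — mixed-effect models (patient random intercept)
  for well-level comparisons, chi-squared/ANOVA cohort tables.
* **A synthetic-cohort generator** — a seeded, first-class module that
  emulates the study design (groups of 36/23/30/16 patients, 2 plasma
  concentrations × ±PE × 3 experiments × 4 wells, hundreds of log-normal
  cells per well, plate effects, a dead-cell fraction, and
  proportional-hazards outcomes with ~25 composite events over a 24-month
  horizon), so the entire pipeline is testable without any external data.

## Worked example

```r
library(hypindex)

cfg    <- sim_config(seed = 42)          # the default study design
cohort <- simulate_cohort(cfg)           # patients, plates, cells, outcomes

cells <- apply_cell_filters(cohort$cells, cohort$wells)   # vitality QC
wells <- aggregate_to_wells(cells, cohort$wells)          # per-well means
norm  <- normalize_to_fcs(wells)                          # FCS = 100
hi    <- well_hi(norm, mode = "log")                      # well-wise HI
hi5   <- hi[hi$plasma_pct == 5, ]                         # analysis arm

scan <- scan_cutoffs(hi5, cohort$outcomes, endpoint = "MACE", level = "well")
scan
#> Cutoff scan (well level, endpoint MACE)
#>   candidates: 1259 (938 admissible)
#>   optimal cutoff: 0.04968053  (Wald p = 4.45e-09)

phi <- patient_hi(hi5)
cl  <- classify_patients(phi, select_cutoff(scan))
d   <- merge(cohort$outcomes, cl, by.x = "patient_id", by.y = "sample_id")
fit_cox(d, "hi_class", transform = "dichotomous",
        endpoint = "MACE", reference = "low")
#> Cox PH fit: hi_class (dichotomous), endpoint MACE
#>   HR 0.156 (95% CI 0.0676-0.358), Wald p = 1.24e-05, LR p = 0.000108
#>   n = 105, events = 26
```

Reading the output: the scan found the strongest prognostic separation at a
log-scale HI of ≈ 0.05 (5% of the log reference); patients at or above that
cutoff ("high HI" — a preserved growth response) have roughly one sixth the
hazard of a composite event compared with low-HI patients, with 26 events
among 105 synthetic patients. The synthetic cohort was generated with a
true high-vs-low hazard ratio of 0.24, inside the fitted CI.

One call runs everything and writes the report bundle (stage CSVs,
`summary.json`, `manifest.json` with checksums):

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 42))
```

A thin command-line wrapper is included:

```sh
Rscript inst/cli/hipipeline.R --out run1 --seed 42
```

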