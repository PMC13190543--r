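---
title: "Models and methods behind neoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoquant)
```

## Scope

`neoquant` is the analysis layer of a targeted isotope-dilution LC–MS/MS
method for neonicotinoids and their metabolites in human urine. It starts
from integrated peak areas — chromatography, MRM transitions and peak
integration happen upstream — and covers four stages: method validation,
calibration, censoring-aware quantification, and cohort statistics. A
synthetic peak-area generator stands in for raw instrument data, which for
biomonitoring studies is typically not publicly releasable.

## The validation model

Three spike designs drive the validation metrics. Matrix fortified *before*
extraction measures process efficiency, PE (%) = 100·mean(A_pre)/mean(A_neat);
matrix fortified *after* extraction isolates the ionization (matrix) effect,
ME (%) = (mean(A_post)/mean(A_neat) − 1)·100; and the two combine in the
post-extraction spike framework to yield apparent extraction recovery,
RE = PE/(1 + ME). The estimators use plain means of replicate areas, with
the replicate spread reported as an SD on the same percent scale.

Two conventions matter and are implemented exactly as stated:

* **No blank subtraction in PE/ME.** The area-ratio estimators are taken as
  defined. When the matrix carries endogenous analyte, the post-extraction
  ratio is inflated by `(1 + ME)·background·recovery/spike` — about +8
  points for a 0.30 ng/mL clothianidin background against a 1.5 ng/mL spike.
  The test suite asserts this bias in closed form rather than hiding it; the
  parameter-recovery properties are therefore checked in background-free
  material, which is also how a lab would isolate them.
* **Accuracy conventions differ by matrix.** Synthetic urine (background
  free) uses the plain ratio of measured to nominal; pooled urine uses the
  blank-corrected form 100·(final − initial)/spiked. QC acceptance is
  accuracy 70–130 % with RSD < 20 %.

Detection limits are 3σ (LOD) and 10σ (LOQ) where σ is the SD of measured
concentrations of low-level fortified QC replicates, pooling all injections
rather than per-extract means — the convention that matches how inter-day
replicate designs are analyzed. LOQ/LOD is exactly 10/3 before rounding;
reported values are rendered to two significant figures (rounding half away
from zero in decimal, so 0.0455 reports as 0.046) while full precision is
kept internally and for arithmetic.

**Matrix selection.** For analytes with measurable endogenous background in
pooled urine, σ is estimated in fortified synthetic urine instead, and the
resulting limits are tagged *method detection limits*; pooled-urine limits
are *practical reporting limits*. The interference criterion is qualitative
in origin; we fix the default threshold at half the low-level fortification
(0.0125 ng/mL against the 0.025 ng/mL QCL). That choice reproduces exactly
the eight panel analytes with pooled-urine background (CLO at 0.30 ng/mL
down to IMI at 0.02 ng/mL — note IMI falls *below* the QCL itself, so
"blank > QCL" would be too strict) while staying an order of magnitude above
the back-calculation noise floor of simulated blanks. The threshold is a
parameter of `select_lod_matrix()` for users who want a different rule.

## Calibration

Calibration fits the internal-standard response ratio (analyte area / ISTD
area) against nominal concentration by weighted least squares over
0.01–25 ng/mL with the ISTD at 5 ng/mL (50 µL of a 100 ng/mL working
solution in a 1 mL calibrator). The default weighting is 1/x: across 3.5
decades of concentration, unweighted least squares lets the top calibrators
dominate and low-end accuracy collapses; 1/x is the standard compromise and
`none` and `1/x²` remain selectable. A curve is accepted when r² ≥ 0.99 and
the slope is positive; back-calculation inverts the line, floors negative
estimates at zero with a `negative_estimate` flag, and flags extrapolation
above the calibrated range. Curves are fit per batch — the run layout
defines a fresh calibration series per batch, and pooling across batches
would launder inter-batch drift into the curve. Per-analyte range overrides
(the panel ships 10 ng/mL upper limits for NIT and CLO-U, whose response
departs from linearity earlier) live in the panel configuration rather than
in code.

Mid-run stability: one calibrator is re-analyzed after every ten unknowns;
each re-check is back-calculated and compared to nominal with a default
tolerance of ±20 %, matching the global precision bound.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs. The signal model per injection is

```
area      = rf · (background + spike) · recovery^(pre-extraction only)
               · (1 + ME)^(in matrix) · lognoise(cv)
istd_area = rf_istd · 5 ng/mL · recovery^(extracted) · (1 + ME)^(in matrix)
               · lognoise(istd_cv)
```

with `lognoise` multiplicative log-normal noise of mean exactly 1 and the
given CV. The ISTD is added before extraction and therefore co-experiences
recovery and suppression — that is its purpose — with a small independent
residual (CV 2 %), so ISTD-ratio quantification is unbiased by construction
but not noiseless. With all CVs at zero, every downstream estimator equals
its closed form exactly, and the test suite asserts this.

Default per-analyte parameters (`default_sim_params()`): recoveries 0.59–0.92
anchored where the method reports worked values (e.g. ~0.90 where PE 38 %
combines with ME −58 %); pooled-urine matrix effects spanning −0.669 to
−0.36 and synthetic-urine effects at 0.31× the pooled value (−0.21 to
−0.11), inside the observed suppression ranges of the two matrices;
endogenous background only in pooled urine, taken from the shipped panel's
blank column (eight analytes, 0.02–0.30 ng/mL); instrument noise CV 5 % on
areas. Urinary concentrations are log-normal with per-analyte medians
roughly tracking the population medians of the measured cohort (0.0003–0.35
ng/mL) and a common geometric SD of 3.5 — urinary biomarker distributions
are right-skewed across 1–2 orders of magnitude, and a GSD near 3 is
typical. Temporal structure is a multiplicative factor per 2-year bin on
the analytes with rising population exposure (THX 1.15, ACE-N-DES 1.12, FLU
1.25, SUL 1.30, SUL-X 1.20); creatinine is log-normal with median 100 mg/dL
and GSD 1.6. The default cohorts are 246 samples spanning 2010–2025 and 47
samples from a single winter with a 2.4× exposure multiplier, mirroring the
two-cohort design the statistics layer is built for. Batches are assigned
as consecutive blocks (not randomized), matching box-by-box processing of
archived specimens.

Randomness derives from one master seed with deterministic per-stream
substreams, so each table is independently reproducible; identical seeds
give byte-identical output files.

The batch-sequence generator reproduces the run layout (three equilibration
injections of a mid-range calibrator, solvent blank, reagent blank,
calibration series, rinse, three pooled-urine QCs, water extract, unknowns
with a calibrator re-check every ten). Its optional drift multiplies the
*analyte* channel only: a drift common to both channels would cancel in the
ISTD ratio and no mid-run check could ever detect it, so the simulated
failure mode is analyte-specific sensitivity drift.

What the generator does **not** emulate: chromatographic peak shape,
carryover chemistry, within- vs between-day variance partitioning (a single
combined CV is used; both components exist in real inter-day designs),
correlated exposures between analytes (samples are drawn independently per
analyte, so between-analyte correlation tests run against a null generator),
and creatinine–exposure dependence. Passing tests therefore demonstrate
correctness of the estimators and statistics under a faithful signal model,
not that any particular cohort result will replicate.

## Quantification conventions

Censoring uses substitution: raw ≤ LOD is a non-detect reported as ½·LOD;
LOD < raw < LOQ is reported as ½·LOQ; raw ≥ LOQ is reported as measured.
The boundary convention is a literal reading of "exceeding the LOD": a value
exactly at the LOD counts as a non-detect, a value exactly at the LOQ as
quantified. Reported concentration is non-decreasing in the raw value. The
matrix-appropriate limit set for real samples is the practical reporting
limits (pooled urine), the default of `panel_limits()`. Creatinine
adjustment is µg/g = 100·(ng/mL)/(mg/dL); missing creatinine propagates as
missing, never as zero. Aggregates are plain sums of substituted values,
computed on both the ng/mL and µg/g scales; because the clothianidin
aggregate's members are a subset of the thiamethoxam aggregate's,
ΣTHX ≥ ΣCLO holds for every non-negative row. No maximum-likelihood or
multiple-imputation treatment of censored values is offered — substitution
is the convention being reproduced; alternatives are future work.

## Statistics

All inference is nonparametric on creatinine-adjusted substituted values:
Kruskal–Wallis across temporal bins or batches (tie-corrected chi-square
approximation), Spearman correlation against collection date and between
analytes (asymptotic p, tie-corrected ranks), Wilcoxon rank-sum for the
two-cohort comparison, all two-sided at α = 0.05 with no multiplicity
adjustment — matching the analysis being reproduced; a Benjamini–Hochberg
step is easy to bolt on via `p.adjust` for users who want it. When the
total sample size is ≤ 12 the Kruskal–Wallis p value is computed exactly by
enumerating all distinct group reassignments; the tests verify this path
against an independent exhaustive-permutation oracle. Degenerate inputs
(all values tied, constant columns, single batches) return p = 1 or NA with
explicit flags rather than errors. Temporal bins are half-open calendar
intervals anchored at the study start (a date in 2012 with width 2 anchored
at 2010 falls in "2012-2013"). The 95 % CI of the mean uses the normal
approximation and is labeled as such; for the skewed distributions involved
it is reported for comparability, and the medians and quantiles carry the
interpretation.

Type-I calibration of the rank tests (rejection ≈ 5 % under the null for
the trend, correlation and batch tests) is asserted over 500 replicates
with binomial bounds in the acceptance suite. The heavier simulations in
the test suite use n = 9 or 18 replicates per level for validation (the
replicate counts validation experiments actually use; the replicate count is
a config parameter since both appear in routine designs) and cohorts of a
few dozen samples for pipeline tests, with the full 246 + 47 design
exercised where the result depends on it.

## Known limitations

* PE/ME estimates in matrices with endogenous background carry the
  documented bias of the raw area-ratio definitions; interpret pooled-urine
  PE/ME for the eight background analytes accordingly.
* The calibration model is strictly linear; quadratic or 4-parameter fits
  are out of scope, and analytes that saturate early are handled by range
  overrides instead.
* The generator's independence assumptions (between analytes, between
  creatinine and exposure) make some real-data correlation structure
  untestable here.
* Summary means and CIs on heavily censored analytes are substitution
  artifacts as much as exposure estimates; they are labeled as computed on
  substituted values.
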