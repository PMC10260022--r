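---
title: "Methods: quantitative metabolomics for interstitial-fluid-matched culture"
author: "tifmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative metabolomics for interstitial-fluid-matched culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tifmtools)
```

# Scope and model

Solid tumors — pancreatic ductal adenocarcinoma in particular — perfuse
their cells with interstitial fluid (IF) whose nutrient content differs
sharply from both plasma and standard culture media (arginine, for
example, sits at only a few µM in the tumor IF versus ~125 µM in plasma).
`tifmtools` implements the quantitative chain needed to study cell
metabolism under such conditions:

1. **Formulation** — compound a culture medium in which each nutrient
   matches its mean IF concentration, and verify the compounded product.
2. **Quantitation** — convert LC–MS/GC–MS peak areas into absolute µM
   via isotopically labeled internal standards and external standard
   curves.
3. **Flux (Co/Re)** — per-cell consumption/release rates in
   pmol/cell/day from paired unspent/spent media and exponential growth,
   with propagated SEMs.
4. **Tracing** — mass-isotopomer distributions, natural-abundance
   correction, and enrichment comparisons between compartments.
5. **Tissue concentrations** — ellipsoid-volume tumor density converting
   amount-per-mass into intratumoral µM.
6. **Scores** — weighted positive-pixel IHC scores and 2^−ΔΔCt qPCR
   expression.

Every stage has a synthetic-data generator with known ground truth, so
the full pipeline is testable without instrument data.

# Medium formulation

Metabolites measured in IF are eligible for the medium when they are
commercially available at high purity, stable in aqueous solution, and
present above 0.5 µM. The threshold comparison is **strict** (a
metabolite at exactly 0.5 µM is excluded) and configurable in
`select_components()`. Pool membership (the recipe is compounded as ten
separate dry-powder pools) is treated as input metadata: no assignment
rule exists beyond practical compounding, so the package validates the
ten-pool structure but never optimizes membership.

Electrolytes are balanced per ion against a reference medium
(RPMI-1640): for each tracked ion,

$$\text{added salt} = \text{reference} - \text{serum} - \sum_\text{components} \text{counter-ions},$$

computed in mM with component contributions converted from µM. Counter-ion
stoichiometry is **supplied as data** (`counterion_table()`) because the
salt form of each component is a sourcing choice the formulation text
does not pin down. A salt addition can never be negative; if components
plus serum exceed the reference for some ion, the balance is reported
infeasible with the ion named and the deficit quantified. When several
single-salt choices could supply an ion the per-ion ledger leaves the
choice explicit rather than guessing an intent.

The packaged recipe (`tifm_formulation()`) is a **synthetic
reconstruction**: it has the documented structure (115 metabolite
components over ten pools, salts and bicarbonate carried separately, 10%
dialyzed serum) and anchors the two concentrations that are printed
(citrulline 67 µM, arginine 2 µM); all other concentrations are
realistic IF-scale values fixed once. It exists so that structural code
paths are exercisable, not as a measured recipe.

`verify_formulation()` compares measured against intended
concentrations by Pearson correlation on raw concentrations (matching
the usual expected-versus-measured scatter); a `log_scale` option is
provided because concentrations span nearly four orders of magnitude and
log-scale correlation weights the low end more fairly.

# Absolute quantitation

The detector model is linear: `area = response_factor × concentration` in
the extract. Extraction of `s` µL of sample with `e` µL of mix dilutes by
`(s+e)/s` (10 for the default 5 + 45 µL protocol). The dilution factor
is modeled explicitly and **cancels symbolically** whenever samples and
standards share a protocol, so asymmetric protocols work without special
cases.

*Internal standards.* A labeled standard present at fixed unknown
concentration `C` in the extraction mix is calibrated against the
external dilution series: under a shared per-metabolite response factor
(labeled and unlabeled isotopologues co-elute and co-ionize, the standard
LC–MS assumption — and the identifiability condition for this
calibration), the unlabeled/labeled area ratio is `c_i / C`, so `C` is
the reciprocal slope of the ratio regression. A single-point estimator is
available; regression is the default. Calibrations whose ratio fit has
r² < 0.95 are rejected as non-monotone. Sample quantitation is then
`(sample area / standard area) × C`.

*External curves.* Unweighted OLS of (normalized) area on concentration
over a ≥4-level series spanning 5 mM to 1 µM; 1/x weighting is available
for heteroscedastic data. Curves with r² < 0.95 are excluded from
quantitation by name. Inverse prediction outside the calibrated range is
**flagged as extrapolated rather than refused** — the caller decides, the
flag travels with the value.

*Elution matching.* Metabolites without their own labeled standard are
normalized to the standard nearest in retention time (absolute
difference; "similar elution" is not otherwise quantified). Equidistant
ties break lexicographically so results are deterministic.

# Consumption/release fluxes

Two cell counts a day apart determine the exact exponential
`k = ln(n2/n1)/Δt` (three or more trigger a log-linear fit, which leaves
the two-point case unchanged). The integrated cell-days are analytic,
`(N(t2) − N(t1))/k`, with a second-order series used when
`|kΔt| < 1e-8` to cross the removable singularity at `k = 0`; the test
suite holds the analytic form to adaptive quadrature within 1e-10
relative.

The flux is `ΔC × volume / cell·days` with 1 µM·mL = 1000 pmol.
Consumption is **negative** by default (a deliberate choice — the sign is
conventionally ambiguous in consumption/release tables); a flag flips the
convention. SEMs propagate by the quotient rule,
`|rate|·sqrt((σ_ΔC/ΔC)² + (σ_cd/cd)²)`, degenerating to the linearized
`volume·σ_ΔC/cell·days` when ΔC = 0. Monte-Carlo resampling at 10% CVs
agrees with the formula within 5% in the tests. Not-detected metabolites
are carried as explicit `NA` with flag `"ND"`, never as zero, because the
detection threshold that would justify a zero is unknown. Media volume is
assumed constant over each 24 h window (media replaced daily), so
evaporation and blank-media degradation are not modeled.

Glucose availability QC: a culture fails when
`(unspent − spent)/unspent > 0.30`; apparent release always passes.

# Natural-abundance correction

For a molecule with `n` observable tracer atoms, the correction matrix's
column `j` is the theoretical mass-shift spectrum of the species carrying
exactly `j` tracer atoms: labeled positions are excluded from the
natural-abundance draw, the remaining tracer-element atoms follow that
element's natural distribution, and all other elements of the formula are
convolved in (restricting to the tracer element alone is a switch, since
the low-resolution correction convention differs between laboratories).
Spectra are truncated at shift `n`, which the inversion respects
consistently. The measured MID is deconvolved by **non-negative least
squares** (`pracma::lsqnonneg`) — unconstrained inversion can return
negative fractions on noisy channels — then renormalized to a probability
vector; an unconstrained solver remains available for diagnostics.
Isotope abundances ship as a versioned data table and the version string
travels into every corrected result.

`labeled_fraction()` (1 − M+0) refuses uncorrected input so the
correction step cannot be skipped silently.
`synthesis_fraction_from_precursor()` reads the tracer-diagnostic shift
(e.g. +5 for a skeleton built from a fully ¹³C₅-labeled precursor); it
refuses to interpret non-steady-state (bolus) labeling as a synthesis
fraction, because kinetic labeling admits no such reading — for bolus
designs only `excess_enrichment()` (paired one-tailed t per isotopologue)
is meaningful. Degenerate zero-variance comparisons report `p = 0.5`
(no difference) or the double-precision underflow floor (constant
difference) instead of failing.

# Intratumoral concentrations

Caliper semi-axes give `V = (4/3)πABC`; density is mass over volume,
per-tumor by default with a cohort-average mode (the pooling level is a
genuine open choice; per-tumor preserves animal-level variance).
`amount (pmol/mg) × density (mg/mm³)` is pmol/mm³, which is numerically
µM. The denominator is whole-tissue volume — water plus solids, no
intracellular/extracellular partitioning — a documented caveat of the
approach. Tumor-versus-IF comparisons report the ratio of means and a
two-tailed two-sample t statistic, withheld with a note when either
group has fewer than two replicates or zero variance.

# IHC and qPCR scores

Positive pixels weighted Low = 1, Medium = 2, High = 3, normalized to
total region pixels (range 0–3); sample scores average regions
**unweighted** by region size, with a pixel-weighted pooled option.
Absolute scores inherit the upstream pixel classifier's proprietary
intensity thresholds — class counts are consumed, not recomputed.
ΔΔCt uses the arithmetic mean of control ΔCt (standard Livak), making
the control condition's geometric mean expression exactly 1.

# The synthetic-data generators

`ground_truth()` fixes every true quantity once: nine default metabolites
at IF-scale concentrations (arginine 2 µM, citrulline 67 µM, millimolar
glucose/lactate), per-cell fluxes of a few pmol/cell/day (glucose and
lactate an order larger), growth at ln 2/day sampled on days 1 and 2 in
2 mL, per-metabolite response factors in 0.5–3, a labeling scenario
(argininosuccinate, +5 diagnostic shift, synthesis fraction 0.45,
precursor enrichment 1), and ~1.05 mg/mm³ ellipsoidal tumors with
arginine 30-fold enriched over IF. These defaults **are** the simulated
study conditions; they were chosen once from the printed scales and are
not tuned against test outcomes.

Measurement noise is multiplicative lognormal at a stated CV
(mean-1 parameterization), the natural error scale for positive LC–MS
quantities; isotopologue channels optionally take additive Gaussian noise
clipped at zero. At zero noise every generator is the exact inverse of
its analysis counterpart — the tests hold these round trips to 1e-9.
Each generator reseeds deterministically from the single ground-truth
seed (with a fixed per-scenario offset) and records the seed it used, so
any scenario is independently reproducible.

What the generators deliberately do **not** emulate: chromatographic
peak shape and integration error, retention-time drift, matrix effects
and ion suppression, metabolite degradation in blank media, tumor
necrotic-core heterogeneity, and resolution-dependent isotopologue
overlap. Passing tests therefore demonstrate correctness of the
computations under the stated statistical model, not robustness to every
failure mode of real instrument data.

# Numerical choices, problem sizes, limitations

- r² exclusion threshold 0.95 for both calibration routes (as
  published); strict selection threshold 0.5 µM.
- `k → 0` switchover at `|kΔt| < 1e-8` with a second-order series.
- NNLS for MID deconvolution; renormalization after solving.
- Ties in elution matching break lexicographically.
- Electrolyte feasibility tolerance 1e-12 mM; balanced totals are exact
  to < 1e-9 mM.
- Test-suite problem sizes: 20-metabolite flux panels with 6 replicates
  over 200 seeded repetitions; 1000 random MIDs across C₁–C₂₀ and
  N₁–N₄ tracer formulas; 1e5-draw Monte-Carlo check of the SEM
  propagation. These sizes give stable acceptance statistics while
  keeping the suite fast to iterate.
- Known limitations: the packaged recipe is a labelled synthetic
  stand-in; no kinetic (ODE) flux fitting; no osmolarity model beyond
  tracked ions; single-timepoint Co/Re assumes constant volume and
  constant per-cell flux over the window.

# A worked round trip

```{r roundtrip}
gt <- ground_truth(seed = 42)
sim <- simulate_culture(gt, n_replicates = 6, noise_cv = 0.05)
core <- co_re_analysis(sim$media, sim$counts, sim$volume_mL)
core[order(core$metabolite), c("metabolite", "rate_pmol_cell_day", "sem", "n")]
```

Negative rates are consumed nutrients; compare against
`gt$metabolites$flux_pmol_cell_day` to see the recovery.
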