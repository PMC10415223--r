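---
title: "Methods: a whole-body PBPK model of cefepime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model of cefepime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cefepbpk)
```

## The model

Cefepime is a parenteral fourth-generation cephalosporin that is almost
entirely cleared by the kidney and distributes into a small, essentially
extracellular volume (reported Vss about 0.22 L/kg, half-life about 2 h in
subjects with normal renal function). `cefepbpk` implements a whole-body
physiologically based pharmacokinetic (PBPK) model of its disposition after
intravenous infusion:

* **Structure.** Fifteen perfusion-limited tissue compartments (heart, brain,
  muscle, skin, adipose, bone, kidney, gonads, liver, spleen, stomach, small
  and large intestine, pancreas, and a rest-of-body pool), a lung in series
  with cardiac output, and arterial and venous blood pools. Splanchnic organs
  drain through the liver via the portal vein. For each perfusion-limited
  organ the balance is `dA/dt = Q (C_art - C_t / (Kp/BP))` in blood
  concentrations, where `Kp` is the tissue:plasma partition coefficient and
  `BP` the blood:plasma concentration ratio.
* **Input.** Constant-rate IV infusion into the venous pool; multiple-dose
  regimens are supported, although every bundled study arm is single-dose.
* **Elimination.** Renal only. There is no reported hepatic clearance for
  cefepime, so the model's plasma clearance is entirely renal and is applied
  as filtration of the arterial plasma entering the kidney. This choice makes
  the linear-elimination identity `dose / AUC(0-Inf) = CL_plasma` hold
  exactly, which the package uses as a 2% numerical oracle on every simulated
  subject; applying the clearance to the kidney *outflow* instead would bias
  the identity by the kidney extraction ratio (about 18% at the healthy
  flows), which the predicted AUC/CL pairs of the source tables do not show.
* **Observation.** Venous *plasma* concentration in ug/mL, converted from
  blood via `BP = 1 - HCT` (see below). Units are fixed package-wide: hours,
  mg, L, L/h; organ flows are entered in L/min and converted once at model
  assembly.

## Drug parameters and tissue partitioning

The drug input set (`cefepime_defaults()`) is: MW 517 g/mol (hydrochloride),
log P 0.6914, pKa 13.2 (basic center) and 4.06 (carboxylic acid), fraction
unbound 55% (reported range 51.6-99.2%, exposed for sensitivity runs), and a
specific renal clearance of 2.1 mL/min/kg referenced to the 70-kg reference
adult.

Tissue:plasma partition coefficients come from the Rodgers-Rowland unified
equations with a baked-in published tissue-composition table
(`tissue_compositions()`). Two choices deserve comment:

* **Ionization branch.** Cefepime is a zwitterion whose quaternary ammonium
  is permanently charged and internally paired with the carboxylate. Treating
  both charges independently in the intracellular-pH partition term would
  concentrate the permanent cation in cells and push Vss to about 0.67 L/kg,
  far above every literature report for this polar, low-permeability (BCS
  class 3) drug. The package therefore uses the acid/anion form of the
  equations (intracellular exclusion driven by the carboxylate, no acidic
  phospholipid association). With the default composition table this yields
  Vss = `r round(pbpk_model(build_reference_adult(70, 180, 30))$vss, 3)` L/kg
  for the reference adult, in line with the reported 0.22 L/kg. The branch is
  overridable through the `ionization` field.
* **Blood:plasma ratio.** No measured value is available; the erythrocyte
  partition coefficient of this polar zwitterion is taken as zero, giving
  `BP = 1 - HCT` (about 0.55 in healthy males). Venous plasma is the
  observation compartment because clinical assays report plasma.

Disease scaling of plasma protein binding uses the protein binding factor
PBF: `fu' = 1 / (1 + PBF (1 - fu) / fu)`, the unbound fraction obtained when
the binding-protein concentration is multiplied by PBF. Partition
coefficients are recomputed per subject from the adjusted `fu'`.

## Physiology and its variants

`build_reference_adult()` scales a baked-in ICRP-style reference organ table
(volumes in L, flows in L/min) so total organ volume equals body weight at
unit density; flows scale with weight^0.75. The glomerular filtration rate is
indexed to Du Bois body surface area, `GFR = 120 x BSA / BSA_ref` mL/min, so
the (70 kg, 180 cm) reference has exactly 120 mL/min and clearance rises
mildly with body size, as the healthy study arms require.

The disease transforms are pure functions over this object:

* **Moderate CKD** (`apply_moderate_ckd`): gastric emptying time 20.625 min,
  PBF 0.9265, hematocrit 0.433; GFR inside the 31-60 mL/min band, midpoint
  45.5 by default (the per-patient values behind the source study are not
  reported; the midpoint is overridable per scenario).
* **Severe CKD** (`apply_severe_ckd`): GET 24.375 min, HCT 0.398, PBF 0.837,
  renal blood flow 0.17 L/min, hepatic arterial flow 0.16 L/min, GFR midpoint
  20.5 mL/min of the 11-30 band. The source lists the five severe-CKD values
  in an order that would assign a flow to the dimensionless PBF; the package
  assigns 0.837 to PBF and 0.17 L/min to renal flow, since a binding factor
  cannot carry flow units and 0.17 L/min is a physiological severe-CKD renal
  perfusion.
* **Obesity** (`apply_obesity`): GFR = 143 mL/min per 1.73 m^2 of Du Bois
  BSA; hematocrit and protein binding untouched. Excess mass over a lean
  reference is added to adipose so unit-density closure is preserved.
* **Pediatrics** (`apply_pediatric`): volumes scale linearly with weight;
  the eleven published pediatric organ flows (large intestine 0.43, heart
  0.35, hepatic artery 0.53, spleen 0.29, skin 0.23, small intestine 1.4,
  stomach 0.10, pancreas 0.08, muscle 0.88, kidney 1.4, brain 1.85 L/min)
  are applied at their 70-kg equivalent and scaled by weight^0.75, as is GFR.
  Several of these published values (notably small intestine 1.4 L/min)
  exceed plausible pediatric flows and their reference size is unstated; they
  are applied as given and down-scaled, and the effective cardiac output is
  recomputed as the sum of the arterial-side flows. The allometric exponents
  (1.0 volumes, 0.75 flows/GFR) are the conventional choice and are
  arguments of the transform.

Gastric emptying time is carried and reported for fidelity but has no effect
on these IV-only simulations.

### Renal clearance across individuals

The specific clearance of 2.1 mL/min/kg is anchored at the 70-kg reference
adult and carried across individuals by their GFR:

```
CL_plasma = 2.1 mL/min/kg x 70 kg x 0.06 x GFR_i / 120  [L/h]
```

i.e. 8.82 L/h at the reference and proportional to filtration elsewhere.
This single rule reproduces the healthy-adult predictions (about 8.8-8.9 L/h
for the 1000 mg arm), scales CKD clearance with the within-band GFR, and
gives pediatric per-kg clearances (about 0.15-0.17 L/h/kg) close to the
published pediatric prediction of 0.20 L/h/kg — a naive per-kilogram scaling
would instead *halve* pediatric per-kg clearance relative to adults and
nearly double it in the obese, neither of which the published predictions
show. The obese arm is the one place the rule over-predicts: BSA-indexed
143 mL/min/1.73 m^2 gives large absolute GFRs in heavy subjects, and the
simulated obese clearance (about 14-15 L/h) exceeds the published predicted
9.16 L/h. The packaged evaluation tables, not the simulator, carry the obese
qualification statistics.

## Numerics

Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and absolute
tolerance 1e-10 mg, restarted at every infusion on/off boundary so the
discontinuous input never crosses a solver step. Mass balance
(`infused = in body + eliminated`) holds to better than 1e-6 relative error
on every run and is checked in the tests. Collapsing the model to a single
well-stirred compartment (`collapse_model()`: all Kp = 1, BP = 1, flows
scaled by 1e4) reproduces the closed-form one-compartment infusion solution
to better than 0.1%; the residual error decays as the reciprocal of the flow
scale. Default output grids are 0.05 h over 0-12 h for adults and 0.1 h over
0-48 h for CKD, where the drug persists far longer.

NCA follows standard conventions: earliest-time tie rule for Tmax,
linear-up/log-down trapezoid (log segments are exact for exponential decay;
a segment touching zero falls back to linear), terminal slope by log-linear
regression over candidate tails of at least 3 post-peak points selected by
best adjusted R-squared (ties within 1e-4 prefer the longer tail),
`AUC(0-Inf) = AUC(0-tlast) + Clast/lambda_z` with a warning above 20%
extrapolation, and `CL = dose/AUC(0-Inf)`. Pediatric clearance is reported
per kilogram to match the weight-based dosing convention.

## Virtual populations and synthetic observed data

Each bundled scenario mirrors one study arm: 100 virtual subjects per arm,
ages and weights uniform over the reported ranges, sex assigned to the
reported female count, height back-computed from a cohort-appropriate BMI
draw (20-27 lean, 31-45 obese) because the study reports omit height. For
pediatric arms age and weight are drawn independently — only weight enters
the transforms, so the missing growth-curve correlation does not affect any
computed quantity. Inter-individual variability beyond anthropometry is
deliberately off by default, so population results are driven entirely by
documented inputs. Percentile bands report the pointwise mean, empirical
5th/95th percentiles (linear-interpolation quantiles), minimum and maximum —
the standard visual-predictive-check summary.

The source study's digitized concentration profiles are not publicly
deposited, so `generate_observed()` emulates them: the model's own subjects
are sampled at a dense-early/sparse-late clinical schedule (0.25-12 h),
multiplied by proportional log-normal noise (`sigma = sqrt(log(1 + CV^2))`,
default CV 15%, typical of digitized mean clinical PK data) and averaged.
`recovery_harness()` closes the loop: synthetic data are pushed through NCA
and the fold-ratio/AFE machinery against the noiseless generating profile,
and the ratios converge to 1 as CV goes to 0. Passing these checks shows the
pipeline is self-consistent; it does not validate the physiology against
real patients beyond the packaged observed/predicted tables.

## Qualification statistics

`fold_ratio()` is observed/predicted; `afe()` is `10^mean(log10 R)`, the
geometric mean fold error; `mean_ratio()` is the arithmetic mean with a
normal-approximation 95% CI; the two-fold criterion is `0.5 <= R <= 2` with
inclusive boundaries. `qualification_summary()` recomputes the headline
statistics from the packaged tables (transcribed exactly as printed,
including one anomalous block and two cells whose printed ratios disagree
with their own quotient beyond display rounding; both are flagged in the
fixture rather than silently corrected). Display rounding is two decimals,
half-up; all comparisons in code use unrounded values.

## Known limitations

* Cellular permeability is not modeled; organs are perfusion-limited, the
  standard simplification when permeability values are unpublished. For this
  low-permeability drug that overstates how quickly tissues equilibrate, but
  the small Kp set keeps the effect on plasma kinetics modest.
* The simulated healthy terminal half-life is about 1.4 h, below the 2-2.3 h
  reported for cefepime from clinical studies. This is a structural
  consequence of the input set, not a numerical artifact: a clearance of
  8.82 L/h against a distribution volume of about 16 L fixes the terminal
  slope near 0.53 1/h, and the source model's own predicted Cmax/AUC pairs
  imply the same slope. The clinical 2-2.3 h corresponds to the lower
  literature renal clearance (96-116 mL/min), not to the optimized
  2.1 mL/min/kg used here.
* Obese clearance is over-predicted (see above).
* Metabolites, urine-data NCA, oral and intramuscular routes, below-LOQ
  censoring and dialysis are out of scope.

## Reproducibility

Every stochastic step (population draws, residual noise) takes an explicit
integer seed and restores the caller's RNG state. A scenario run is fully
described by (scenario file, seed, package version), captured in the run
manifest. Simulation problem sizes used by the test-suite and by
`scripts/acceptance.R` — 100-subject arms for the population statistics,
25-subject arms for secondary summaries, 20 replicate synthetic studies —
were chosen to keep Monte-Carlo error on reported means well under the
tolerances being checked.
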