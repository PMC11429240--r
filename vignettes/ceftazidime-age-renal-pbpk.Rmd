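---
title: "Methods: population PBPK of ceftazidime across age and renal function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PBPK of ceftazidime across age and renal function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model: what is assumed,
which parameters matter, how the virtual population is constructed, which
numerical choices were made where the design was genuinely open, and what
the simulations can and cannot say about real patients.

## The model

Ceftazidime disposition is described by a whole-body, perfusion-limited
PBPK model with 14 compartments: venous blood, arterial blood, lung, and
eleven systemic tissues (adipose, bone, brain, gut, heart, kidney, liver,
muscle, skin, spleen, pancreas), with gut, spleen and pancreas draining
into the liver. Each tissue is a well-stirred space in instantaneous
equilibrium with its outflowing blood, so the drug-specific inputs reduce
to the tissue:plasma partition coefficients (Kp), the blood:plasma ratio,
and two clearance terms.

**Distribution.** Kps are predicted mechanistically for an ionized acid:
partitioning into extracellular water, intracellular water with a
Henderson–Hasselbalch correction between plasma pH 7.4 and intracellular
pH 7.0, a (negligible, for logP −3.75) lipid term, and association with
interstitial albumin scaled by each tissue's albumin ratio, with the
plasma association constant back-calculated from `fu = 0.9`. Because
ceftazidime is essentially fully ionized (pKa 2.43/2.89) and extremely
hydrophilic, every Kp is well below 1 and
`Vss = (V_plasma + V_ery·E:P + Σ V_t·Kp_t)/BW` comes out at ~0.20 L/kg.
With `B:P = 0.55` and hematocrit 0.45, the erythrocyte:plasma partition is
zero — the drug is confined to plasma water within blood. Vss is, by
construction, independent of dose and of renal function; only clearance
changes across the age × RI grid, which is exactly the separation the
analysis is after.

**Elimination.** Renal clearance is passive filtration, so an individual's
value scales linearly with renal function:
`CL_R = 6.0 L/h × CLcr / CLcr_ref`. It is drawn from venous plasma, which
makes the urinary-recovery identity `fe = CL_R·AUC/Dose` exact in the
model. The minor biliary route is a well-stirred liver acting on unbound
liver water: per-hepatocyte intrinsic clearance 0.085 µL/min/10⁶ cells,
scaled by hepatocellularity and liver mass, with 30% lognormal
inter-individual CV. Its apparent plasma clearance is ~0.7 L/h, ~10% of a
healthy adult's total — matching the known ~88–90% urinary recovery. There
is no enterohepatic recirculation and no transporter term.

**Reference clearance calibration.** The one calibrated constant is
`CLcr_ref`, the renal function at which `CL_R` equals its healthy-adult
value of 6.0 L/h. It was fixed once by requiring the simulated 25–35 y,
50% female cohort to reproduce a mean total clearance of 7.4 L/h: with
that cohort's mean Cockcroft–Gault CLcr of 117.6 mL/min/1.73 m² and mean
apparent biliary clearance of 0.72 L/h, `CLcr_ref = 6×117.6/(7.4−0.72) ≈
106`. It is exposed as the `gfr_ref` argument everywhere downstream. As a
plausibility check, the mechanistic alternative `CL_R = fu·GFR` gives
6.0 L/h at CLcr ≈ 111 — the two readings of "reference" agree to ~5%, and
the scaling by CLcr ratio is retained.

## The virtual population

The generator replaces a proprietary population database with documented
parametric models (all constants in `population_defaults()`):

* weight ~ lognormal, median 78 kg (M) / 67 kg (F), CV 15%;
* height ~ normal, 176/163 cm, SD 7 cm, −0.05 cm/year after age 50;
* serum creatinine ~ lognormal, CV 15%, median 80 µmol/L (M) / 65 µmol/L
  (F), flat to age 40 and rising 0.4%/year thereafter. The near-flat
  trajectory is deliberate: in healthy aging, declining muscle mass
  (creatinine production) roughly offsets declining filtration, so the
  age signal in Cockcroft–Gault comes mostly from the `(140 − age)` term.
  The ~20% male–female creatinine difference makes male and female CLcr
  nearly equal under the 0.82 female factor, consistent with the
  reference predictions this package reproduces;
* hematocrit 0.45; hepatocellularity 99×10⁶ cells/g (the standard human
  literature value); cardiac output = cardiac index 3 L/min/m² × BSA,
  declining 0.8%/year after 25; organ volumes as sex-specific fractions of
  body weight, liver mass 1600 g at BSA 1.86 m² scaled by BSA; blood flows
  as fixed fractions of cardiac output, with kidney perfusion scaled down
  with CLcr (floored at 10%) and the deficit rerouted through muscle so
  the venous/arterial nodes always balance.

**Renal-impairment stages.** Stages are CLcr bands (normal ≥90, mild
60–90, moderate 30–60, severe 15–30 mL/min/1.73 m²; a boundary belongs to
the milder class; 0 is anuric; values below 15 are treated as severe). A
"normal" cohort is *normal-for-age*: creatinine is sampled and CLcr
computed, so a healthy 70-year-old sits near 60–70 mL/min/1.73 m², not 90.
An explicitly staged cohort is sampled by drawing disease severity as a
CLcr uniform in the band *at an anchor age of 40*, carrying the implied
creatinine to the individual's age through Cockcroft–Gault, and truncating
the resulting CLcr into the band. The rationale: a patient's degree of
renal pathology is encoded by their creatinine, and two patients with the
same creatinine but different ages differ in CLcr by the Cockcroft–Gault
age factor; truncation reflects that stage membership is defined by the
measured CLcr. This gives severe-stage cohorts a mean CLcr of ~26 at age
20 falling to ~17 at age 70 — the within-stage aging that a flat,
age-independent uniform draw cannot produce — while keeping 100% band
containment. Creatinine for staged individuals is back-computed so that
the generated record is internally consistent to 1e−9.

**What the generator does not emulate.** No pediatric or pregnant
populations, no hemodialysis or end-stage physiology (anuric subjects keep
otherwise-normal organ function with `CL_R = 0`), no ethnicity-specific
physiology, no frailty covariates (e.g. mechanical ventilation), and no
correlation between creatinine and muscle mass at the individual level.
Passing tests therefore demonstrate internal consistency and agreement
with the reproduced population predictions — not validity in, say,
critically ill patients.

## Numerics

The compartment system is linear and time-invariant within each dosing
segment, so it is solved exactly: one eigendecomposition of the 14×14 rate
matrix per individual, with boluses as state jumps and infusions as
piecewise-constant inputs. Cumulative urine and bile are the analytic
integrals of the venous and liver states (with a series limit for
near-zero eigenvalues), so mass balance holds to numerical precision at
every output time — the 0.5%-of-dose conservation check is met trivially
rather than by solver tuning. An independent `deSolve::ode` integration of
the same rate matrix serves as the oracle in the test suite.

Sampling grids are log-spaced early (from 0.01 h — the post-bolus venous
mixing spike decays with the cardiac-output time constant, and the dense
early points keep the log-trapezoid AUC error below ~0.2%) and extend to a
renal-class-dependent horizon: 24 h (normal), 36 h (mild), 48 h
(moderate), 72 h (severe), 240 h (anuric), chosen as ≥8 terminal
half-lives. NCA conventions: linear-up/log-down trapezoid; λz by
log-linear regression over the best adjusted-R² window of the last 3–6
positive points excluding Cmax, ties resolved toward more points;
`AUC∞ = AUC_last + C_last/λz`; twice-daily regimens are simulated to the
fifth dose and summarized by the final-interval AUC_tau. Cohort statistics
are arithmetic means ± SD with 5th–95th percentile bands, matching the
"mean ± SD" presentation of the tables being reproduced.

## Study library

Sixteen published designs (plus two model-application designs) ship as one
YAML per study: dose and route (including 15 mg/kg weight-based dosing and
a 0.5 g reduction in one severe arm), age range, sex split (0.5 when
unreported), and the renal-function model. Where a study reports a CLcr
range, individuals are drawn uniformly from it — BSA-normalized first when
the study reported mL/min rather than mL/min/1.73 m². One dose
discrepancy was resolved in favour of internal consistency: the
younger/elderly bolus study whose observed AUC (~134 h·mg/L) and clearance
(~7.5 L/h) imply 1 g is encoded as 1 g even though the demographic table
prints 2 g. Every arm runs as 20 virtual trials × 10 subjects with child
seeds derived from one master seed, and `predicted_observed_table()`
applies the closed-interval 2-fold acceptance rule, omitting (not
failing) parameters with no observed value.

Known replication limits: the study with ⁵¹Cr-EDTA-measured clearance in
normal-function elderly is over-predicted in AUC (its observed clearances
are higher than all comparable studies — the one acknowledged outlier),
and the male-only young cohort with EDTA-measured CLcr of 101 ± 6.5 cannot
be matched by any Cockcroft–Gault-based generator that also reproduces the
reference clearance predictions, since Cockcroft–Gault overestimates
measured GFR in young men; the mixed-sex demographic groups are matched
within 1 SD.

## Problem sizes

Default cohorts are 200 subjects (20 × 10), the grid is 6 ages × 4 classes
× 200 male subjects, and the exact solver makes a full grid-plus-studies
acceptance run complete in well under a minute; unit tests use scaled-down
cohorts (15–50 subjects) where only structure, determinism or ordering is
being asserted.

```{r example}
library(ceftazpbpk)
grid <- run_age_ri_grid(n_per_cell = 200, dose = 2000, seed = 1)
print(grid)
plot(grid)
```
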