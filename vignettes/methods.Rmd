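---
title: "A reduced-order cardiovascular-renal model for antihypertensive therapy simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order cardiovascular-renal model for antihypertensive therapy simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Purpose and scope

`htnsim` simulates mono- and dual antihypertensive therapy in populations of
virtual hypertensive patients. Its three layers are

1. a **pharmacodynamic drug layer**: each drug multiplies its target
   variables by `1 - E(D)` (inhibition) or `1 + E(D)` (stimulation), with the
   aggregate magnitude per target summed over the active drugs of a class;
2. a **reduced-order physiology core**: a beat-averaged
   cardiovascular-renal model with a renin-angiotensin-aldosterone (RAAS)
   cascade, exposing every drug target as an explicit multiplicative site;
3. a **population layer**: constrained generation of virtual patients,
   per-drug gain calibration against clinical response tables, 4-week
   treatment simulation, and population statistics.

The physiology core is deliberately small: five slow states (total
exchangeable sodium, pulmonary venous volume, renin, angiotensin I,
angiotensin II) plus an algebraic closure for the beat-averaged
hemodynamics. It is a surrogate for far more detailed multi-compartment
models; what it preserves is the *control structure* — Frank-Starling
ventricles, a baroreflex, renal pressure natriuresis, and the RAAS — rather
than anatomical detail.

## The drug layer

Effect magnitudes are fixed per (drug, dose) pair: aliskiren follows the
saturating dose-response `E(D) = 0.99 D / (D + 20)` (half-maximal at
20 mg/day); the chronic systemic vasodilation of hydrochlorothiazide ramps
linearly over 1,950,000 s (about 22.6 days, consistent with the 4-6 week
recovery of extracellular fluid volume under chronic thiazide treatment)
and saturates at 0.074; every other magnitude is a constant. Only the
studied dosages are accepted; no dose extrapolation is attempted because
only aliskiren carries a dose-response formula. Combination therapy is the
union of the component effect vectors; within-class magnitudes add.

A per-drug scalar **gain multiplier** scales all of a drug's magnitudes
jointly (the aliskiren half-maximal dose is never scaled). These gains are
what `calibrate_drug_gains()` fits so that simulated population-mean
responses match the clinical response table — the same role the original
magnitude fitting plays against clinical trials. The surrogate core is not
the model the printed magnitudes were fitted in, so its calibrated gains
differ from 1; the calibration procedure, not the printed constants, carries
the quantitative burden.

## The physiology core

**Hemodynamics.** At each instant mean arterial pressure solves the
beat-averaged fixed point `MAP = HR * SV_L * SVR_eff + CVP`. Ventricular
filling maps filling pressure to end-diastolic volume through a saturating
exponential (offset 6 mmHg, capacity 600 ml), and ejection follows
`SV = K * SVmax * delta(EDV)` with the bell-shaped `delta` rising over
60 ml, peaking near 180 ml and declining by 0.002/ml beyond it —
overdistension depresses ejection, which is what makes pump failure and
cardiogenic shock representable. `K = K0 + 0.25 * sigma(H, K0)` gives
depressed ventricles the largest sympathetic headroom and vanishes at
`K0 = 0.8`. Pulse pressure is `SV/Ca`; systolic and diastolic pressure
follow the standard beat-averaged split `SBP = MAP + 2PP/3`,
`DBP = MAP - PP/3`.

**Neurohumoral factor.** `H` collects the baroreflex error
(gain `g_b = 2` on the relative distance of MAP from its set point) and
stress-receptor activity `S` (carrying the beta-blocker and diuretic
inhibition sites and an AT1 modulation with slope `sl_stress`). `H` drives
heart rate (`alpha_H = 0.35`), vascular tone (`g_H = 0.3`) and inotropy
(sigmoid slope `k_H = 0.8`); stress activity additionally drives heart rate
directly (`beta_S = 0.75`), which is the channel through which the beta
blocker achieves its chronotropic effect while the baroreflex still
produces reflex tachycardia under pure vasodilators.

**Kidney.** A three-segment resistance divider (preglomerular, afferent,
efferent) with a myogenic exponent of 2 on the preglomerular segments sets
glomerular pressure; filtration is `KfG * (Pglom - 45)` with the AT1 signal
*lowering* the filtration coefficient as it rises (slope `sl_KFG`), which
is what keeps GFR stable under RAAS blockade. Sodium handling is
proximal (fraction 0.92), a thiazide-sensitive distal segment (fraction
0.8 of delivery), and an aldosterone-regulated fine-tuning segment whose
escaping fraction closes sodium balance at baseline. Two asymmetries
matter: aldosterone *deficit* produces strong natriuresis (slope 1.4)
while aldosterone *excess* retains weakly (slope 0.3, the escape
phenomenon); the same asymmetry applies to the proximal AT1 effect
(0.3 vs 0.1). Excretion finally carries an explicit pressure-natriuresis
factor `(MAP / MAP_ref)^3.5`. Without the asymmetry, the renin rise under
thiazides cancels their own natriuresis; without the explicit
pressure-natriuresis exponent, a salt load has to travel through volume
overload before excretion can match intake.

**RAAS.** Renin secretion responds to afferent-arteriolar pressure
(exponent 1.5), distal sodium delivery (0.5) and central venous filling
(0.5, a cardiopulmonary volume-receptor surrogate), bounded to a 0.05-20
fold range through a smooth log-cap. Plasma renin activity is
`PRA = k * PRC * (1 - DRI)`; angiotensin I and II turn over through
ACE-dependent (90%, inhibitable) and independent (10%) routes;
AT1-bound angiotensin II is `(1 - ARB) * AngII` relative to baseline, and
aldosterone follows `AT1^0.7` with a strong hypokalemia brake
(`(K_eff/K)^8`) so that the thiazide potassium effect restrains its renin
rebound. All rate constants are derived from the declared baselines, so
the drug-free cascade is stationary by construction.

**Equilibrium-anchored construction.** `build_patient()` inverts the
closure: given cuff pressures, heart rate, anthropometrics and sampled
internal targets (systemic resistance, ejection fraction, filling
pressures, GFR, filtration fraction, sodium intake), it derives the
resistances, compliances, unstressed volume, inotropic states and tubular
fractions so that the drug-free state is an *exact* equilibrium at those
targets. This is the fixed-point construction the whole package leans on:
optimization then refines around a point that is already feasible, rather
than searching a 40-dimensional space blind.

## Virtual patients and populations

Clinical targets are rejection-sampled from independent normals
(default moments: SBP 160 ± 10, DBP 100 ± 10 mmHg, HR 75 ± 10 /min,
BMI 29 ± 5 kg/m², weight 80 ± 20 kg, an even sex split) against the
inclusion/exclusion rules for uncomplicated hypertension. Height is derived
as `100 * sqrt(weight / BMI)` — the dimensionally consistent reading of a
height-from-BMI back-calculation — and a draw whose height leaves 160-180 cm
is rejected as a whole.

Generation is two-stage: the renal block is fitted under fixed exchanged
boundary values (MAP from the cuff targets; cardiac output and hematocrit
sampled from physiological ranges), then the cardiovascular block is fitted
so the joint equilibrium reproduces the drawn SBP/DBP/HR, both stages using
the stochastic-ranking evolution strategy with the normalized-distance
objective and the quadratic constraint penalty. Because the constructed
seed individual already satisfies the targets exactly, small populations
(mu = 2, lambda = 8, 3 generations per stage) suffice; the strategy's role
is constraint refinement, not global search. A candidate is pre-screened
with the sodium-loading test *before* optimization, which rejects most
infeasible draws at a fraction of the cost.

The **sodium-loading test** raises intake to 0.243 mEq/min and demands
convergence to a new equilibrium with a systolic rise in (0, 25] mmHg and a
pulmonary-venous-pressure rise below 3 mmHg. In this surrogate,
parameterizations with baseline intake below roughly 0.09 mEq/min rarely
pass — their relative load is largest and the tubular dynamic range runs
out, so volume, not excretion, absorbs the step. The generator therefore
samples intake from 0.10-0.2088 mEq/min; the full 0.028-0.2088 range
remains enforced as a hard constraint. This is a known deviation of the
surrogate from more detailed tubular models, which distribute the
adaptation over more segments.

Constraint defaults come from the main physiological ranges: systemic
vascular resistance 700-1600 dyn s/cm⁵, LV end-diastolic pressure
3-12 mmHg, heart rate 60-90 /min, sodium intake 0.028-0.2088 mEq/min,
inotropic states 0.2-0.8, and total blood volume within ±10% of the
height/weight/sex regression estimate.

## Calibration and treatment simulation

`calibrate_neurohumoral()` fits, per patient, the three AT1 sensitivities
(baroreflex, stress receptors, filtration coefficient) so that equilibrium
heart rate and GFR under the renin inhibitor match their drug-free values;
the population means can then be frozen into the defaults (the shipped
defaults are such calibrated means). `calibrate_drug_gains()` fits one
scalar per drug on a deterministic 24-patient subsample — the gains
generalize across patients because all patients share the closure
constants — evaluating post-treatment equilibria (the 4-week state; the
thiazide ramp saturates within 23 days) with warm-started solves.

`simulate_treatment()` integrates the five slow states over four weeks
(2,419,200 s) with the ramp time-resolved, flags cardiogenic shock
(SBP < 90 mmHg for ≥ 30 min with cardiac index < 2.2 L/min/m² and
pulmonary venous pressure > 15 mmHg, body surface area by the Du Bois
formula), and classifies each observable's change by the 5/10% rule:
below 5% no change, above 10% a signed change, between them transitional
(compatible with both readings). The validity screen compares these
classes against a reconstructed direction-expectation table; that table is
a synthetic reconstruction from cited clinical facts and ships as an
editable data frame.

## Numerical choices

* The hemodynamic fixed point is solved by a warm-started secant iteration
  with a bracketed fallback; in circulatory collapse (no root in
  5-350 mmHg) the pressure of smallest residual is used so that shock
  trajectories remain integrable.
* Equilibria are found Newton-first (finite-difference Jacobian, 10%
  trust region) from the previous state, with a pseudo-time relaxation
  fallback that follows the physical branch; solutions on the congested,
  volume-overloaded branch (sodium beyond 1.5x baseline or pulmonary
  venous pressure above 30 mmHg) are rejected as non-physiological, which
  is also how the sodium test reports pulmonary congestion.
* Trajectories use a stiff solver (`deSolve::lsoda`) at rtol 1e-6; the
  slowest pole (sodium balance) has a time constant near one day, so four
  simulated weeks sit within 0.1% of the treated equilibrium — the
  simulate/equilibrium cross-check in the test suite asserts exactly this.
* Problem sizes were chosen to keep a full population study on one CPU in
  minutes: 50 patients for population studies, a 24-patient calibration
  subsample, (2, 8)-ES with 3 generations per generation stage, and
  (2, 6)-ES with 8 generations per drug calibration. All are arguments.

## Known limitations

* The closure constants (feedback gains, cascade exponents) are shared by
  all patients and were set by hand, once, to reproduce textbook
  hemodynamics and the expected directional drug physiology. They are
  design constants of the surrogate, not fitted quantities.
* The model's systolic response to renin-axis blockade runs 2-5 mmHg
  weaker relative to its diastolic response than clinical tables report:
  preserved stroke volume keeps pulse pressure from narrowing. Thiazide
  monotherapy inherits the same bias. Population means under these
  regimens land within a few mmHg of, but not exactly on, the calibration
  targets; the per-target residuals are reported by the calibration
  routine.
* Chronic blood pressure in this architecture is renal-dominated: systemic
  vasodilation only moves the equilibrium through its renal consequences.
  The thiazide's ramped conductivity effect therefore contributes little
  at the calibrated gain, and diastolic response under thiazide is
  under-predicted.
* The generator samples sodium intake from the upper part of its allowed
  range (see above). Correlation analyses against sodium intake retain
  spread but over a narrower support than the nominal range.
* Synthetic populations vary what the sampling rules vary (pressures,
  heart rate, anthropometrics, internal targets within constraint ranges)
  and are all "uncomplicated hypertension" by construction: no
  comorbidities, no secondary hypertension, no measurement noise, no
  adherence variation. Passing tests demonstrate internal consistency and
  faithful reproduction of the calibrated response tables, not predictive
  validity for real patients.
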