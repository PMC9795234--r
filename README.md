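# htnsim

Virtual-patient simulation of antihypertensive therapy in R.

`htnsim` is for modellers and methods researchers who want an
*in silico* clinical trial of blood-pressure drugs that runs in minutes on
one CPU: it generates populations of virtual hypertensive patients as
constrained equilibrium parameterizations of a reduced-order
cardiovascular–renal model, treats them for four simulated weeks with any
of six antihypertensive drugs (or dual combinations), and summarises the
population response.

## The model in brief

Each drug multiplies its target variables by a pharmacodynamic factor

    F = 1 ± Σ_D E(D) · d_F

where `E(D)` is the effect magnitude at dose `D` and `d_F` the 0/1
treatment indicator; magnitudes sum within a drug class. Aliskiren uses the
saturating dose–response `E(D) = E_max · D / (D + ED50)` with
`E_max = 0.99`, `ED50 = 20` mg/day; the chronic thiazide effect on systemic
conductivity ramps as `min(0.074 · t / 1.95·10⁶, 0.074)` with `t` in
seconds. The targets are explicit sites of a beat-averaged physiology core:
Frank–Starling ventricles (`SV = K · SV_max · δ(EDV)`,
`K = K₀ + 0.25 σ(H, K₀)`), a baroreflex-driven neurohumoral factor, a
three-segment renal vasculature with glomerular filtration and fractional
tubular sodium handling, and a renin–angiotensin–aldosterone cascade
(renin → Ang I → Ang II → AT1 binding → aldosterone) whose rate constants
are derived from declared baselines so the drug-free state is a fixed point.

Virtual patients are found by constrained optimization: the normalized
distance objective

    f_dist = Σ_i (ω_min / ω_i) (X_i − X_i^exp)²,   ω_i = X_i^exp

plus a quadratic penalty for physiological box constraints, minimized by a
stochastic-ranking (μ, λ) evolution strategy. Every generated patient must
additionally pass a sodium-loading test (intake stepped to 0.243 mEq/min;
systolic rise in (0, 25] mmHg with bounded pulmonary congestion).

See the methods vignette (`vignettes/methods.Rmd`) for the full model
account, parameter defaults and limitations.

## Worked example

```r
library(htnsim)

# a 5-patient virtual hypertensive population (defaults: SBP 160+/-10,
# DBP 100+/-10 mmHg, HR 75+/-10 /min, with inclusion/exclusion screening)
pop <- generate_population(5, seed = 42)
print(pop)
#> <virtual_population> n = 5 | SBP 149.6 +/- 6.0, DBP 102.0 +/- 2.6, HR 74.0 +/- 7.5

# calibrate the per-drug gain multipliers against the monotherapy
# response table, then treat everyone with enalapril for four weeks
cal <- calibrate_drug_gains(pop, seed = 1)
oc <- simulate_treatment(pop[[1]], drug_regimen("enalapril:20"),
                         gains = cal$gains)
print(oc)
#> <treatment_outcome> enalapril:20 | SBP 160.2 -> 147.6, DBP 98.1 -> 84.6, HR 74.8 -> 73.3
```

The first block prints the achieved baseline moments of the generated
population (each patient's equilibrium reproduces its drawn targets within
2 units). The treatment outcome shows the pre/post equilibrium pressures
and heart rate of one patient; `summarize_population()` aggregates outcomes
into a mean ± SD table with Kolmogorov–Smirnov p-values against baseline
and against component monotherapies, and `report()` writes the result as
CSV tables.

A thin command-line wrapper around the same functions is provided at
`inst/cli/htnsim.R` (subcommands `generate`, `sodium-test`, `calibrate`,
`treat`, `report`; all accept `--seed`).

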