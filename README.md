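# hsmcr — hard-and-soft MCR-ALS with pharmacokinetic constraints

`hsmcr` resolves time-resolved vibrational (Raman) spectra of
drug-inoculated cells into concentration profiles, pure component spectra
**and** kinetic rate constants, in one joint fit. It is aimed at
spectroscopists and chemometricians who follow a drug dose through live or
fixed cells over hours and want the uptake and response kinetics out of the
spectra, not just loadings.

## The model

The data matrix **D** (N spectra × J wavenumber channels) is factored by
the bilinear mixture model

    D = C S,        C: N × I concentration profiles, S: I × J pure spectra,

solved by alternating least squares under per-component constraints
(non-negativity on profiles and/or spectra). What makes the fit
*hard-and-soft* is a pharmacokinetic link: selected columns of **C** must
obey a saturating uptake/response ODE system

    dNb/dt = (Nrecp − Nb) · Kup · D
    dNr/dt = (Nresp − Nr) · Kresp · Nb

where `Kup` (h⁻¹) is the drug uptake rate, `Kresp` (h⁻¹ per unit bound
drug) the cellular response rate, and `Nrecp`, `Nresp` are saturation
capacities (`D` is the constant dose). At every ALS iteration the constants
are refitted to the current soft profiles by bounded Levenberg–Marquardt and
the fitted trajectories replace the linked columns. Iteration stops when the
sum of squared residuals changes by less than 1 % for 20 consecutive
iterations, or at 200 iterations.

Spectra are first normalized to the area of the phenylalanine band
(integrated over 988–1023 cm⁻¹ above a baseline fitted in 986–990 and
1021–1025 cm⁻¹). A synthetic-data module generates the full validation
study: a constant cell spectrum, a drug-binding signature with positive
doxorubicin bands (440/460/1211 cm⁻¹) and *negative* nucleic-acid features
(785/811 cm⁻¹), a slower response signature (1450 cm⁻¹), ODE-driven
dynamics on a 0–72 h half-hour grid (145 spectra) and 1 % uniform noise —
with the exact bilinear ground truth returned alongside.

## Worked example

```r
library(hsmcr)

sim <- simulate_dataset(config = simulation_config(seed = 42))
estimate_rank(sim$dataset)

cfg <- constraint_config(3, kinetic = list(
  model = kinetic_model("uptake_response"), k0 = far_k0()))
fit <- run_mcr_als(sim$dataset, cfg)
fit
```

```
Singular spectrum (first 5 values):
        sv var_pct cum_pct
1 51.87400  99.862  99.862
2  1.60120   0.095  99.957
3  0.61964   0.014  99.972
4  0.10372   0.000  99.972
5  0.10277   0.000  99.972
Hard-and-soft MCR-ALS fit: 3 components, 23 iterations (patience)
  final LOF: 1.689%  (SSR 0.01222)
  kinetic constants:
    Kup   Kresp   Nrecp   Nresp       D 
0.25220 0.09437 0.51730 0.06516 1.00000
```

Three singular values stand above the noise floor, so three components are
modelled: drug binding, cellular response, and the unaffected cell
background. Starting from constants 4–10× off the generating values
(`far_k0()`), the fit converges in 23 iterations at a 1.7 % lack of fit —
the level set by the 1 % added noise. The uptake rate `Kup` comes back at
0.2522 h⁻¹ against a generating value of 0.25 (0.9 % error). `Kresp` and the
capacities are reported in the arbitrary intensity units of the normalized
data: the scale-invariant response rate is the product
`Kresp·Nrecp = 0.0488 h⁻¹`, within 2 % of the generating `0.05`. See the
methods vignette (`vignettes/hsmcr-methods.Rmd`) for why capacities are only
defined up to this intensity-ambiguity scale.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/hsmcr.R simulate --out sim/ --seed 42
Rscript inst/cli/hsmcr.R fit --in sim/dataset.csv --config fit.yaml --out results/
```

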