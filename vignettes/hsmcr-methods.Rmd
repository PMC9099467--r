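---
title: "Kinetically constrained curve resolution of cellular Raman time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetically constrained curve resolution of cellular Raman time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmcr)
```

## The problem

A cell inoculated with a chemotherapeutic drug changes its Raman spectrum in
two overlapping ways: the drug itself (and the spectral consequences of its
binding to nucleic acids) appears quickly, and slower metabolic responses
follow. A time course of spectra is therefore a mixture whose composition
evolves along pharmacokinetic trajectories. Ordinary bilinear unmixing
(MCR-ALS) can separate such mixtures but leaves large rotational ambiguity;
regression against time assumes a linear response that the kinetics do not
obey. `hsmcr` closes the gap by forcing selected concentration profiles to
be solutions of a small pharmacokinetic ODE system whose rate constants are
themselves estimated inside the alternating least squares loop.

## Model and procedure

The data matrix $D \in \mathbb{R}^{N \times J}$ ($N$ spectra, $J$
wavenumbers) is modelled as $D = C S$ with $C \ge 0$ componentwise where
flagged, and $S$ constrained per component. The kinetic system is

$$\frac{dN_b}{dt} = (N_{recp} - N_b)\,K_{up}\,D_{dose}, \qquad
  \frac{dN_r}{dt} = (N_{resp} - N_r)\,K_{resp}\,N_b,$$

a saturating uptake followed by a response driven by the accumulated bound
drug. Both states start at zero (no pre-bound drug, no pre-existing
response) unless configured otherwise. One iteration of `run_mcr_als()`
performs:

1. **S step** — for each wavenumber channel, constrained least squares of
   the channel on the current $C$ (`nnls_rows()`);
2. **C step** — for each time point, constrained least squares of the
   spectrum on the current $S$ (`nnls_cols()`);
3. **kinetic refit** — bounded Levenberg–Marquardt of the ODE trajectories
   against the linked soft columns, warm-started from the previous
   constants (`fit_kinetic_constants()`);
4. **hard substitution** — the fitted trajectories replace the linked
   columns (`apply_kinetic_constraint()`).

The fitting error (sum of squared residuals of $D - CS$) is recorded after
each full pass. Convergence is declared when the error has changed by less
than `rel_tol` (default 1 %) for `patience` (default 20) consecutive
iteration pairs; the loop stops unconditionally at `max_iter` (default
200). A zero error is a perfect fit and converges immediately. With soft
constraints only, each half step solves its least-squares problem exactly,
so the error is non-increasing; the hard substitution can raise it
transiently — that is the cost of forcing model consistency, and the
iteration history keeps it visible.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `Kup` | h⁻¹ (per unit dose) | 0.25 | rapid uptake saturating within ~15 h |
| `Kresp` | h⁻¹ (per unit bound drug) | 0.05 | response saturating toward the end of 72 h |
| `Nrecp`, `Nresp` | arbitrary conc. | 1 | capacities; absorb intensity scale |
| `D` (dose) | dimensionless | 1 | constant; never fitted (see identifiability) |
| `rel_tol` / `patience` / `max_iter` | — | 0.01 / 20 / 200 | the stop rule stated above |
| noise fraction | of max intensity | 0.01 | 1 % additive uniform noise |
| band window | cm⁻¹ | 988–1023 | phenylalanine reference band |
| baseline anchors | cm⁻¹ | 986–990, 1021–1025 | linear baseline under the band |

Normalization divides each spectrum by its own baseline-corrected
phenylalanine band area: the band is a stable internal intensity standard in
cellular Raman spectra, and per-row normalization removes acquisition-to-
acquisition intensity drift. The baseline is one straight line fitted by
least squares to *all* grid points in the two anchor windows (not a
two-point interpolation), which is robust on 2 cm⁻¹ grids where each window
holds several points; integration is a trapezoid on the native grid with no
resampling, and window membership is a closed interval with a 1e−9 cm⁻¹
guard. A spectrum whose corrected area is not positive beyond round-off has
no reference band and raises an error naming the row.

## Identifiability and the intensity ambiguity

Two structural facts shape what the fit can and cannot return:

* `Kup` and the dose enter only as the product `Kup·D`. The dose is
  therefore treated as a known constant and never fitted; `Kup` is reported
  per unit dose and is **scale-free** — it is the parameter the method pins
  down hardest.
* Multiplying a component's concentration column by $\alpha$ and its
  spectral row by $1/\alpha$ leaves $CS$ unchanged. The capacities
  (`Nrecp`, `Nresp`) absorb this arbitrary scale and are recovered only up
  to a factor (the package never renormalizes $C$ columns or $S$ rows
  internally, so the converged scale sits near the initialization).
  Crucially, `Kresp` multiplies $N_b$ in the response equation, so it
  carries the *inverse* of the bound-drug scale: only the product
  `Kresp·Nrecp` (units h⁻¹, the saturated response rate) is
  scale-invariant. `recover_benchmark()` therefore reports, alongside the
  raw estimate, a calibrated response rate
  `Kresp_cal = Kresp_est · Nrecp_est / Nrecp_true` — the scale-invariant
  product re-expressed in the simulator's units. A real experiment obtains
  the same thing by calibrating spectral intensity against amount of
  substance.

Label switching is avoided by convention: kinetically constrained components
occupy the lowest column indices, in model state order, and the initial
profiles are the ODE solutions at the starting constants — so "binding" and
"response" keep their identities provided the starting constants preserve
the qualitative ordering (uptake faster than response). `far_k0()` is far
from the generating values (4–10×) but respects that ordering.

## The synthetic study

`default_library()` builds three pure spectra as sums of Gaussian bands
(centres, FWHM and heights in a declarative table; default FWHM ~10 cm⁻¹)
on a 400–1800 cm⁻¹ grid at 2 cm⁻¹:

* **cell** — a non-negative cellular profile with the phenylalanine band at
  1005 cm⁻¹, nucleic-acid bands at 785/811 cm⁻¹, and the usual protein and
  lipid bands;
* **binding** — positive drug bands at 440, 460 and 1211 cm⁻¹ plus
  *negative* entries at 785/811 cm⁻¹, because intercalation reduces the
  nucleic-acid band intensity; storing the signature signed keeps the
  mixture a single matrix product, and `subtractive_channels` records which
  channels are negative;
* **response** — a protein-change signature peaking at 1450 cm⁻¹.

`simulate_dataset()` integrates the two-state model on a 0–72 h grid at
0.5 h (145 spectra), mixes
`cell + 0.35·Nb(t)·binding + 0.25·Nr(t)·response`, and adds uniform noise on
`[0, 0.01·max)` — a positive, uniform noise floor of 1 % of the maximum
intensity. The amplitudes are chosen so that the subtracted nucleic-acid
features never drive any intensity negative, and so that both dynamic
signatures sit well above the noise while remaining small against the cell
background (binding and response contribute no intensity inside the
normalization window, which keeps per-row normalization a near-uniform
scaling). The exact bilinear ground truth (`C_true`, `S_true`) is returned
with the dataset, and the noiseless matrix equals `C_true %*% S_true` to
machine precision.

What the simulator does **not** emulate: fluorescence baseline drift,
cosmic-ray spikes, detector response, wavenumber miscalibration, or
cell-to-cell heterogeneity. Passing the recovery benchmark therefore shows
that the estimator is correct and well-conditioned under its stated noise
model — not that any real instrument's artefacts are handled; on real data
those artefacts must be dealt with upstream.

## Numerical choices

* **ODE integration**: adaptive explicit Runge–Kutta (`deSolve::ode`,
  method `ode45`) with `rtol = 1e-8`, `atol = 1e-10`; the systems are
  non-stiff in the relevant parameter ranges. Trajectories are clamped to
  zero within 1e−8 to absorb integrator round-off at the boundary; the
  closed-form saturating-uptake solution is kept in the package as an
  independent oracle and agrees to better than 1e−6 relative error.
* **Constrained least squares**: an exact active-set method (Lawson–Hanson
  generalised to per-variable flags: unflagged variables live permanently in
  the passive set), not clipping — clipping is not a minimizer and would
  break the monotonicity of the soft iteration. Entering variables are
  chosen smallest-index-first (Bland-style) to prevent cycling, with a
  3×problem-size outer-iteration cap. For multi-channel solves the
  unconstrained QR solution is computed for all channels at once and the
  active-set routine runs only on channels that violate a flag.
* **Kinetic refit**: `minpack.lm::nls.lm` with zero lower bounds on all
  fitted parameters, warm-started from the previous iteration; optimizer
  failure is downgraded to a warning and the best iterate is kept so the
  ALS loop never aborts.
* **Degenerate inputs**: a rank-deficient factor matrix raises an error
  with its condition number; a component whose spectrum *and* profile both
  collapse to zero mid-run is frozen at zero, excluded from subsequent
  solves, and warned about once (kinetically linked components are exempt —
  the hard substitution always restores their profile); a kinetic fit with
  fewer time points than twice the number of free parameters triggers an
  identifiability warning (sparse experimental grids genuinely cannot
  support the two-state model).
* **Output precision**: CSV writers emit 15 significant digits,
  locale-independent, so write/read round trips are exact to ~1e−12.

## Open design points, as resolved here

* Non-negativity on the spectral matrix is configurable per component, and
  by default the first kinetically constrained component is **exempt**: the
  binding spectrum must be able to carry negative nucleic-acid features,
  and clamping it would bias both the spectrum and the rate fit. Users who
  want strict non-negativity everywhere set `nonneg_spec = TRUE`.
* Unconstrained components initialize as a constant-1 profile — the least
  informative start consistent with a time-invariant background component,
  which is what the unconstrained component resolves to in practice.
* Non-negativity is applied to the soft profiles *before* the kinetic
  refit, so the refit sees physically admissible profiles.
* Normalization is applied to the final (noisy) dataset, i.e. as the last
  preprocessing step before the fit.

## Validation problem sizes

The shipped tests run the full-scale default study (145 × 701) for the
end-to-end checks: a 20-replicate recovery benchmark at 1 % noise with
far-off starting constants (median relative errors: `Kup` well under 10 %,
calibrated `Kresp` likewise), spectral-recovery diagnostics on single fits,
and oracle comparisons at 100 random parameter draws. Property-style tests
(ALS monotonicity, active-set vs exhaustive enumeration) use small random
instances (≈12 × 8, 2 components, 50–60 cases) where exhaustive oracles are
exact. `scripts/acceptance.R` re-runs the same computations from a single
seed in under a minute.

## Known limitations

* The temporal grid must resolve the kinetics: on sparse late-time grids
  the two-state model is practically unidentifiable (the package warns),
  and only the one-state uptake model is a realistic target.
* Capacities are never absolute without an external intensity calibration.
* The convergence rule watches relative changes of the residual, so a fit
  that plateaus early at a poor local solution stops; restarting from a
  different `k0` is the practical remedy.
* Augmented multi-experiment fits, closure/unimodality constraints and
  uncertainty intervals on the constants are out of scope.
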