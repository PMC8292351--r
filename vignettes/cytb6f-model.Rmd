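---
title: "A steady-state model of C3 photosynthesis with Cytochrome b6f as a regulated conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state model of C3 photosynthesis with Cytochrome b6f as a regulated conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytb6f)
```

## The model

`cytb6f` implements a steady-state model of leaf photosynthesis in which the
Cytochrome b6f complex behaves like a transistor: a conductance between the
photosystems and carbon metabolism that is maximal under limiting light and
down-regulated under saturating light. The model couples three layers:

1. **Budgets.** Linear electron flow (LEF, water → PS II → PQ → b6f → PC →
   PS I → Fd/NADPH) and cyclic electron flow around PS I (CEF1) must supply
   Fd, NADPH and ATP at exactly the rates the photosynthetic carbon
   reduction (PCR) and oxidation (PCO) cycles consume them:
   J_NADPH = 2V_c + 1.5V_o, J_Fd = V_o, J_ATP = 3V_c + 3.5V_o. ATP
   production per electron is summarized by two coupling efficiencies, n_L
   and n_C, built from an explicit proton ledger (1 H+/e- from water
   oxidation; 2 or 1 H+/e- at b6f with/without the Q-cycle; 2 or 0 H+/e-
   from the NDH pump in CEF1; 4 or 14/3 H+ per ATP at the synthase). The
   PS I : PS II flux ratio that closes all three budgets simultaneously is
   η = 1 − n_L/n_C + (3 + 7Γ\*/C) / ((4 + 8Γ\*/C) n_C), and the cyclic
   fraction of PS I flow is 1 − 1/η.
2. **Rate laws.** Each photosystem cycles between open and closed reaction
   centers; excitation is partitioned among photochemistry, constitutive
   heat loss, fluorescence, regulated heat loss (PS II only, rate constant
   K_N2) and inter-unit exciton sharing (PS II only, K_U2) in proportion to
   rate constants. b6f turnover is the product of the PQH2 occupancy of the
   Qp site and a turnover constant k\* with ceiling k_q. All rate laws are
   implemented in concentration-free ratio form: closure fractions replace
   absolute complex concentrations, and V_max(CB6F) carries the only
   absolute scale — the tabulated constants never include complex
   concentrations, so nothing is lost.
3. **Minimum rule.** A = min(A_j, A_c). In the b6f-limited regime k\* = k_q,
   the closed fraction of PS II, the PQH2 occupancy of b6f and the oxidized
   fraction of PS I share the value f = Q/(V_max/a + Q) (a = α1·K_P1/ΣK0
   is the PS I initial slope), and the potential PS I flux is the
   rectangular hyperbola f·V_max. In the Rubisco-limited regime the PS II
   flux is pinned by carboxylation; photosynthetic control is represented
   either by derating k\* (`cef_mode = "minimal"`, CEF1 only balances the
   ATP budget) or by an uncoupled regulatory CEF1 that keeps k\* = k_q
   (`cef_mode = "regulatory"`). The two modes are observationally
   equivalent in gas exchange, which the test suite asserts.

The remaining degree of freedom in each regime is closed by back-solving
either the NPQ rate constant K_N2 (fixed pigment allocation) or the
PS II/PS I cross-section split (`state_transitions = TRUE`, K_N2 = 0 below
saturation, split frozen at its saturation value above).

## Fluorescence forward operator

A PAM detector sees α2·Φ_F2·ε_F2 + α1·Φ_F1·ε_F1. The steady-state level
F_s uses the state's own yields including exciton sharing; the extreme
levels (F_m, F_m', F_o, F_o') use the open/closed rate-constant sums
*without* the sharing term — the printed coupling expressions omit K_U2 at
the extremes even though the steady-state PS II sums include it, and the
package follows those sums as printed. All derived indices (Genty yield,
Hendrickson partition, NPQ, qP, qL, k_Lake, k_Puddle) are invariant to the
absolute detector scale; `LEF_app` uses the experimenter's conventional
cross-section 0.85·0.5 = 0.425 by default, deliberately independent of the
model's fitted α2, because the diagnostic must mimic what an instrument
reports.

Two identities anchor the operator and are tested exactly: with ε_F1 = 0
and K_U2 = 0, 1 − F_s/F_m' equals the mechanistic Φ_P2, and qP equals the
open PS II fraction. For a pure lake antenna (K_U2 = ∞), 1 − qL equals the
PQH2 occupancy of b6f, which is why `estimate_vmax_b6f()` (the median of
k_Lake over light-limited records) recovers V_max(CB6F): the package tests
that round trip on a lake-type leaf at 5000 µbar CO2, where CEF1 is
negligible. For a puddle antenna the qL estimator is biased by
construction and qP/k_Puddle is the appropriate index; this is a property
of the indices, not of the implementation.

## Parameters and defaults

All defaults are the tabulated 25 °C values: K_P1 = 14.5, K_P2 = 4.5,
K_D1 = K_D2 = 0.55, K_F1 = K_F2 = 0.05 ns⁻¹, K_X1 = K_P1; k_c = 3.6 s⁻¹,
K_c = 260 µbar, k_o = 0.9 s⁻¹, K_o = 179 mbar; k_q = 300 s⁻¹ (entering
only through k\*/k_q); n_L = 0.75, n_C = 1.00; α_total = 0.85 split
0.41/0.44; V_max(CB6F) = 350 µmol e⁻ m⁻² s⁻¹; V_max(RUBC) = 100 µmol CO2
m⁻² s⁻¹; C = 200 µbar, O = 209 mbar. These give a maximum PS I
photochemical yield of 96 %, PS II 88 %, closed-state PS II fluorescence
yield 8 %, Γ\* = 37.95 µbar, η = 1.0344 (cyclic share 3 %), and a light
saturation point of 663 µmol m⁻² s⁻¹.

Decisions taken where the sources were open:

* **R_d.** The tabulated "0.01" respiration entry is read as a *fraction*
  of V_max(RUBC) — 1 µmol m⁻² s⁻¹ at the reference V_max — and exposed as
  an independent override.
* **PS I fluorescence yield.** The rate constants give K_F1/ΣK0 =
  0.05/15.1 ≈ 0.33 %, slightly below the 0.35 % sometimes quoted for
  PS I; the package uses the rate-constant definition throughout.
* **Unit policy.** O is stored in mbar, C and Γ\* in µbar; conversions
  happen inside operations, never at call sites.
* **Lake connectivity.** K_U2 = ∞ is evaluated analytically
  (Φ_P2 = (1−f)K_P2/(ΣK − f·K_P2) and the non-photochemical yields
  proportional to their rate constants), rather than by a large finite
  stand-in; tests confirm K_U2 = 10³ ns⁻¹ approaches the limit.
* **Dark pigment state.** With state transitions enabled the balance
  condition is indeterminate at Q = 0 (there is no flux to balance), so
  the dark-adapted state carries the leaf's own α1/α2; any positive light
  re-balances the split. This also makes the dark-adapted α2 an
  identifiable parameter of the inversion through the dark F_m/F_o
  records.
* **Saturation coupling.** The shared closure at the light-saturation
  point is f_sat = J'_req/V_max(CB6F) independently of the cross-section
  split (the hyperbola satisfies J' = f·V_max at any closure), so the
  split frozen above saturation is computed in closed form; an iterative
  fixed-point route would converge to the same value and is used as a
  cross-check in the tests. Below saturation the split does depend on
  closure when K_U2 > 0 and is found by a damped fixed-point iteration
  (damping 0.5, tolerance 10⁻¹²).
* **PS II-limited corner.** At high CO2 the budgets can demand more PS II
  flux than the bed can supply even with K_N2 = 0 (η → 1 while PS II's
  maximum yield is 88 % of its cross-section). The solver then lets the
  shared closure float to the value where PS II supply equals its share of
  b6f throughput and flags the state (`psii_limited`). This is why the
  simulated maximum quantum yield at 5000 µbar CO2 (0.106 mol CO2 per mol
  absorbed photons on the package's light grid) sits below the PS I-side
  analytic limit (0.113).
* **Numerical root-finding.** K_N2 has a closed quadratic form (linear for
  the lake limit) used on the fast path; the exported `solve_npq()` is a
  bracketed `uniroot` on [0, 100] ns⁻¹ (bracket widened adaptively) with
  absolute tolerance 10⁻¹⁰, and the two agree in tests. Ties between A_j
  and A_c classify as b6f-limited, keeping k\*/k_q left-continuous.

## Simulations

`simulate_case(1:12)` reproduces the canonical simulation set: absorptance
and V_max sweeps, the five proton-coupling scenarios (cyclic shares 3, 6,
14, 27 and 62 % of PS I flow — the last computes to 62.4 % from the stated
ledger), chloroplast CO2 from 100 to 5000 µbar, the four regulatory modes,
antenna connectivity with and without state transitions, and joint scaling
of the two V_max values at fixed ratio 3.5, under which the PQ poise at the
light-saturation point is invariant. Cases 1–4 report the *potential*
(b6f-limited) chain by lifting the Rubisco cap. The package's light grid
for these simulations is 0–2400 µmol m⁻² s⁻¹ in steps of 50, chosen once
as a plotting-resolution grid; the maximum absorbed quantum yield of gross
assimilation on it is 0.062 at 200 µbar CO2 and 0.106 at 5000 µbar.

## Synthetic data and inversion

`generate_dataset()` emulates the sine-wave gas-exchange/PAM protocol: an
8-h half-sine of light (peaks 200–2400 µmol m⁻² s⁻¹) sampled every 8 min,
chloroplast CO2 held constant (the simulations' convention; a stomatal
model is deliberately out of scope), fluorescence forwarded through a
configurable detector, and mean-one lognormal multiplicative noise with
configurable CV per channel. Gas-exchange records are emitted with a fixed
total conductance and transpiration so that inverting the diffusion path
recovers the prescribed chloroplast CO2 exactly.

The generator emulates steady-state sampling only: no induction
transients, no flash artifacts, no drift, and noise that is independent
across records and channels. Passing the recovery test therefore shows
that the estimator is consistent and well-identified under the sampling
design — not that real leaves satisfy the model's structural assumptions.

`fit()` estimates six free parameters (dark α2, K_U2, both V_max values,
g_m, and the PS I:PS II detector weighting ε_F1/ε_F2) by minimizing two
objectives simultaneously — a fluorescence misfit and a gas-exchange
misfit, each normalized by 2 % of the observable's dynamic range — with an
elitist NSGA-II (population 200, 300 generations, SBX crossover with
distribution index 2 — the wide setting is needed to traverse the sloppy
valley along which V_max(RUBC) and g_m compensate — polynomial mutation
with index 20 at rate 1/6, Latin-hypercube initialization, all randomness
from one seed). The arbitrary detector scale is profiled out by
weighted least squares before the misfit is computed, so only fluorescence
*ratios* inform the fit. The model is driven at each record's chloroplast
CO2, reconstructed from its own gas-exchange columns and the candidate
g_m, with state transitions permitted below saturation and the pigment
distribution frozen above — matching how the measured series is
interpreted. On a noiseless synthetic dataset the truth yields exactly
(0, 0), and the full-size GA recovers all six parameters to within 1 % of
truth at the front medians (asserted in the test suite). Published
leaf-level estimates (V_max(CB6F) ≈ 378, V_max(RUBC) ≈ 114, g_m ≈ 0.084,
ε-ratio ≈ 2, K_U2 ≈ 2.1) serve only as plausibility ranges: the underlying
single-leaf measurements are not public, so the binding contract is the
synthetic recovery.

## Known limitations

* Steady-state only: millisecond flash transients and induction kinetics
  are out of scope.
* All kinetic constants are 25 °C values; temperature is carried but does
  not rescale them.
* PS I closure is donor-side only; acceptor-side limitation is not
  represented.
* No triose-phosphate-utilization limitation, and no explicit
  proton-motive-force or lumen-pH state — photosynthetic control is
  represented by its functional effect on k\*/k_q.
* The `regulatory` CEF1 mode and the `minimal` mode cannot be
  distinguished by gas exchange; distinguishing them requires fluorescence
  observables.

## Problem sizes used in checks

The bundled tests and the acceptance script run entirely from generated
inputs: light grids of ≤ 49 points, sine-wave datasets of 61 records, a
grid-refinement oracle on 20 random parameterizations, and one full-size
NSGA-II recovery (200 × 300 evaluations). These sizes were chosen as the
smallest that exercise every regime of the solver.
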