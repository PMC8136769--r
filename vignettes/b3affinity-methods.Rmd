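---
title: "Methods: from biosensor kinetics to in vivo activity of B3 domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biosensor kinetics to in vivo activity of B3 domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b3affinity)
```

## The scientific problem

Plant B3 DNA-binding domains from ABI3, FUS3, LEC2 and VAL1 transcription
factors all recognise the same Sph/RY cis-element, yet differ sharply in
their in vivo potency: LEC2-B3 and FUS3-B3 act as autonomous, hyper-active
recognisers, while ABI3-B3 and VAL1-B3 are attenuated and depend on hormone
(ABA) signalling integrated through the rest of the protein. A small set of
clade-specific residues contacting the DNA backbone — the beta4-triad at
alignment positions 64, 66 and 69 — interconverts these behaviours, and the
quantitative bridge between the two worlds is the equilibrium dissociation
constant of the *low-affinity* binding mode and its standard binding free
energy. This package implements that quantitative chain:

1. decompose biphasic biosensor (BLI) dissociation curves into fast and
   slow first-order components;
2. fit an independent two-site kinetic model globally across protein
   concentrations with the off-rates fixed, to estimate on-rates and hence
   `Kd1 = k_fast/k_on1` and `Kd2 = k_slow/k_on2`;
3. convert `Kd` to `ΔG°` with propagated uncertainties and form the
   comparative quantities (ΔΔG°, fold changes);
4. scan B3 alignments for clade-specific structural variants;
5. quantify in vivo reporter activation per seedling and regress it on
   `ΔG°1`.

## Kinetic model and assumptions

During association, each of two independent site classes `i` on the sensor
obeys

$$\frac{dB_i}{dt} = k_{on,i}\,C\,( \mathrm{cap}_i - B_i) - k_{off,i}\,B_i,$$

with constant free protein concentration `C` (the analyte is in solution at
its nominal concentration; sensor capacity is negligible, so no depletion).
During dissociation `C = 0`. Total signal is `B1 + B2`, with the
signal-per-complex proportionality absorbed into the capacities. Under
these assumptions the model has an exact pseudo-first-order solution,

$$B_i(t) = B_{eq,i}\left(1 - e^{-(k_{on,i} C + k_{off,i})t}\right),
  \qquad B_{eq,i} = \frac{\mathrm{cap}_i\, C}{C + K_{d,i}},$$

which `two_site_timecourse()` uses by default; a numerical ODE route
(`method = "ode"`, via `deSolve::lsoda` at `rtol = 1e-12`) is kept as an
independent cross-check and agrees with the closed form to better than
1e-8 of capacity (asserted in the test suite, observed ~1e-13).

Two structural consequences are load-bearing and tested as properties:
dissociation of the two-site model is *exactly* a two-component
exponential with `k_fast = k_off1`, `k_slow = k_off2` and fast fraction
`b = B_1(t_0)/(B_1(t_0)+B_2(t_0))` at dissociation onset; and association
signal is monotone in both time and concentration, with `0 ≤ B_i ≤ cap_i`.

Site labels follow the convention that site 1 is the lower-affinity,
fast-dissociating site (`Kd1 ≥ Kd2`); constructors and fits canonicalise by
relabelling, so a label swap in an initial guess cannot change a reported
result.

## Stage 1: biphasic dissociation fit

`fit_biexponential()` fits
`v = b\,v_0 e^{-t k_{fast}} + (1-b)\,v_0 e^{-t k_{slow}}`
to the dissociation phase (clock restarted at zero at the phase boundary)
by Levenberg–Marquardt least squares. Internally the fit runs on
`log k_fast`, `log k_slow`, `logit b` and `log v0`, which enforces
positivity and the `[0, 1]` range of `b` without constrained optimisation;
standard errors are mapped back to the natural scale by the delta method.
Initial values come from a two-slope heuristic (tail log-linear fit for the
slow component, early-time residual fit for the fast one), with up to 10
seeded multiplicative-jitter restarts if convergence is poor. When the
fitted `b` lands within 0.01 of 0 or 1 the data are effectively
single-exponential; the function then reports the reduced one-rate model
with a `degenerate` flag rather than an unstable two-component fit. Fits
are per trace (per concentration); `pool_off_rates()` combines the
per-trace off-rates by inverse-variance weighting before stage 2.

## Stage 2: global on-rate estimation

`fit_on_rates()` fixes `(k_off1, k_off2)` at the stage-1 estimates and
minimises the summed squared residuals of the two-site forward model over
all traces and phases simultaneously (unweighted SSE; capacities are
shared across concentrations, reflecting identical sensor loading). The
search exploits the model structure: for fixed on-rates the capacities
enter linearly, so each candidate `(log10 k_on1, log10 k_on2)` is scored
after a two-column linear least-squares solve for `(cap1, cap2)` (variable
projection). A small seeded differential-evolution search (population 50,
rand/1/bin, bounds `log10 k_on ∈ [1, 8]`, bracketing diffusion-limited
binding) supplies the global stage, followed by Levenberg–Marquardt polish
of all four parameters; on-rate standard errors come from the local
quadratic (residual-variance scaled) approximation at the optimum. The
whole procedure is deterministic given its seed. A site fitted with
(near-)zero capacity is flagged unidentifiable and its on-rate SE set to
`NA`; a single-concentration input is accepted but warned about and
flagged, since on-rates are then weakly identified.

`compute_affinities()` forms `Kd1 = k_off1/k_on1`, `Kd2 = k_off2/k_on2`
with first-order ratio propagation
`SE_{Kd}/Kd = \sqrt{(SE_{koff}/k_{off})^2 + (SE_{kon}/k_{on})^2}`.

## Thermodynamics

`delta_g()` computes `ΔG° = -RT\ln(1/K_d) = RT\ln K_d` (kJ/mol, 1 M
standard state) with `R = 8.314` J/mol/K. The temperature default is
**298 K**: the assay temperature is not part of the published record, and
298 K is the unique round value that back-solves every one of the five
published `(Kd1, ΔG°1)` pairs to the printed 2-decimal precision
(298.15 K fails for ABI3-B3). For the uncertainty of `ΔG°`,
`delta_g_se()` defaults to the one-sided log form `RT\ln(1 + SE_{Kd}/K_d)`
— the upward shift in `ΔG°` from a one-SE increase in `Kd` — because it
reproduces all five published SEs (0.34, 0.32, 0.34, 0.51, 0.05 kJ/mol) at
2 d.p., whereas the symmetric first-order form `RT\,SE_{Kd}/K_d` does not
(it gives 0.56 for LEC2-B3 RRP). The first-order alternative is exposed
behind `method = "first_order"`. Reporting follows the conventions of the
field: `Kd` in 3-significant-figure scientific notation, free energies at
2 d.p. (`affinity_table()`).

```{r thermo}
ref <- reference_affinities()
data.frame(domain = ref$domain,
           dG1 = round(delta_g(ref$Kd1), 2),
           se = round(delta_g_se(ref$Kd1, ref$se_Kd1), 2))
```

## Clade-specific variant scanning

`find_clade_specific()` classifies an alignment column as a clade-specific
structural variant when every clade is internally invariant at the column
(one residue per clade) and at least two clades differ; columns invariant
across all sequences are excluded. Positions are 1-based uniform alignment
coordinates. Design choices where the rule leaves room: a clade with a
mixed gap/residue column is non-conserved (rule ii fails), an all-gap
clade participates with the residue `-`; residues are compared
case-insensitively; ambiguity codes (X, B, Z, ...) never count as
conserved. The scanner is verified against a brute-force per-column
double-loop oracle on seeded random alignments, and on a faithful fixture
(`b4_fixture_alignment()`) that mirrors the published variant map: 16
clade-specific positions, of which 8 separate VAL1 from a shared AFL
residue, 6 distinguish FUS3 from ABI3, and 4 distinguish ABI3 from LEC2 —
the beta4-triad 64/66/69 (ABI3 `R,R,P` vs LEC2 `K,K,S`) plus the L77V
variant.

## Activity quantification and regression

`activity_metric()` expresses CRC reporter expression as
`log10` units above a 0.01 copies/ng baseline, clamped at zero — values at
or below the detection baseline carry no evidence of activation, and the
clamp mirrors how such baselines are drawn in reporter assays.
`high_expressor_mean()` filters seedlings above a transgene-expression
threshold (3.5 log10 copies/ng for the stringent comparisons, 2.5 for the
free-energy regression), excludes callus-phenotype seedlings by default
(their CRC expression reflects a developmental transformation rather than
direct activation), and returns group means with standard errors of the
mean. `regress()` is ordinary least squares; `R² = 1 − SSE/SST`. Pairwise
group tests are deliberately out of scope — the module returns the means
and SEs from which any standard test can be run.

## What the synthetic generators emulate — and what they do not

`generate_bli_experiment()` reproduces the measurement protocol: 15 min
association, 30 min dissociation, sub-micromolar three-concentration
panels (1/2/4 × 1e-7 M; 0.2/0.4/1.0 × 1e-7 M for the tighter-binding
FUS3-B3), sampling at 1 Hz, additive i.i.d. Gaussian signal noise with
SD 0.002 signal units. Baseline/loading/quench steps are represented as a
constant zero offset, since only association and dissociation are
analysed. It does **not** simulate instrument drift, non-specific binding,
mass-transport limitation, or analyte depletion — so parameter-recovery
results here show the estimator is correct and well-conditioned under the
stated model, not that it is robust to biosensor artefacts.

The five reference regimes (`reference_kinetic_regimes()`) anchor on-rates
to the published dissociation constants (`k_on_i = k_off_i/K_{d,i}`). The
off-rates themselves are not part of the published record; the package
adopts `k_fast = 5e-3` s⁻¹ and `k_slow = 2e-4` s⁻¹ once for all regimes —
a 25-fold separation with the fast component decaying visibly within
minutes and the slow one within the 30-minute window, which is what makes
a biphasic decomposition meaningful in the first place. Capacities default
to 1.0 and 0.5 signal units.

`generate_seedling_panel()` draws per-seedling transgene expression
log-uniformly over a 2.5-log10-unit range (the >300-fold position-effect
spread of independent transformants; log-uniform asserts no more
distributional structure than that spread) and generates
`log10(CRC) = intercept + slope·log10(transgene) + noise`, floored at the
detection limit. `generate_toy_alignment()` plants exact clade-specific
columns in an otherwise invariant background, optionally with scrambled
columns guaranteed to violate within-clade conservation. All generators
are seeded and bit-reproducible.

## Numerical choices

* Optimiser tolerances: `ftol = ptol = 1e-15` (Levenberg–Marquardt), which
  recovers noiseless truths to ~1e-6 relative or better.
* DE defaults population 50 × 40 generations; the variable-projection
  objective makes candidate evaluation a closed-form computation, and the
  subsequent polish supplies the precision, so modest generation counts
  suffice (test and demonstration runs use 12–25 generations).
* Degenerate inputs: constant signals, fewer than 8 dissociation samples,
  non-positive rates/concentrations and unassigned sequences are rejected
  with validation errors; non-convergence is flagged, never silently
  zeroed.
* Tie-break at the association/dissociation boundary: the boundary sample
  belongs to dissociation with clock zero, making the total signal
  continuous across it.

## Problem sizes used in tests and the acceptance script

Recovery studies run the full two-stage chain on complete synthetic
experiments (3 traces × ~2800 samples). The test suite uses 20 noisy
replicates per regime for the Kd1-recovery property and 50 replicates for
the off-rate Monte-Carlo; the acceptance script reports the same chain at
10 replicates per regime, alongside the exact thermodynamic reproductions,
a 100-alignment scanner-vs-oracle comparison, and the noiseless
activity-chain regression. Observed performance: noiseless recovery is
exact to ~1e-13 relative; noisy median Kd1 error is ~1–2%, far inside the
20% acceptance band.

## Known limitations

* The activity regression against `ΔG°1` is demonstrated on synthetic
  panels: the per-seedling reporter measurements behind the published
  R² = 0.99 (and 0.94 for the fast-fraction correlation) were never
  released as tables, so those exact coefficients are not reproducible
  from data; the package validates the *chain* (generation → filtering →
  means → regression) instead.
* Off-rate values for the five domains are adopted, not published; only
  the `Kd` values they imply are anchored to the published table.
* The scanner demonstrates the published 16/8/6/4 site counts on a
  faithful fixture; re-deriving them from the original ortholog alignment
  would require the unpublished supplementary alignment.
* One-replicate experiments: standard errors derive from fit covariance
  (and delta-method propagation), not from experimental replication.
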