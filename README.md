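# b3affinity

Quantitative analysis of DNA binding by plant **B3 domains** — the
~110-residue DNA-binding domains of the ABI3, FUS3, LEC2 and VAL1
transcription factors that all recognise the Sph/RY cis-element yet differ
sharply in their in vivo potency. The package implements the full chain
linking in vitro binding kinetics to in vivo transcriptional activity:

* **Biphasic dissociation decomposition** — non-linear least-squares fit of
  biolayer interferometry (BLI) dissociation time courses to
  `v = b·v0·e^(−t·k_fast) + (1−b)·v0·e^(−t·k_slow)`, resolving fast- and
  slow-dissociating fractions of total binding;
* **Constrained two-site global fit** — simultaneous fit of full
  association/dissociation time courses at three protein concentrations
  under an independent two-site model (`dB_i/dt = k_on,i·C·(cap_i − B_i) −
  k_off,i·B_i`) with off-rates fixed from stage 1, yielding
  `Kd1 = k_fast/k_on1` and `Kd2 = k_slow/k_on2`;
* **Thermodynamics with error propagation** — `ΔG°1 = −RT·ln(1/Kd1)` at a
  1 M standard state, standard errors propagated through rate-constant
  ratios and onto `ΔG°`, plus ΔΔG° and fold-change comparisons;
* **Clade-specific variant scanning** — classification of alignment columns
  where every clade is internally invariant but clades differ (e.g. the
  β4-triad at positions 64/66/69 that interconverts LEC2-B3 and ABI3-B3
  behaviour);
* **Activity analysis** — per-seedling reporter quantification
  (log10 CRC copies/ng above a 0.01 baseline), high-expressor group means,
  and the linear regression of in vivo activity on `ΔG°1`.

Seeded synthetic-data generators emulate the BLI protocol (15 min
association / 30 min dissociation, sub-micromolar concentration panels,
additive Gaussian noise), per-seedling qPCR panels with a >300-fold
transgene dynamic range, and toy alignments with planted clade-specific
sites — so the entire pipeline is testable end to end without external
data.

## Worked example

Reference free energies from the published dissociation constants:

```r
library(b3affinity)
ref <- reference_affinities()
affs <- lapply(seq_len(nrow(ref)), function(i)
  affinity_result(ref$domain[i], Kd1 = ref$Kd1[i], se_Kd1 = ref$se_Kd1[i],
                  Kd2 = ref$Kd2[i], se_Kd2 = ref$se_Kd2[i]))
affinity_table(affs)
#>        domain            Kd1 (SE)            Kd2 (SE)      dG1 (SE)
#> 1     ABI3-B3 2.00E-06 (2.95E-07) 2.62E-08 (5.13E-10) -32.51 (0.34)
#> 2     LEC2-B3 3.66E-07 (5.11E-08) 2.23E-08 (4.74E-09) -36.72 (0.32)
#> 3 ABI3-B3 KKS 4.99E-07 (7.35E-08) 3.48E-08 (3.34E-09) -35.95 (0.34)
#> 4 LEC2-B3 RRP 9.00E-07 (2.05E-07) 1.86E-08 (6.12E-09) -34.49 (0.51)
#> 5     FUS3-B3 2.63E-07 (4.94E-09) 4.16E-09 (4.77E-10) -37.54 (0.05)
```

The weakest binder (ABI3-B3, `Kd1` 2.0 µM) sits 4.21 kJ/mol above the
strongest of the LEC2/ABI3 family (LEC2-B3), and the reciprocal β4-triad
mutants (`ABI3-B3 KKS`, `LEC2-B3 RRP`) each close more than half of that
gap — a 4-fold and 2.5-fold shift in `Kd1` respectively.

The two-stage kinetic fit, run on a synthetic BLI experiment generated
under the ABI3-B3 regime (noise SD 0.002 signal units):

```r
p <- reference_kinetic_regimes()[["ABI3-B3"]]
tr <- generate_bli_experiment(bli_experiment_spec(p, seed = 42))
dfit <- fit_dissociation(tr)
summary(dfit)[, c("conc_M", "b", "k_fast", "k_slow")]
#>   conc_M         b      k_fast       k_slow
#> 1  1e-07 0.1703265 0.004984002 0.0001995409
#> 2  2e-07 0.2046527 0.005025731 0.0002001093
#> 3  4e-07 0.2727537 0.004936345 0.0001985825

gf <- fit_on_rates(tr, pool_off_rates(dfit), seed = 42)
compute_affinities(gf, domain = "ABI3-B3 (synthetic)")
#> <affinity_result> ABI3-B3 (synthetic)
#>   Kd1 1.97e-06 (2.47e-08) M   Kd2 2.61e-08 (5.98e-11) M
#>   dG1 -32.55 (0.03) kJ/mol at 298 K
```

The fitted off-rates (~5.0e-3 and 2.0e-4 s⁻¹), the concentration-dependent
fast fraction `b`, and the recovered `Kd1` all match the generating truth
to ~1–2%.

Clade-specific variant scanning on the bundled β4 fixture:

```r
fx <- b4_fixture_alignment(seed = 1)
sites <- find_clade_specific(fx$alignment, fx$clades)
pairwise_distinguishing(sites, "ABI3", "LEC2")
#> [1] 64 66 69 77
extract_triad(fx$alignment, fx$clades)
#>   clade pos64 pos66 pos69
#> 1  ABI3     R     R     P
#> 2  FUS3     K     R     P
#> 3  LEC2     K     K     S
#> 4  VAL1     R     R     P
```

`run_pipeline(default_run_config(seed = 1))` ties all stages into one
reproducible run and returns a machine-readable report; a thin CLI wrapper
lives at `inst/scripts/b3affinity.R`
(`Rscript b3affinity.R simulate|fitdissoc|fitglobal|thermo|cladescan|activity|run ...`).

## Vignette

`vignettes/b3affinity-methods.Rmd` documents the models, their
assumptions, the adopted constants (temperature, off-rates, noise levels)
and the reasoning behind every open design choice.
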