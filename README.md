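# emuflux

Steady-state ¹³C metabolic flux analysis (MFA) and kinetic flux profiling
for a compact atom-mapped network covering serine synthesis, the pentose
phosphate pathway (PPP), the TCA cycle and nucleotide synthesis — the
sub-network through which PHGDH activity shapes nucleotide metabolism. It
is written for metabolism researchers who have isotopologue intensity
tables from [U-¹³C]glucose tracing (or want to prototype such an
experiment in silico) and need growth-rate-relative fluxes out the other
end.

## What it computes

* **Network model.** A plain-text carbon-transition format (atom maps,
  biomass drains, branch-reporter registry) with a packaged 19-reaction /
  21-metabolite reconstruction, `build_phgdh_network()`. Validation
  enforces carbon conservation per reaction.
* **Forward simulation.** Elementary metabolite unit (EMU) decomposition
  with cascaded linear solves gives the steady-state mass-isotopomer
  distribution (MID) of any metabolite for a flux vector *v* and tracer:
  for each EMU size the balance `A(v) X = B(v) Y` is solved directly. A
  brute-force positional-isotopomer oracle (2ⁿ states) verifies the
  cascade independently.
* **Flux estimation.** Branch-point flux ratios are read from reporter
  MIDs (e.g. de novo serine share = serine m+3 / 3PG m+3), then all
  fluxes relative to growth rate (biomass flux ≡ 1) are solved
  analytically from the ratios plus the stoichiometric matrix,
  `S v = 0`. Replicate means ± sd, condition ratios and per-flux
  t-tests follow; an EMU-based least-squares refit cross-checks the
  analytical route.
* **Kinetic flux profiling.** First-order approach-to-plateau fits
  `F(t) = F∞(1 − e^(−kt))` of labeled-fraction time courses; turnover
  flux ratios between conditions.
* **Synthetic data.** Ground-truth control and PHGDH-inhibited scenarios
  with replicate noise, plus labeling time courses, so the whole pipeline
  closes on data with known answers.

## Worked example

```r
library(emuflux)

net <- build_phgdh_network()
net
#> Atom-mapped metabolic network: 19 reactions, 21 metabolites
#>   balanced: 13  source: 7  sink: 1

# simulate the control scenario (3 replicates, 1% fraction noise) and
# estimate fluxes back from the "measured" MIDs
ctrl <- make_scenario("control")
inh  <- make_scenario("phgdh_inhibited", seed = 2)
est_c <- estimate_fluxes(simulate_mid_dataset(ctrl), net, tracer_spec(),
                         "control")
est_i <- estimate_fluxes(simulate_mid_dataset(inh), net, tracer_spec(),
                         "phgdh_inhibited")
cmp <- compare_conditions(est_c, est_i)
subset(cmp, flux %in% c("PPPOX", "PDH", "PC", "SSP", "SHMT"),
       c(flux, ratio, p))
#>     flux  ratio         p
#> 2  PPPOX 0.4314 2.997e-08
#> 4    SSP 0.4493 4.702e-04
#> 6   SHMT 1.0229 8.660e-01
#> 9    PDH 0.3819 1.170e-04
#> 10    PC 0.3892 2.747e-06
```

G6P→R5P, Pyr→AcCoA and Pyr→OAA drop to ≈0.38–0.43× control
(p < 1e-3), de novo serine to ≈0.45×, while serine→glycine stays ≈1.02×
(p = 0.87) — the generated truth is 0.4×, 0.5× and exactly 1.0×. The
matching kinetic experiment:

```r
res <- run_kfp(ctrl, inh, out_dir = tempdir())
res$turnover[res$turnover$metabolite %in% c("R5P", "AKG", "SER"), ]
#>   metabolite k_control k_treated turnover_ratio
#> 3        SER    0.0889    0.1058          1.190
#> 5        AKG    0.0963    0.0458          0.476
#> 6        R5P    0.4883    0.1977          0.405
```

The PPP and TCA reporters turn over at ≈0.4× control while the serine
pathway is spared — the kinetic counterpart of the flux comparison.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate_labeling.R` (datasets), `02_flux_estimation.R`
(estimates, comparison, least-squares cross-check),
`03_kinetic_profiling.R` (time-course fits), writing tables under
`results/`.

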