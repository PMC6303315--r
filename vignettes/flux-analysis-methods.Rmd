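---
title: "Methods: EMU-based 13C flux analysis of the serine/PPP/TCA/nucleotide network"
author: "emuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMU-based 13C flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The problem

Phosphoglycerate dehydrogenase (PHGDH) diverts the glycolytic intermediate
3-phosphoglycerate (3PG) into serine synthesis. Serine feeds glycine and
folate-bound one-carbon units into purine synthesis, while the pentose
phosphate pathway (PPP) supplies nucleotide ribose and the TCA cycle
supplies aspartate carbon for pyrimidines. `emuflux` implements a complete
steady-state ^13^C metabolic flux analysis (MFA) for this sub-network: it
simulates mass-isotopomer distributions (MIDs) under a [U-^13^C]glucose
tracer, estimates growth-rate-relative fluxes from measured MIDs via
branch-point flux ratios and an analytical stoichiometric solve, and
analyses tracer-switch labeling time courses by kinetic flux profiling.
Every stage is testable against synthetic data the package generates
itself.

## The network model

The packaged model (`build_phgdh_network()`) has **19 reactions and 21
metabolites**: glycolysis (hexokinase-lumped uptake, the triose split with
the DHAP carbon inversion, pyruvate kinase), the oxidative PPP branch
(G6P to R5P with loss of carbon 1 as CO~2~), serine synthesis (3PG to
serine), serine hydroxymethyltransferase (serine to glycine plus a
one-carbon unit from serine C3), exogenous serine/glycine/aspartate
uptake, pyruvate dehydrogenase and pyruvate carboxylase, a lumped citrate
synthase to alpha-ketoglutarate step and a lumped AKG-to-OAA step with
50/50 succinate/fumarate scrambling (two half-weight atom-map variants),
aspartate synthesis, carbamoyl phosphate from CO~2~, and de novo versus
salvage synthesis of IMP (ribose + glycine + two one-carbon units + CO~2~)
and UMP (ribose + aspartate + carbamoyl phosphate, dropping the aspartate
alpha-carboxyl at the OMP decarboxylation step).

Only the model's size and the twelve reported flux groups are fixed by the
source material; the full reaction list with atom maps is a documented
**reconstruction** shipped as a plain-text reaction file
(`inst/extdata/phgdh_network.txt`). Every operation in the package is
network-agnostic, so a corrected file can be dropped in without code
changes. Specific reconstruction decisions:

* **CO~2~ is one of the 21 metabolites** and is treated as an unlabeled,
  infinite source/sink: CO~2~ produced by decarboxylations disappears into
  the large bicarbonate pool, and CO~2~ fixed by pyruvate carboxylase and
  carbamoyl phosphate synthetase is unlabeled. Back-labeling through CO~2~
  refixation is therefore not modeled.
* **The one-carbon pool (MEETHF) is excluded from the steady-state balance
  rows.** One-carbon units are produced in excess of the purine demand and
  the surplus is oxidized/overflows; its labeling is still tracked (it
  carries serine C3). This makes the 13 balance equations plus 6 branch
  ratios exactly determine the 19 fluxes.
* **All reactions are irreversible net fluxes**; exchange fluxes are out
  of scope.
* **Biomass coefficients** (SER 0.4, GLY 0.5, ASP 0.35, IMP 0.10,
  UMP 0.08 per unit growth) are literature-plausible relative demands from
  dry-weight composition, shipped in the network file and editable there.

The reaction-file grammar writes stoichiometric multiplicity by repeating
a term with distinct atom maps (the triose split produces two 3PG terms),
because an atom map names each carbon exactly once; numeric coefficients
would be ambiguous.

## EMU simulation and its oracle

`emu_decompose()` walks backwards from the target metabolites through
every atom-map variant and stratifies the resulting elementary metabolite
units by size; `simulate_mids()` then solves one dense linear system per
size (the systems are tiny, a few dozen EMUs at most, so no sparse
machinery is used). EMU ordering is lexicographic by (metabolite,
positions) so the balance matrices are reproducible. At steady state, a
pool's MID is the production-flux-weighted mixture of its inflow MIDs,
which makes all simulated MIDs invariant to rescaling the whole flux
vector — a property the tests assert.

`enumerate_isotopomers_bruteforce()` is an independent oracle: it solves
the full positional-isotopomer balance (2^n states per metabolite, n <= 12)
by fixed-point iteration to a sup-norm tolerance of 1e-14 and
marginalizes to mass distributions. The two routes share no code beyond
the network parser, and they agree to < 1e-8 on five packaged toy
networks (chain, cleavage, convergence, a TCA-like scramble cycle with a
convolution node, split/recombine) and on the full packaged network —
including with an impure tracer.

The tracer defaults to pure [U-^13^C]glucose (per-carbon purity 1.0, no
unlabeled fraction), with both overridable in `tracer_spec()`.

## Branch ratios and the analytical solve

Flux ratios at six branch points determine the six degrees of freedom the
13 balance equations leave open. The reporter relation for each branch is
**data, not code**: a `BRANCH` line in the network file holding a small
expression over `m(met, k)` (measured m+k fraction), `m0(met)` and
`L(met)` (labeled fraction). The shipped relations are exact under the
generative model with a pure tracer:

| branch | share of | relation |
|---|---|---|
| SER | 3PG to serine | serine m+3 / 3PG m+3 |
| GLY | serine to glycine | glycine m+2 / serine m+3 |
| ASP | aspartate synthesis | labeled ASP / labeled OAA |
| OAA | pyruvate carboxylase | OAA m+3 / (m+3 + m+4) |
| IMP | de novo IMP | labeled IMP / labeled de novo precursor mix |
| UMP | de novo UMP | labeled UMP / (1 - m0(R5P) m0(ASP)) |

The anaplerosis/PDH split is registered at the OAA production convergence:
under the pure tracer, carboxylase-derived OAA is m+3 (the fixed CO~2~ is
unlabeled) while TCA-recycled OAA is m+4, so the m+3 share reads the
carboxylase fraction directly — the conventional m+3-versus-m+2-family
TCA reporter logic expressed at one node. The oxidative-PPP share needs no
reporter in this reconstruction: R5P demand is pinned by de novo
nucleotide synthesis through the stoichiometric matrix.

`solve_fluxes_analytical()` stacks the balance rows (biomass flux fixed at
one) and one linear row per ratio and solves by QR — exact, no iteration.
Guard rails: a denominator below 1e-4 marks the branch unidentifiable
(the replicate is excluded with a message); shares outside [0, 1] from
noise are clipped with a warning; a negative solved flux raises an
infeasibility error. Replicate means and standard deviations follow the
three-biological-replicate design of the emulated experiment, and
condition comparisons report per-flux ratios with unpaired Student's
t-tests (no multiple-testing correction, matching the emulated analysis).

`fit_fluxes_least_squares()` is the deliberate cross-check: it
parameterizes the flux space by the six branch shares, reconstructs each
candidate flux vector through the same analytical solve, simulates the
measured panel through the EMU cascade and minimizes squared MID
residuals (L-BFGS-B, multi-start). On noise-free data it agrees with the
analytical route to < 1e-4 relative; on noisy data the two estimators
weight errors differently and deviate at the few-percent level, which is
expected and reported, not hidden.

## Kinetic flux profiling

Labeled-fraction trajectories after a tracer switch are fitted with the
single-pool first-order model F(t) = F~inf~ (1 - e^(-kt)), the canonical
kinetic-flux-profiling form; turnover flux is J = k P for pool size P.
Initialization is deterministic (F~inf,0~ = max observed fraction;
k~0~ = 1/t~half~, fallback median time), fitting uses
Levenberg-Marquardt (`minpack.lm::nlsLM`) with box constraints
F~inf~ in [0, 1], k >= 0. A pool whose maximum observed fraction is below
0.02 is reported as `"no-labeling"` rather than given an arbitrary rate.
Precursor correction (dividing by upstream enrichment) is off by default
because the emulated figures report raw fractions. The fitted k scales
exactly inversely with a rescaling of the time axis.

## The synthetic-data generator

`make_scenario()` defines the study conditions once: control branch
shares SER 0.10 (serine uptake far exceeds de novo synthesis), GLY 0.50,
ASP 0.70, OAA 0.60, IMP 0.85, UMP 0.80; three replicates; additive
Gaussian noise of sd 0.01 on MID fractions (clipped at zero,
renormalized), the simplest model consistent with replicate s.e.m. bars
on published MID figures. These are plausible values consistent with the
qualitative statements of the source study, not its fitted values (those
exist only as figure bars). The inhibited scenario is produced by scaling
target fluxes (serine synthesis x0.5, PPP-fed nucleotide synthesis x0.4,
TCA x0.4, serine-to-glycine x1.0) and re-deriving the branch shares so
uptake and salvage rebalance the network exactly; the construction makes
e.g. the G6P-to-R5P inhibited/control ratio exactly 0.4.

Time courses use relative pool sizes (3PG 0.5, SER 5, GLY 5, R5P 0.3,
AKG 2, ASP 8) giving control turnover rates between ~0.05/min (aspartate)
and ~1.1/min (3PG), sampling times 0–120 min, and noise sd 0.02 (no noise
at t = 0: the pre-switch baseline defines zero).

What the generator does **not** emulate: natural-abundance contamination
(simulated data is born corrected; the correction matrix route is
exercised separately), peak-intensity-dependent noise, missing
isotopologues, retention-time artifacts, or isotopic non-stationarity of
the full network (the kinetic module uses the lumped first-order model
instead). Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every artifact of
real LC-HRMS data.

## Numerical choices

* MID ingestion tolerance on sum-to-one: 1e-3 (instrument rounding);
  internal tolerance 1e-6; simulated MIDs are checked to 1e-9.
* Natural-abundance correction is C-only (abundance 0.0107) by inversion
  of the lower-triangular binomial convolution matrix, with small
  negatives clipped and renormalized; it is an explicit pipeline step,
  intended on for measured data and off for simulated data, because
  fluxes at the few-percent level are sensitive to ~1% ^13^C abundance.
* Brute-force oracle: Jacobi fixed-point iteration, tolerance 1e-14,
  cap 20000 sweeps.
* Least-squares refit: L-BFGS-B on shares bounded to [1e-6, 1 - 1e-6],
  three starts (one central, two seeded-random).
* Problem sizes throughout the tests and the acceptance script: the full
  network (largest metabolite 10 carbons, 2^10 brute-force states), 100
  noise seeds for the robustness summary, three optimizer starts — all
  chosen so a complete run takes well under a minute per stage.

## Known limitations

* The reaction list is a reconstruction; the packaged file documents each
  assumption and is replaceable.
* The glycine-branch reporter (glycine m+2 over serine m+3, true values
  0.05 and 0.10 under the control truth) has high relative variance:
  with fraction noise of sd 0.01 and three replicates, the
  serine-to-glycine flux ratio between conditions carries a ~16% typical
  error, so a single default comparison cannot certify that ratio to
  within 5% of unity — it reliably shows the *ordering* (PPP and TCA
  fluxes fall much further), which is the scientific headline. Certifying
  the 5% band would need fraction noise below ~0.002 or many more
  replicates.
* Reporter relations assume a pure tracer and unlabeled exogenous
  sources; with an impure tracer they become approximations and the
  least-squares refit is the better estimator.
* No confidence intervals by profile likelihood, no absolute flux units,
  no reversible/exchange fluxes, no nitrogen or deuterium tracers.
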