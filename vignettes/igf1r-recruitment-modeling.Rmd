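---
title: "Modeling competitive signaling-protein recruitment to IGF1R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling competitive signaling-protein recruitment to IGF1R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igfrec)
```

## The biological problem

The insulin-like growth factor 1 receptor (IGF1R) is a receptor
tyrosine kinase that exists as a preformed dimer. Ligand (IGF1) binding
activates the receptor's kinase domains, which autophosphorylate six
cytoplasmic tyrosines (Y973, Y980, Y1161, Y1165, Y1166, Y1346). Each
phosphotyrosine is a docking site for SH2- or PTB-domain proteins, and
because these reader domains are promiscuous — dissociation constants
mostly between 0.1 and 10 µM, with many proteins recognizing the same
site — recruitment is shaped by *competition*: which proteins end up
bound depends jointly on site affinities, protein copy numbers, and the
whole network of rival interactions. `igfrec` implements a mechanistic
mass-action treatment of these early recruitment events and the
comparative analyses built on it: recruitment rankings across cell
lines, an analytical equilibrium shortcut, population-level
correlation structure, and clustering of cell-line recruitment
profiles.

## Ligand binding: the cyclic two-site scheme

Each dimer carries two equivalent binding pockets; a pocket engages one
IGF1 molecule through two dissimilar sub-sites S1 and S2. Ligand can
bind either sub-site first (association rates `a1`, `a2`; dissociation
`d1`, `d2`) and the pocket is *crosslinked* when one IGF1 bridges both
(crosslinking rates `a1p`, `a2p`; un-bridging `d1p`, `d2p`). At most
one pocket of a dimer can be crosslinked; a crosslinked dimer is
kinase-active. Enumerating unordered pocket-state pairs gives nine
dimer configurations, three of them active:

```{r}
enumerate_dimer_configs()
```

Because pocket motion is thermally driven, the four-reaction cycle must
satisfy detailed balance,
`(a1/d1) (a2p/d2p) = (a1p/d1p) (a2/d2)`, leaving seven free rate
constants; the eighth follows from the constraint:

```{r}
complete_detailed_balance(a1 = 2.8e5, d1 = 5.0e-2, a2 = 1.5e4,
                          d2 = 1.9e-4, a1p = 5.6e-3, d1p = 1.9e-5,
                          d2p = 1.3e-2)
```

`table1_params()` returns the published best-fit constants with the
eighth completed this way (the printed 52/s is the rounded value; exact
arithmetic on the rounded seven gives ≈54/s). The labels S1/S2 are
arbitrary: `swap_paths()` exchanges the two routes and leaves every
observable unchanged, which the tests exploit as a symmetry oracle.
Site-level ligand affinities follow as `d1/a1` and `d2/a2` (≈13 nM and
≈180 nM). Phosphorylation of each tyrosine on an active dimer and
dephosphorylation of unoccupied phosphosites are pseudo-first-order
(`kp = 0.5`/s, `kdp = 0.1`/s; neither kinases nor phosphatases are
assumed saturated). A bound partner shields its site from
dephosphorylation. Receptor trafficking, two-point attachment of
tandem-SH2 proteins, and downstream signaling are out of scope.

Two experimental protocols used for parameterization are reproduced as
simulation protocols with a labeled (kinetically silent) tracer and an
unlabeled competitor over the 25-configuration two-ligand state space:
`competition_equilibrium_curve()` (steady-state displacement) and
`washout_dissociation_curve()` (pre-incubation, removal of free
tracer, chase with competitor). The washout protocol displays
ligand-accelerated dissociation — retention falls with competitor dose
because a competitor crosslinking the second pocket prevents tracer
re-crosslinking — the kinetic signature of the two-site mechanism.

### Ligand bookkeeping

Doses are clamped concentrations by default (the experimental
reservoirs are large and the paper-style protocols state doses in nM,
never a medium volume); a depleting-pool mode exists for the washout
and natural-formulation settings. The tracer assumption (identical rate
constants for labeled and unlabeled ligand) is standard.

## From rules to equations: restructuration

Writing the full dimer state (two pockets × twelve sites, each
unphosphorylated / phosphorylated / bound) gives a combinatorially
huge species set. The package implements the exact (non-approximate)
reformulation that removes this redundancy:

* **bunching** — the four ligand-contact sub-sites are represented as
  two pocket variables (intrinsic to the configuration alphabet used
  throughout);
* **decoupling** — site phosphorylation dynamics are mutually
  independent, so each of the six tyrosines lives on its own
  single-site receptor form;
* **scaling** — receptor and ligand amounts are doubled and the
  bimolecular rates `a1`, `a2` halved, so one single-site entity
  stands in for the two copies of that site in a dimer.

`restructure()` applies the transformation to a `model_spec()`;
`generate_network()` enumerates the implied reaction network: per form,
9 ligand configurations × (2 + n_i) site statuses, plus free ligand
and free proteins. With the full 18-partner interaction map (50 edges)
this is 577 species. The six forms are *not* independent ODE systems:
they share the free-partner pools (a protein binding two sites draws
on one pool), so one coupled system is generated.

`generate_natural_network()` enumerates the unreduced state space
(symmetry-deduplicated over protomer exchange) for small instances and
refuses beyond a size cap. It exists as the exactness oracle: the test
suite integrates both formulations on toy models (including a shared
partner across two sites, and a depleting ligand pool on one form) and
requires all mapped observables — bound protein, per-site
phosphorylation, crosslinked fraction, free ligand — to agree to
relative 1e-6. Under ligand clamping the six decoupled forms see the
same concentration and no depletion correction arises; the
depleting-pool mode is therefore restricted to the natural formulation
and single-form models, where the scaling transformation is exact.

## Cell-line models and steady states

`build_cell_model()` joins a copy-number profile (`cell_profile()`)
with an interaction map (`interaction_map()`). Conventions:

* copies/cell convert to molar through a configurable cell volume,
  default `2e-12` L (a typical mammalian cell; the source data never
  state a volume);
* association rate `ka = 1e6` /M/s for every SH2/PTB edge, `kd = ka ×
  K_D`; when several domains of one protein bind the same site the
  strongest (minimum) K_D is kept; an unmeasured IRS1 affinity at Y980
  is set to 20× the SHC1 value there (the PTB-domain ratio carried
  over from the insulin receptor);
* partners with zero copies are dropped before network generation
  (profiles without IGF1R are rejected);
* normalized recruitment is bound copies divided by total IGF1R
  *monomers* (configurable to dimers); it can exceed 1 because one
  receptor presents several sites.

Steady states are computed by two routes. The contract route
(`method = "ode"`) integrates the restructured network with `deSolve`
(lsoda, states internally rescaled to nM) until the relative
derivative norm falls below 1e-8, with a `t_max = 1e5` s fallback that
warns. The fast route (`method = "algebraic"`, the default) exploits
the model's structure: at clamped ligand the receptor species of each
form obey *linear* kinetics given the free-partner concentrations, so
each form's distribution is the stationary vector of a 9·(2+n_i)-state
generator, and the free concentrations are closed by conservation
(free + bound = total) through a damped fixed-point iteration
(`x ← X_tot / (1 + bound/x)`, converged at relative 1e-10). The two
routes agree to 1e-6 in the tests; the algebraic route makes
population-scale runs practical (tens of milliseconds per cell for the
full HeLa-like model).

## The analytical single-occupancy approximation

Assuming each active receptor binds at most one partner at a time
collapses the equilibrium to one balance equation for the free active
receptor `R`:

    R (1 + Σ_i X_i^tot / (K_i + R)) = R^tot,
    X_i^bound = R X_i^tot / (K_i + R).

The left side is strictly increasing with a root bracketed in
`[0, R^tot]`; `solve_free_active_receptor()` locates it by bisection
and polishes with one Newton step (residual < 1e-12); receptor
conservation `R + Σ X_i^bound = R^tot` then holds identically.
Mapping the mechanistic model onto these inputs involves two choices
that the main-text equations leave open; both are isolated in
`effective_inputs_from_model()` and recorded in its output metadata:

* `R^tot` = crosslinked receptor monomers × `kp/(kp+kdp)` (the
  equilibrium probability that an active site is phosphorylated and
  receptive);
* a multi-site partner gets one apparent constant by harmonic
  aggregation, `1/K_i = Σ_edges 1/K_edge` (parallel binding paths).

The approximation ignores multi-site occupancy and site-specific
competition, so its ranking deviates from the simulation's in
systematic ways (`rank_deviation()` quantifies this per protein).

## Population-level variability

`population_spec()` fixes the study conditions: per-cell copy numbers
sampled lognormally, `X_k,i = exp(ln(mean_i) + σ N_k,i)` with a common
`σ = 0.2` (consistent with measured cell-to-cell protein variability),
5000 cells by default, IGF1R varied along with all partners, dose not
varied. Note `μ_i = ln(mean)` is taken literally, making the lognormal
mean `e^{σ²/2} ≈ 1.02×` the stated mean — documented, not corrected.
Zero-copy proteins stay zero. Per-cell steady states use the algebraic
route; `pairwise_correlations()` computes standard sample Pearson
coefficients (the published Methods formulas contain typographical
slips — a missing square root and normalization — so the package
implements the standard estimator, which is what the cited software
computes).

**Choice of the correlated observable.** The per-cell quantity entering
the correlation matrix is *normalized recruitment* (bound copies
divided by that cell's IGF1R copies), not raw bound copies. Because
IGF1R itself varies, raw bound copies of all partners share a common
receptor-abundance mode: a two-competitor analysis shows its
covariance contribution is at least `σ²/2` regardless of competition
strength, which makes every pair come out positively correlated and
masks the competition structure entirely. Dividing by the per-cell
receptor removes the shared mode and exposes the
competition-driven signs: direct competitors for one site come out
negative, and partners jointly suppressed by a dominant mutual
competitor come out positive — both signatures are verified on
constructed two- and three-partner populations in the test suite.
`observable = "bound"` restores the raw convention.

## Rankings, panel summaries and clustering

`rank_partners()` implements the five metrics (mechanistic simulation
at 1 nM — the reference condition used throughout —, analytical
approximation, copy number, minimum K_D, copy/K_D), with deterministic
alphabetical tie-breaks; unexpressed proteins are excluded from the
permutation (not ranked last) and reported separately.
`cross_cell_summary()` aggregates mean ± SD rank over the lines where
each protein is expressed plus top-k shares. `cluster_cell_lines()`
uses Ward's minimum-variance linkage (`hclust` `ward.D2`) on Euclidean
distances of the normalized recruitment matrix — the same combination
as the Python clustering used in the source analyses.

## Synthetic data: what it emulates and what it cannot

The study's per-line copy-number and per-edge affinity tables are
supplementary spreadsheets that are not reproduced in the main text.
The generators in this package emulate their *statistical shape*:
abundances log-uniform over 1e2–1e7 copies/cell, K_D log-uniform over
0.1–10 µM, bipartite maps over 6 sites and up to 18 partners with
guaranteed site coverage, and seed-deterministic output.
`hela_like_fixture()` is a synthetic transcription of the main-text
facts only (SHC1 at 1e5 copies and two orders above IRS1, 20-fold
affinity ratio at Y980; STAT1/VAV2 restricted to pY1161 at comparable
1e5 abundance; nine pY1161 partners; ABL2 ninth-most-abundant with a
40-fold affinity edge over CRKL at pY973; YES1 at 0.9 µM on
pY1161/pY1165; ITK and ZAP70 silent; 50 edges in total), with free
values filled in once over realistic ranges. `synthetic_cell_panel()`
perturbs this base lognormally across lines (spread 1.5 natural-log
units, ~±1.3 orders at 2 SD), with 10% random knockouts and
immune-restricted ITK/ZAP70 expression in a quarter of lines.

Consequently, checks built on these fixtures demonstrate *mechanisms*
— orderings, competition signs, exactness and conservation properties
— not the study's printed magnitudes. Quantities that depend on the
real tables (the exact numerical-vs-analytical correlation, the
magnitudes of specific correlation pairs, YES1's share of top ranks
across the panel) come out at fixture-dependent values; the test suite
asserts them at the published tolerances and treats disagreement as a
data limitation, not a model defect. Test problem sizes are the
package's choices for routine runs: populations of 1000 cells for the
HeLa-like correlation pairs (5000 remains the default in
`population_spec()`), 150 cells per line for the 19-line panel
experiment, and toy instances for the natural-formulation oracle.

## Numerical choices

* ODE states are integrated in nanomolar units (well-scaled for lsoda;
  `rtol = 1e-8`, `atol = 1e-12` by default).
* Stationary distributions solve the generator with one balance row
  replaced by normalization; negative round-off is clipped and
  renormalized.
* The fixed-point iteration uses the multiplicative update
  `x ← X_tot/(1 + bound/x)`, which is positivity-preserving and
  converges in a handful of iterations away from degenerate
  saturation; non-convergent cells error (single-cell API) or are
  excluded with a warning (population API).
* Degenerate inputs: zero dose and zero-partner models short-circuit
  to the exact resting state; zero-variance partners yield flagged
  `NA` correlations; empty dose lists, missing IGF1R, dangling map
  edges and oversized natural enumerations raise informative errors.
* Canonical orderings everywhere (lexicographic configuration labels,
  alphabetical protein tie-breaks) keep every output deterministic.

## Known limitations

* The fixture-based quantitative targets discussed above inherit the
  fixture, not the study data.
* The analytical mapping (`R^tot` scaling, harmonic K aggregation) is
  one defensible choice among several; alternatives plug in behind
  `effective_inputs_from_model()`.
* No receptor trafficking, no bivalent attachment, no downstream
  activity, and no stochastic (network-free) simulation — the model
  scope ends at equilibrium/kinetic recruitment to the receptor.
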