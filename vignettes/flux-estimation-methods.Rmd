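---
title: "Estimating metabolic fluxes from 13C mass isotopomer distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating metabolic fluxes from 13C mass isotopomer distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflux)
```

## The problem

In a stable-isotope tracing experiment an organism is fed a 13C-labeled
nutrient (here, uniformly labeled fructose) until metabolism reaches
isotopic steady state. LC-MS then measures, for each metabolite, the
fractions of its molecules carrying 0, 1, ..., n heavy carbons — the mass
isotopomer distribution (MID). How label spreads through glycolysis and
the TCA cycle depends on the relative magnitudes of the intracellular
fluxes, so the observed MIDs constrain those fluxes. `isoflux` solves this
inverse problem: it models a carbon-mapped metabolic network, predicts the
MIDs implied by any candidate flux vector, and searches for flux vectors
that reproduce the measurements under steady-state balance constraints.

## The forward model

Every metabolite pool `i` at steady state satisfies a precursor-averaging
relation: its MID is the average of the MIDs contributed by its producing
reactions, weighted by their fluxes,

$$
\tilde M_i \;=\; \frac{\sum_j v_{ji}\, M_{ji}}{\sum_j v_{ji}},
$$

where \(M_{ji}\) is the MID of `i`-molecules produced by reaction `j` and
\(v_{ji}\) the corresponding flux. \(M_{ji}\) is assembled from the
substrate MIDs through the reaction's carbon map:

* **condensation** (two substrates joined, e.g. citrate synthase): the
  product MID is the discrete convolution of the substrate-fragment MIDs;
* **carbon loss** (e.g. decarboxylation): the substrate MID is
  marginalized hypergeometrically — labeled carbons are treated as
  exchangeable among positions, so the number of labels retained when
  `k` of `n` carbons survive follows a hypergeometric law.

These two completions are the unique mass-conserving, position-agnostic
ways to evaluate \(M_{ji}\) at MID resolution. Full positional isotopomer
tracking (EMU/cumomer decompositions) would preserve positional
information through symmetric intermediates such as succinate and fumarate,
at substantially higher model complexity; it is deliberately out of scope,
and the carbon maps retain enough structure that a positional engine could
be added without changing the network declaration format.

Because the TCA cycle is cyclic, the averaging relation cannot be solved
by substitution in any pool order. We close it by fixed-point iteration:
Jacobi sweeps (every pool updated from the previous sweep's values, in
declaration order) starting from fully unlabeled pools. The map is a
convex combination of simplex vectors and contracts in practice; the
iteration stops when the largest per-entry change in one sweep falls below
`1e-12` (cap 20,000 sweeps), which keeps the distance to the true fixed
point well below `1e-10` even for slowly mixing cycles. A `damping`
argument is available for pathological networks but the default is
undamped. Predicted MIDs depend only on flux *ratios*: rescaling all
fluxes by a common factor cancels in the averaging formula.

## The network model

A network is declared in YAML: pools (with tracked carbon counts and
`source` / `internal` / `sink` roles), reactions with explicit atom maps
(every product carbon assigned to a substrate carbon; unretained substrate
carbons declared `lost`), per-reaction flux bounds, and optional extra
linear equality constraints. `buildNetwork()` validates the declaration
(complete carbon maps, produced-and-consumed internal pools, ordered
finite bounds) and assembles the steady-state balance matrix `A` with one
row per internal pool and entries +1/-1/0 for production/consumption;
`b = 0` encodes strict steady state. Reversible steps are expanded into
irreversible forward/backward pairs so that all fluxes are non-negative.

The bundled fixture (`centralCarbonNetwork()`) covers glycolysis from
glucose and fructose sources, the pyruvate node (lactate efflux, pyruvate
dehydrogenase, pyruvate carboxylase with CO2), the TCA loop
CIT → AKG → SUC → MAL → OAC with its decarboxylations, malic-enzyme
cataplerosis, and the 3PG → serine → glycine branch. Three design choices
matter:

* **Scale pinning.** MIDs determine only flux ratios, so the fixture adds
  an uptake-normalization constraint (glucose + fructose uptake = 100
  relative units) — the standard convention of reporting fluxes relative
  to substrate uptake.
* **Dietary inflows.** Unlabeled serine and acetyl-unit inflows, fixed by
  equality constraints (10 units each), are both biologically realistic
  and what makes the serine branch and the pyruvate-dehydrogenase flux
  identifiable: a branch that merely copies its precursor's MID carries no
  flux information, whereas a branch that mixes differently labeled
  precursors does.
* **Unmeasured pools.** Acetyl-CoA and oxaloacetate are flagged
  unmeasured, as is typical for LC-MS of these unstable/low-abundance
  species; their labeling is inferred through citrate.

The reference flux scenario (fructose share 60 of 100 uptake units,
lactate efflux 25, PDH 60, TCA flux 70, anaplerosis = cataplerosis 15)
satisfies every constraint exactly and is the truth used throughout the
tests. The tracer is U-13C6 fructose at purity 0.99, a documented
stand-in for a vendor-reported purity that users should replace.

## Measurement processing

Measurement tables use the schema
`metabolite, mass_level, value, replicate, condition` with explicit
0-based integer mass levels. Raw intensity patterns are corrected for
natural 13C abundance by inverting the binomial smearing matrix
\(C_{ij} = \binom{n-j}{\,i-j\,} p^{\,i-j}(1-p)^{\,n-i}\) with
\(p = 0.0107\) by default; the inversion is solved as a non-negative least
squares problem (via `pracma::lsqnonneg`) rather than direct matrix
inversion so measurement noise cannot produce negative fractions. Only
the carbon skeleton is corrected — at unit-mass resolution carbon
dominates the isotope envelope, and multi-element correction would
require elemental formulas the table schema does not carry. Replicates
are averaged arithmetically per mass level and renormalized. Labeling is
summarized per metabolite as the mean enrichment
\(\sum_m (m/n)\,x_m\) (fraction of carbon atoms labeled); the alternative
labeled-molecule fraction \(1 - x_0\) is available behind a flag since
reports differ in which convention they plot.

## The inverse problem

The objective is the plain sum of squared errors over measured (target)
metabolites,
\(L_\mathrm{total}(v) = \sum_i \lVert \tilde M_i(v) - M_i \rVert^2\),
minimized subject to \(A v = b\) and \(0 \le v_\mathrm{min} \le v \le
v_\mathrm{max}\). Which metabolites enter the loss is controlled entirely
by the network's `measured` flags.

Each local fit parameterizes the equality constraints away:
\(v = v_p + N z\) with \(N\) an orthonormal null-space basis of the
stacked equality rows (balance + extra constraints) and \(v_p\) the
minimum-norm particular solution, so equality holds to machine precision
(~1e-13) at every iterate. On the reduced coordinates we run
Levenberg–Marquardt — the natural gradient-based method for a nonlinear
least-squares objective — with a central finite-difference Jacobian
(step `1e-6` relative); trial steps that would leave the flux box are
halved until feasible, so bounds hold exactly throughout. Iteration stops
on relative loss improvement below `1e-12` or a flat gradient. Starts are
drawn uniformly inside the bounds and orthogonally projected onto the
constraint affine set; projections that land outside the box are retried
ten times and then blended toward a strictly interior reference point
found by a one-time phase-1 minimization of squared box violations.
Optimizer failure is recorded as `converged = FALSE` on the result,
never raised.

The published procedure this package implements repeats the local fit
from 10,000 random starts and keeps the 50 lowest-loss solutions; those
are the package defaults (`profile = "paper"`, roughly five minutes for
the bundled network on one core). Routine work and the test suite use the
documented desk profile of 200 restarts keeping 20, which on the bundled
noiseless scenario reaches losses of order 1e-26 and recovers every flux
to sub-ppm accuracy. Retained solutions are sorted by loss; the per-flux
ensemble mean is the reported flux and the ensemble standard deviation
measures how sharply the data pin it down. The full restart trace
(`restart, seed, L_total, converged`) is kept for auditing the selection
rule. Restart `r` uses seed `base_seed + r - 1`, making every ensemble
reproducible and resumable.

## Identifiability

Not every flux is determined by MID data. `fluxIdentifiability()`
linearizes the stacked measured MIDs around a reference flux vector
(finite differences along the null-space directions) and propagates an
assumed per-mass-level noise through the Gauss–Newton covariance
\(\sigma^2 (J^\top J)^{-1}\) back to flux space. For the bundled scenario
at noise sd 0.01 and 3 replicates this analysis classifies the glycolytic
fluxes and fixed inflows as sharply determined (predicted relative sd
below 2%), the TCA fluxes as moderately determined (6–8%), and the
lactate exchange as weak (~18%) — it is observed only indirectly through
the pyruvate mass balance. The recovery tests therefore demand 10%
accuracy only of fluxes whose predicted relative sd is at most 5%, i.e.
those the experiment determines with ~2-sigma headroom; demanding it of
all fluxes would fail for reasons the Fisher analysis predicts, not
because the optimizer underperforms.

## Condition comparison

Published tracing studies attach significance stars to per-flux bar
charts via unpaired two-tailed t-tests. The only defensible reading at
the level of this package is a per-reaction unpaired t-test (Welch by
default) across the two conditions' retained-solution flux values, and
`compareConditions()` implements exactly that, labeled as an
interpretation. Two caveats are documented rather than hidden: ensemble
solutions are optimization replicates, not biological replicates, so
p-values can be spectacularly small for differences that are tiny in
relative terms; and with noiseless data ensembles can collapse to a
constant, so the degenerate zero-variance case returns a flagged sentinel
(`t = 0, p = 1` for equal constants, `p = 0` otherwise) instead of `NaN`.
Raw p-values are primary, matching how such stars are usually computed;
a Benjamini–Hochberg column is included.

## What the synthetic generator does and does not emulate

`generateExperiment()` propagates a known flux vector to steady-state
MIDs, adds independent Gaussian noise (sd `sigma`) per mass level to each
replicate, clips at zero and renormalizes — the simplest simplex-
respecting noise model — then averages replicates exactly as the pipeline
does. Per-replicate random streams derive from the base seed by fixed
offsets, so regeneration is byte-identical. The generator's default
conditions (sigma = 0.01, 3 biological replicates) reflect the replicate
scale of the motivating fly-tracing study and a per-isotopologue error
typical of well-integrated LC-MS peaks.

Passing recovery tests on these data shows the estimator is correct and
well-conditioned under its own assumptions. It does not show robustness
to what real data add: mass-level-dependent and intensity-dependent
error, imperfect isotopic steady state, compartmentation (one pool per
metabolite is assumed), metabolite misannotation, or an incorrect network
topology. Those failure modes must be assessed per experiment.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| Fixed-point sweep tolerance | 1e-12 (cap 20,000) | keeps fixed-point error < 1e-10 |
| Balance residual accepted | 1e-6 (inf-norm) | well above the ~1e-13 achieved by the null-space parameterization |
| LM loss tolerance | 1e-12 relative | noiseless self-consistency to < 1e-8 |
| FD Jacobian step | 1e-6 relative | loss curvature is O(1) on the reduced coordinates |
| Natural 13C abundance | 0.0107 | standard terrestrial value |
| Tracer purity default | 0.99 | documented stand-in, user-replaceable |
| MID simplex tolerance | 1e-9 | validation threshold everywhere |
| Restart seeds | base + 0..n-1 | reproducible, resumable ensembles |

Degenerate inputs are rejected early with named errors: all-zero
patterns, carbon maps that drop or duplicate atoms, internal pools
without producers or consumers, pools with zero total inflow at the
candidate fluxes, inverted bounds, duplicate measurement rows.

## A small worked run

```{r worked, eval = FALSE}
sc <- centralCarbonNetwork()
exp <- generateExperiment(sc$model, sc$fluxes, sc$tracer,
                          sigma = 0.01, n_replicates = 3, seed = 42)
ens <- fitEnsemble(sc$model, exp@measurements, sc$tracer,
                   profile = "desk", base_seed = 1)
head(summarizeEnsemble(ens))
```

The README shows this run with its actual printed output; every number
there is produced by the code above.

## Known limitations

* MID-resolution only: positional isotopomers, multi-element tracers
  (2H, 15N) and resolution-dependent isotope interference are out of
  scope.
* Steady-state only: no kinetic (instationary) labeling dynamics.
* The bundled network is a faithful-scope fixture for testing and
  illustration, not a reconstruction of any particular published model;
  users fit their own biology by writing their own YAML declaration.
* Ensemble spread is a practical spread-of-solutions summary, not a
  calibrated confidence interval; profile likelihood or bootstrap would
  be needed for formal uncertainty statements.
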