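# isoflux

Steady-state 13C metabolic flux analysis from mass isotopomer
distributions (MIDs), for tracing experiments in which an organism is fed
a 13C-labeled nutrient (e.g. uniformly labeled fructose) and LC-MS
reports, per metabolite, the fractions of molecules carrying 0..n heavy
carbons. From those labeling patterns the package estimates relative
intracellular fluxes through a user-declared, carbon-mapped metabolic
network — glycolysis, the TCA cycle and adjacent branches in the bundled
example.

It is aimed at metabolomics/fluxomics practitioners who have isotopologue
tables and a network hypothesis, and want a reproducible, testable
estimation pipeline rather than a black box.

## The method

At isotopic steady state every pool's MID is the flux-weighted average of
the MIDs contributed by its producing reactions,

    M̃_i = Σ_j v_ji · M_ji / Σ_j v_ji ,

where M_ji is built from the substrate MIDs via the reaction's carbon
map: discrete convolution for condensations (citrate synthase),
hypergeometric marginalization for carbon losses (decarboxylations).
Cycles are closed by fixed-point iteration. Fluxes are estimated by
minimizing the sum of squared differences between predicted and measured
MIDs of the target metabolites,

    min_v  L_total(v) = Σ_i ‖M̃_i(v) − M_i‖²
    s.t.   A·v = b  (steady-state balance + declared constraints),
           0 ≤ v_min ≤ v ≤ v_max ,

with a multi-start procedure: by default the constrained local fit
(Levenberg–Marquardt on the equality-constraint null space) is repeated
from 10,000 random starts and the 50 lowest-loss solutions are retained;
their per-flux mean and spread are the reported estimate. Raw isotope
patterns can first be corrected for natural 13C abundance (binomial
deconvolution solved as non-negative least squares), replicates are
averaged, labeling is summarized as mean enrichment, and conditions are
compared per flux by unpaired two-tailed t-tests.

A synthetic-data generator simulates complete experiments (known fluxes →
steady-state MIDs → replicate noise → measurement tables), so the whole
inverse problem is exercised end to end without any external data.

## Worked example

```r
library(isoflux)

sc <- centralCarbonNetwork()     # bundled network + reference fluxes + tracer
exp <- generateExperiment(sc$model, sc$fluxes, sc$tracer,
                          sigma = 0.01, n_replicates = 3, seed = 42)
ens <- fitEnsemble(sc$model, exp@measurements, sc$tracer,
                   profile = "desk", base_seed = 1)   # 200 restarts, keep 20
summarizeEnsemble(ens)
```

which prints (abridged):

```
 reaction mean_flux sd_flux n_retained min_loss
    r_glc   39.9600       0         20   0.0012
    r_frc   60.0400       0         20   0.0012
  r_gapdh  100.0000       0         20   0.0012
    r_ldh   22.1609       0         20   0.0012
    r_pdh   62.7753       0         20   0.0012
     r_cs   72.7753       0         20   0.0012
     r_pc   14.8451       0         20   0.0012
```

Reading this: fluxes are relative units with hexose uptake normalized to
100. The generating truth was `r_frc = 60`, `r_pdh = 60`, `r_cs = 70`,
`r_pc = 15`; with noise sd 0.01 on three replicates the ensemble recovers
the sharply identifiable fluxes to well under 1% (`r_frc`, `r_gapdh`) and
the TCA fluxes to a few percent, consistent with the linearized
identifiability analysis (`fluxIdentifiability()`). `sd_flux = 0` here
means all 20 retained restarts found the same optimum — the retained
spread reflects solution-set variability, not biological replication.
`min_loss` is the sum of squared MID errors at the optimum.

A YAML-driven pipeline (`runSimulate()` / `runFit()`) writes flux
reports, enrichment tables, condition comparisons and a run manifest; a
thin command-line wrapper is installed at
`system.file("scripts", "isoflux", package = "isoflux")` with verbs
`simulate`, `fit`, `correct` and exit codes 0/2/3
(success/validation/runtime).

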