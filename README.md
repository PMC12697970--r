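# erythrotune

Feedback-control modeling and statistics for cytokine-tuned
erythropoiesis.

Red blood cell production is a negative feedback loop: low blood oxygen
raises erythropoietin (Epo); Epo expands erythroid progenitors and rescues
proerythroblasts (ProE) from apoptosis; new RBCs restore oxygen delivery
and Epo falls. Accessory cytokines such as IL-17A *tune* this loop. This
package is for systems biologists and computational hematologists who want
to (i) simulate and analyze that control circuit and (ii) run the
accompanying statistical pipeline on colony-assay, flow-cytometry and
single-cell RNA-seq readouts.

## The model and metrics

Four compartments — progenitors `P`, ProE/precursors `Q`, RBCs `R`, Epo
`E` — with Hill kernel `h(x; K, n) = x^n / (x^n + K^n)`:

    dP/dt = F + (gmin + Δg·h(E; Ka, na) − k_P)·P
    dQ/dt = k_P·P − k_Q·Q
    dR/dt = k_Q·h(E; Ks, ns)·Q − δ_R·R
    dE/dt = β_E·(1 − h(pO2; K_E, m_E)) + D − δ_E·E,   pO2 = c_O2·α(t)·R

`α(t)` ramps down at hypoxic onset. Performance of a parameterization is a
pair: **over-production cost** = 1/(ProE survival) at the normoxic steady
state, and **response speed** = 1/tITSE, the reciprocal root
integral-time-squared error of pO2 from target after onset. Random
ensembles over physiological parameter ranges expose a Pareto front in the
cost/speed plane; IL-17 tuning is modeled either as Epo-independent
progenitor expansion (Model 1, modulating `gmin`) or increased Epo
sensitivity (Model 2, modulating `Ka` or `Δg`), and a 72-hour four-arm
simulation compares the combined Epo + IL-17 fold-change with the product
of the single treatments.

The statistics half implements Hill dose–response fits with per-experiment
reference normalization, exact paired Wilcoxon signed-rank tests (Pratt
zero handling), Kruskal–Wallis with Conover–Iman/BY post hocs, subset PCA
with loading-group tests, observed-vs-multiplicative synergy, and a
single-cell pipeline (QC/CP10K, kNN label transfer, k = 200 neighborhood
density enrichment with pseudocount 1e-4, replicate-combined Wilcoxon DE
via Fisher's method, per-gene gaussian GLM likelihood-ratio tests,
expression-matched gene-set scores, cell-cycle phase calls). Seeded
generators (`synth_colonies()`, `synth_flow_counts()`, `synth_sc_counts()`,
`synth_reference()`) emulate every input with planted ground truth.

## Worked example

```r
library(erythrotune)

p <- erythro_params()          # calibrated baseline circuit
steady_state(p)
#>         P         Q         R         E
#>  0.989621  1.335988 16.031861  1.000000

overproduction_cost(p)         # 1 / (ProE survival 0.3)
#> [1] 3.333333

traj <- simulate_model(p, hypoxia_profile())   # alpha: 1 -> 0.6 at day 5
traj
#> Erythroid feedback trajectory: 1201 time points over [0, 60] d
#>   pO2 range [0.6771, 1.012]; final E 1.9

performance_point(p)
#>       cost    speed     titse recovered E_star tags
#> 1 3.333333 1.078976 0.9268044      TRUE      1
```

pO2 dips to 0.68 after onset and returns to within 2% of target; the
trajectory's tITSE of 0.93 gives this circuit a response speed of 1.08 at
a constitutive cost of 3.33 (seven of every ten ProE made in normoxia die).

```r
synergy_experiment(p, model_id = 1, il17_strength = 0.3)
#> Model 1 synergy at 3 d: Epo 1.138 x, IL-17 1.089 x, combined 1.252 x
#>   combined / (Epo x IL-17) = 1.0105 (~multiplicative)
synergy_experiment(p, model_id = 2, il17_strength = 0.3)
#> Model 2 synergy at 3 d: Epo 1.138 x, IL-17 1.023 x, combined 1.243 x
#>   combined / (Epo x IL-17) = 1.0674 (super-multiplicative)
```

Epo-independent tuning multiplies out (ratio ≈ 1); Epo-sensitivity tuning
is super-multiplicative — the model-level signature distinguishing the two
IL-17 mechanisms.

```r
colonies <- synth_colonies(seed = 1)          # Epo titration + IL-17 arms
percent_increase(colonies, "IL-17A")
#> IL-17A increase: 38.1% +/- 2.7% over 12 replicate pairings
coef(fit_hill(normalize_colonies(colonies), ligand = "none"))
#>   Vmax   EC50      h
#> 1.1323 0.1038 1.4087
```

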