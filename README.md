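# glomsim

Passive compartmental models and synapse-count statistics for olfactory
glomerular circuits.

## The problem

In the *Drosophila* antennal lobe, every olfactory receptor neuron (ORN) of a
given class synapses onto every projection neuron (PN) of its target
glomerulus, on both sides of the brain. The strength of each unitary
ORN→PN connection is set largely by how many synapses it contains, and that
number varies: systematically (ipsilateral connections carry ~35% more
synapses than contralateral ones, grounding odor lateralization behavior) and
unsystematically ("connection noise", a coefficient of variation of ~0.31 in
each ORN's normalized contribution to a PN's synapse pool). This package
implements the quantitative machinery needed to connect such synapse-level
wiring measurements to circuit function:

* **Morphology** — SWC skeleton I/O, inflation of wireframes into
  cylinder-cable trees, discretization into compartments by electrotonic
  length, path-length and axon–dendrite proximity statistics.
* **Passive simulation** — an implicit (backward Euler) cable-equation solver
  with tree-ordered elimination (linear cost per step, written in C++), the
  double-exponential synaptic conductance `g(t) ∝ e^(−t/τ_d) − e^(−t/τ_r)`
  (τ_r = 0.2 ms, τ_d = 1.1 ms, peak 0.1 nS), and the standard measurement
  protocols: miniature EPSPs (single synapse), unitary EPSPs (all synapses of
  one axon), attenuation, input resistance, summation efficacy.
* **Connectivity statistics** — everything computable from the ORN×PN
  synapse-count matrix: normalized contributions, contribution CV,
  ipsi/contra surplus, left–right totals, cross-PN weight correlations with
  permutation p-values and Holm correction.
* **Resampling** — permutation tests (add-one Monte-Carlo p-values), synapse
  location shuffling, and per-trial synapse-count equalization.
* **Decoding tasks** — ideal-observer odor detection and lateralization:
  fixed-count Poisson population spike trains with a 4 ms refractory period
  drive the PN models, and a threshold classifier reads out the time-averaged
  somatic voltage, comparing real against count-equalized wiring.
* **Synthetic data** — generators for branched dendrites, connectivity
  matrices, synapse placements and synapse-size tables with the statistical
  structure observed in the DM6 micro-circuit (27/26 ORNs, 3/2 PNs, ipsi
  surplus 1.35, contribution CV 0.31, side-specific shared wiring noise),
  so every stage is testable without the original EM reconstruction.

The membrane model is passive and uniform: specific membrane resistance
20.8 kΩ·cm², capacitance 0.8 µF/cm², axial resistivity 266.1 Ω·cm (whole-cell
measurements from antennal-lobe PNs). The electrotonic discretization keeps
every compartment between 0.0001 and 0.1 space constants.

## Worked example

```r
library(glomsim)

circuit <- generate_circuit(circuit_spec(seed = 1))
circuit
#> <connectivity_table> 53 ORNs (27L/26R) x 5 PNs (3L/2R), 260 connections, 6156 synapses

connection_stats(circuit)[, c("n_connections", "mean_synapses")]
#> # A tibble: 1 × 2
#>   n_connections mean_synapses
#> 1           260          23.7

contribution_cv(circuit)
#> [1] 0.290
ipsi_contra_comparison(circuit)$surplus_pct_grand
#> [1] 37.8

models <- build_circuit_models(circuit, morphology_spec(), membrane_params(),
                               seed = 1)
pn <- models[["PN_L_1"]]
conns <- measure_connections(pn$model,
                             dplyr::filter(pn$sites, orn_side == "L"))
head(conns[, c("orn_id", "n_synapses", "uepsp_mv", "efficacy")], 4)
#>   orn_id   n_synapses uepsp_mv efficacy
#> 1 ORN_L_01         27     4.89    0.746
#> 2 ORN_L_02         19     3.17    0.848
#> 3 ORN_L_03         42     6.87    0.734
#> 4 ORN_L_04         19     4.27    0.771

run_detection_task(models["PN_L_1"], circuit, conditions = c(13, 17, 20),
                   seed = 2)[, c("condition", "accuracy")]
#>   condition accuracy
#> 1        13    0.658
#> 2        17    0.926
#> 3        20    0.994
```

The generated circuit reproduces the shape of the measured one (53 ORNs, 5
PNs, 260 connections of ~23 synapses each, ~35% ipsilateral surplus,
contribution CV ~0.31). Unitary EPSPs scale with synapse count around a ~5 mV
mean; summation efficacy stays below 1 because concurrent conductances
interact. Detection accuracy rises from chance toward 1 as the odor adds
spikes above the 12-spike spontaneous baseline, and equalizing synapse counts
across axons (with the peak conductance rescaled to 0.0958 nS) improves it —
connection noise costs performance.

`run_pipeline(config)` chains all stages from a single YAML/list config and
writes per-stage CSV/JSON outputs plus a seed manifest; `autoplot()` methods
draw the connectivity heatmap, voltage traces and accuracy curves. See the
vignette (`vignettes/wiring-variability.Rmd`) for the model details and
design choices.

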