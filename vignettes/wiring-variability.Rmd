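---
title: "Models and methods: from synapse counts to circuit function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from synapse counts to circuit function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glomsim)
```

This vignette documents the models implemented in glomsim, the parameters
that matter, the numerical choices, and what the synthetic-data generators do
and do not emulate. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## The passive compartmental model

A PN dendrite is represented as a tree of cylindrical cables. Skeletons
(SWC; µm units) are *inflated*: each path between branch points becomes one
cylinder whose diameter is twice the mean node radius along the path and
whose length is the summed inter-node Euclidean distance. The soma, when
present (SWC label 1 at the root), becomes a single cylindrical compartment
with length = diameter = the soma diameter; voltage "recorded at the soma"
means this compartment. Cables are then split into compartments of equal
length such that each compartment's electrotonic length

$$L = \ell / \lambda, \qquad \lambda = \sqrt{\frac{R_m\, d}{4\, R_a}}$$

lies in $[10^{-4}, 0.1]$ (`n = max(1, ceiling(L_cable / 0.1))` per cable;
cables below the lower bound are merged into their parent's distal
compartment, with a message). With the default membrane a 1 µm cable has
$\lambda \approx 442$ µm.

Membrane parameters (preset `cell3`) are the whole-cell measurements for
antennal-lobe PNs: $R_m = 20.8$ kΩ·cm², $C_m = 0.8$ µF/cm²,
$R_a = 266.1$ Ω·cm, so the membrane time constant is
$\tau_m = R_m C_m = 16.64$ ms. Only this parameter set is published with full
precision; the `alt_low`/`alt_high` presets are synthetic ±20% variations for
robustness checks, and explicit values are accepted. The resting potential
($E_\text{rest} = -60$ mV) and synaptic reversal ($E_\text{syn} = 0$ mV,
cholinergic) are our choices: all amplitude measures are differences from
rest, so $E_\text{rest}$ only sets the driving force
$E_\text{syn} - E_\text{rest} = 60$ mV.

Each synaptic event opens a true (voltage-dependent-driving-force)
conductance $g(t) = g_\max N (e^{-t/\tau_d} - e^{-t/\tau_r})$ with
$\tau_r = 0.2$ ms, $\tau_d = 1.1$ ms, normalized so the peak (at
$t^\* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln\frac{\tau_d}{\tau_r} =
0.417$ ms) equals $g_\max$. The default $g_\max = 0.1$ nS; the
count-equalized protocols use 0.0958 nS so that mean uEPSP amplitudes are
preserved when summation efficacy rises. Equal time constants fall back to
the alpha-function limit.

**Solver.** Backward Euler on
$C_i \dot V_i = -(V_i - E_\text{rest})\,g^\text{leak}_i +
\sum_{j \sim i} g^\text{ax}_{ij}(V_j - V_i) + g_i(t)(E_\text{syn} - V_i)$
with the synaptic conductance evaluated at the start of each step and folded
into the implicit diagonal. Compartments are numbered parent-before-child, so
the symmetric tridiagonal-on-a-tree system solves in one leaf-to-root
elimination plus one root-to-leaf substitution per step (linear cost; C++).
Units are mV / ms / nF / µS / nA. Default `dt` = 25 µs; halving it moves EPSP
peaks by <0.2%, and the somatic response matches an independent stiff ODE
solver (`deSolve::lsoda`) on the identical system to <0.5% (both asserted in
the tests). Steady-state quantities (input resistance, transfer resistance)
use the same elimination without the capacitive term; a sealed cylinder
reproduces $R_\infty \coth(L)$ to 1% at mesh bound 0.01.

**Protocols.** A mEPSP activates one synapse in isolation (each simulation
contains a single event, equivalent to the sequential protocol with 200 ms
gaps); amplitudes are peak minus rest at the soma and at the synapse's own
compartment, their ratio the attenuation. A uEPSP activates all of one
axon's synapses synchronously. Summation efficacy is the uEPSP peak divided
by the *sum of mEPSP peak amplitudes*. Two effects push it below 1:
driving-force saturation where synapses crowd electrotonically, and temporal
dispersion — somatic mEPSP waveforms from different locations peak at
different times, so even the purely linear superposition has
peak(sum) < sum(peaks). Consequently efficacy converges to 1 in the
small-conductance limit only for co-located synapses, which is how the limit
is tested; for dispersed sites the small-$g$ plateau sits below 1. Peak
detection is max-over-trace minus baseline, no smoothing. Synapse positions
within a compartment are collapsed to the compartment (below mesh resolution
by construction). Per-cable input resistance is measured at each cable's
middle compartment.

## The synthetic circuit generator

The generator's defaults are the study conditions: 27 left / 26 right ORNs
(one per side unilateral, connecting only ipsilaterally), 3 left / 2 right
PNs. Counts follow the multiplicative model

$$c_{ij} = \max\!\left(1, \text{round}\!\left(b\, r^{[s_i = t_j]}
e^{f_i^{t_j}}\, d_j\, \varepsilon_{ij}\right)\right)$$

* $r = 1.35$, the ipsilateral surplus;
* $f_i^t \sim \mathcal N(-\sigma_f^2/2, \sigma_f^2)$, a per-ORN latent
  log-strength drawn **independently for each target side** ($\sigma_f =
  0.2$). This is the minimal mechanism that makes same-side PNs share wiring
  noise while opposite-side PNs do not; it is a modelling choice, not a claim
  about development.
* $d_j$, a per-PN size factor. The default (`pn_size_mode = "share"`) sets
  $d_j$ = (mean PNs per side) / (PNs on $j$'s side), conserving each
  glomerulus's synapse total; with 3 vs 2 PNs this makes individual right PNs
  receive ~50% more ORN synapses than left PNs, the analogue of the measured
  right–left difference. `pn_size_mode = "equal"` switches it off (used by
  the degenerate-circuit tests).
* $\varepsilon_{ij}$, i.i.d. lognormal noise with
  $\sigma_\varepsilon^2 = \log(1 + \text{CV}^2) - \sigma_f^2$, so the total
  CV of normalized contributions is the requested 0.31. A requested CV below
  the latent-factor floor is an explicit error.
* $b$ is solved analytically so the expected ipsilateral mean count equals
  `mean_syn_ipsi`. The default 26.3 makes the grand mean over all 260
  connections ≈ 23, the observed figure, given the 133/127 ipsi/contra split
  implied by two unilateral ORNs.

Counts are rounded lognormals: strictly positive and right-skewed, chosen
because only the mean and CV of the real distribution are known. The
calibration (ipsi mean, surplus, CV, each within 5% over 100 seeds; positive
same-side and null opposite-side contribution correlations) is asserted in
the tests.

**Morphologies** are grown tips: exponential inter-branch intervals
(`branch_rate` per µm), binary branching, a fixed radius taper (0.9) at each
branch point so radii never increase away from the soma, 2 µm node spacing,
and growth stops exactly at the target path length (tips whose radius falls
below 0.05 µm retire; if all retire early the generator fails rather than
truncating silently). The default target of 1500 µm with a 0.6 µm primary
neurite was calibrated once so that the mean unitary EPSP under the default
circuit and synapse model is ≈5 mV, the amplitude anchor for these synapses;
it was not tuned further. Synapses are placed uniformly per unit path length,
independently across ORNs, and bound to compartments through the cable
arc-length bookkeeping.

**Synapse sizes** (T-bar volume, contact area) are correlated bivariate
lognormals grouped by connection; defaults (per-synapse CV 0.5, log-scale
correlation 0.5, means 2×10⁶ nm³ and 10⁵ nm²) are round numbers of the right
order, chosen once. What matters for the analyses is the relative structure:
the 1/√n shrinkage of per-connection-mean CVs and the independence of mean
size from synapse count, both asserted in tests.

What the generator does *not* emulate: glomerular geometry, axon
trajectories, distance-dependent synapse clustering, multiglomerular inputs,
or any developmental mechanism. Passing tests therefore show that the
pipeline recovers the statistics it was given and reproduces the qualitative
orderings — not that real dendrites behave like the synthetic ones.

## Resampling machinery

Permutation tests pool the two samples and re-split at the original sizes
(mean difference) or permute one vector (Pearson correlation), two-sided,
with the add-one rule $p = (1 + \#\{|T_0| \ge |T|\})/(1 + n)$ — never zero,
exact in expectation. Default 10,000 permutations (the original count is
unstated; it is configurable). Holm correction delegates to
`stats::p.adjust`. Paired t-tests delegate to `stats::t.test`. Location
shuffles permute the pooled synapse locations while each axon keeps its
count; equalization gives every axon $\lfloor N/k \rfloor$ or
$\lfloor N/k \rfloor + 1$ sites (remainders randomly assigned), re-drawn
independently on every trial.

## Decoding tasks

Spike trains are conditioned Poisson: exactly $n$ spike times uniform on a
200 ms window, each assigned to a uniformly random ORN; trials violating the
4 ms same-ORN refractory period are rejected and redrawn whole. (The
alternative reading — generating whole trains first and then assigning trains
to axons — collapses to the same distribution under a fixed population count,
so only per-spike assignment is implemented.) The spontaneous baseline is 12
spikes: a 58 Hz pooled spontaneous event rate over 26.5 ORNs gives
2.2 spikes/s/ORN, times 0.2 s times the population. Odor conditions raise the
count to 13–20.

The classifier is a threshold on one scalar — the time-averaged somatic
depolarization µ over the stimulus window for detection, the left-mean minus
right-mean of per-PN µ values for lateralization (every PN receiving both
antennae's trains). Orientation comes from the class means; the threshold
minimizes training error with ties broken toward the midpoint of class means;
accuracy is reported on held-out trials only (default 250 train / 250 test
per class; the full-scale protocol of 2500/2500 is a parameter).

Trial responses use a linearity-exploiting fast path: the somatic response to
a single event at each synapse-bearing compartment is simulated once with
the full solver, its cumulative time-integral is tabulated on a 0.1 ms grid,
and a trial's µ is the superposition $\sum_s I_{c(s)}(T - t_s)/T$ over
spikes. This is exact up to the interaction between *concurrent* conductance
events, which is small in the 0.1 nS regime (the full solver remains the
reference and the two agree on the solver tests). Under equalized wiring the
site-to-axon assignment is re-drawn per trial per antenna pool and
$g_\max = 0.0958$ nS.

Expected behavior, asserted in the tests at reduced scale: chance accuracy
when both classes have 12 spikes; accuracy monotone in the odor spike count;
equalized wiring at least as good as real wiring (sign test over PNs ×
conditions); lateralization below detection at matched surplus (the decision
variable differences two noisy quantities whose wiring noise is correlated
within sides but not across); and with the generator's connection CV near 0
the real/equalized gap vanishes — the gap is caused by count dispersion
alone.

## Problem sizes and runtime choices

The test suite and acceptance script run on synthetic PNs of 1500 µm
(~100–200 compartments at mesh bound 0.1) with 250/250 trials per class and
conditions sampled from {12, 13, 14, 16, 17, 20}; wiring statistics average
over 25–100 generated circuits; the type-I-error check uses 1000 null
permutation tests of 500 permutations each. These sizes were chosen to keep
the full suite in the minutes range while leaving every assertion
well-powered; all are parameters, and paper-scale settings (2500/2500 trials,
10,000 permutations, finer meshes) are plain argument changes.

## Known limitations

* Passive membranes only: no active conductances, spiking PN output,
  synaptic depression/facilitation, or inhibitory interneurons.
* The morphology generator reproduces path length, branching and taper
  statistics only in a generic way; electrotonic detail of real arbors
  (e.g. the measured left-right asymmetries of reconstructed cells) is out of
  reach of any statistical generator, so left-right *electrophysiological*
  contrasts are demonstrated qualitatively, not numerically.
* The per-connection mEPSP-consistency CVs depend strongly on the morphology
  realization; the shuffle control's informative output is the real-versus-
  shuffled comparison, not the absolute CV.
* Synapse sizes do not feed back into conductance: every event has the same
  $g_\max$, mirroring the uniform-conductance assumption justified by the
  low across-connection variability of synapse sizes.
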