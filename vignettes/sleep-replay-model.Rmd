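---
title: "A thalamocortical model of sleep replay and sequence memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamocortical model of sleep replay and sequence memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcreplay)
```

## The scientific question

Sequentially training two memories that compete for the same synapses
erases the older one — catastrophic forgetting.  `tcreplay` implements a
conductance-based thalamocortical network in which spike sequences are
trained by spike-timing-dependent plasticity (STDP) in an awake-like
state, and then spontaneously replayed during simulated slow-wave (N3)
sleep.  The package exists to study how sleep replay reorganises the
plastic weight matrix: strengthening a single trained sequence, and —
when two opposite sequences share one population — segregating neurons
and synapses into subsets specific to one memory or the other
(orthogonalisation), so that both can be recalled after sleep.

## The model

**Populations and connectivity.**  Four populations on a line: 500
cortical pyramidal cells (PY), 100 cortical interneurons (IN), 100
thalamocortical relay cells (TC) and 100 thalamic reticular cells (RE)
at full scale.  All projections are topographic and radius-limited
(`default_projections()` lists the thirteen projections with their
printed radii, e.g. R = 20 for PY→PY AMPA, R = 8 for TC→RE).  The
PY→PY AMPA projection is probabilistic (p = 0.6), Gaussian-initialised
(mean 0.075 µS, truncated at 0 and `g_max`), and is the only plastic
projection.  Everything else is deterministic within its radius and
fixed in strength.

**Neurons.**  PY and IN are two-compartment Hodgkin–Huxley models: the
dendrite carries fast Na⁺, persistent Na⁺, slow non-inactivating K⁺
(Km), Ca²⁺-dependent K⁺ (KCa, fed by a decaying intracellular Ca pool
loaded by a high-voltage-activated Ca current), a cholinergically
scaled K⁺ leak and a Cl⁻ leak; the axo-somatic compartment carries
fast Na⁺/K⁺ and is treated as fast — its current balance
`g(V_D − V_S) = −ΣI_S` is solved algebraically each step, which is
linear in `V_S` once the gating states are frozen for the step.  IN
omit the persistent Na⁺ current.  TC and RE are single-compartment
models with fast Na⁺/K⁺, a low-threshold Ca²⁺ current (the burst
generator) and, in TC only, the hyperpolarization-activated mixed
cation current I_h, whose activation curve
`1/(1 + exp((V + 75 + HA_gh)/5.5))` is shifted by the histamine level.
Gating variables follow `dx/dt = −(x − x_∞)/τ_x` with
`τ_x = 1/((α+β)·Q_T)` and the temperature factor
`Q_T = Q^((T−23)/10) = 2.9529` (Q = 2.3, T = 36 °C).

The membrane equations fix which currents exist; the rate functions and
conductances behind them are not uniquely determined by those
equations, so this implementation uses standard published kinetics for
each current (Traub-type spike currents, the usual low-threshold Ca²⁺
and I_h parameterisations, Mainen-type dendritic channels) with every
conductance exposed in `sim_params()`.  Two consequences of the
algebraic-soma reading are worth recording: the axo-somatic Na⁺/K⁺
kinetics must be threshold-shifted (Traub-style) for the soma to fire
repetitively under the algebraic constraint, and `Q_T` is applied to
the cortical gating rates only — the thalamic spike currents and the
low-threshold-Ca/I_h time constants are taken from kinetics already
specified at body temperature, and scaling them again would make them
unphysically fast.

**Synapses.**  AMPA, NMDA (with the standard sigmoidal magnesium
block), GABA_A and (RE→TC) slow GABA_B.  Open fractions are aggregated
per target neuron with single-exponential decay (a two-stage cascade
for GABA_B); a presynaptic spike increments the target's conductance by
the edge weight times the available resources.  Short-term depression
of intracortical AMPA follows the resource model
`D = 1 − (1 − D_i(1−U)) exp(−(t−t_i)/τ)` with U = 0.073 and τ = 700 ms.
Miniature PSPs on the PY→PY, PY→IN and IN→PY projections are
inhomogeneous Poisson processes whose hazard after a presynaptic spike
at `t0` is `(2/(1+exp(−(t−t0)/υ)) − 1)/250` per ms (υ = 30), sampled
exactly by thinning against the 4 Hz ceiling; mini amplitudes start at
the printed conductances (0.03/0.02/0.02 µS) and, on the plastic
projection, evolve with STDP.  A dimensionless per-projection gain
(0.15 for the cortical projections) converts these paper-scale
conductances into effective postsynaptic conductances so that unitary
PSPs lie in the physiological 0.5–3 mV range; the gain multiplies
weights and minis alike, so all weight-level semantics (the 0.065
classification threshold, `g_max`) remain on the paper's scale.

**Plasticity.**  Nearest-neighbour STDP on PY→PY AMPA:
`F(Δt) = A₊e^(−|Δt|/τ₊)` for post-after-pre, `−A₋e^(−|Δt|/τ−)`
otherwise (τ± = 20 ms; A± = 0.002 balanced; A₋ = 0.001 during
training; exact ties Δt = 0 produce no update).  Weights move by
`g_max·F(Δt)`, clipped to `[0, g_max]`; mini amplitudes move by
`f·A_PY-PY·F(Δt)` with f = 0.01, floored at 0.  Each spike pairs with
the most recent spike of the opposite neuron, the same nearest-spike
convention the replay analysis uses.  No homeostatic mechanisms are
implemented.

**Arousal states.**  `arousal_state()` bundles the neuromodulation:
GABA_A scaling 0.22 → 0.44 (IN-sourced) and 0.6 → 1.2 (RE-sourced),
cortical AMPA 0.133 → 0.4332, thalamocortical AMPA 0.6 → 1.2 going from
awake to N3.  The cholinergic K-leak scales and the histamine shift are
not printed constants; they are calibrated once so the network meets
its dynamical contracts (below) and then frozen.  The calibrated
thalamic scales follow the expected direction (less acetylcholine in
sleep → more K leak: 0.5 → 2.5 for TC, 0.5 → 1.0 for RE; histamine
shift −8 mV → 0).  The cortical scales came out inverted (0.6 awake →
0.25 N3): at one-fifth scale the N3 cortex must ignite Up states from
miniature-PSP coincidences, which needs a resting potential closer to
threshold than the awake state, whose excitability is in turn bounded
by the recall readout (background spiking must not drown the evoked
response).  The awake/N3 contrast is otherwise carried entirely by the
printed synaptic scalings.  This is a known desk-scale compromise, not
a claim about cholinergic physiology.

## Protocols

Training presents each letter group with a 10 ms DC pulse, 5 ms between
pulses, one sequence sweep per 1 s trial; testing pulses only the first
group and reads the response within 350 ms; probing stimulates every
group alone (for response-delay analysis); sleep delivers no input.
The pulse amplitude is not printed in the source material; it is
calibrated so that a stimulated group spikes reliably
(`calibrate_stim_amplitude()` bisects the threshold on an isolated
cell).  Two amplitudes are used: training pulses (default 0.7 nA) must
fire their group against the feed-forward inhibition left by the
preceding pulse, while the isolated first-letter test pulse uses a
smaller amplitude (default 0.45 nA) that avoids over-driving the
network and blurring the evoked sequence.  Wake↔sleep transitions are
instantaneous parameter switches.  STDP stays on (balanced) during
testing; `stdp_enabled = FALSE` reproduces the plasticity-off control.
Runs start with a 0.5 s unrecorded settling period.

## Analysis suite

* **Recall**: per group, the mean instantaneous rate in the 350 ms
  response window is smoothed with a 50 ms Gaussian kernel on a 1 ms
  grid (kernel width read as ±2 SD); the order of smoothed-rate peak
  times over groups with at least one spike is the recalled word.
  Equal peaks break toward the earlier time, then by group index.
* **String match**: `SM = (2N − Σ|L_i − i|)/(2·|ideal|)` with
  `N = |S_test|`; recall succeeds at SM ≥ 0.8 and performance is the
  percentage of successful trials.  Reading the normalisation literally
  means missing letters cap SM below 1 and full reversals score
  negative (ABCDE vs EDCBA → −0.2).
* **Up states**: spikes chained at 15 ms, candidates merged when closer
  than 300 ms, and an interval counts only when flanked on both sides
  by ≥ 300 ms of silence (a Down state); recording bounds delimit the
  outer gaps, so tonic firing contains no Up state.
* **Group activations and replay**: a group is active when at least
  half its neurons (5 of 10) spike within 15 ms; the activation instant
  is the mean of the first five distinct-neuron spike times.  A full
  replay is a complete ordered transition chain of the sequence within
  an Up state; occurrences are counted greedily and disjointly.
* **Per-synapse replay**: per Up state, each presynaptic spike is
  paired with its nearest postsynaptic spike, the delays pass through
  the balanced STDP kernel, and a positive net sum marks the synapse as
  preferentially replayed; synapses replayed in strictly more than 2/3
  of Up states ("66%") are reliable.
* **Directionality**: per neuron, total incoming weight from the
  preceding (`l`) vs following (`r`) group (within-group edges
  excluded).  The weight directionality index embeds `(l, r)` in the
  unit square by dividing by the largest single-side total in the
  region at that snapshot and measures the distance from the centre,
  scaled by `√0.5` so one-sided input maps to 1 (the unscaled formula
  alone peaks at 0.707, contradicting the stated one-sided value of 1;
  the normalisation reconciles the two).  The delay directionality
  index is `(Δt_S1* − Δt_S1)/(Δt_S1* + Δt_S1)`, signed or absolute,
  from first-spike latencies after probing the two flanking groups.
* **Connection classes**: after thresholding at 0.065 µS (below the
  initial mean of 0.075), reciprocal pairs with both directions above
  threshold are functionally recurrent; pairs with exactly one, plus
  one-way anatomical edges above threshold, are unidirectional.

## The desk-scale network

The shipped presets divide every population by five
(100 PY / 20 IN / 20 TC / 20 RE) while keeping the sequence geometry of
the full model — letter groups of 10 PY neurons and the PY→PY radius of
20 — because halving both would disconnect adjacent groups and destroy
propagation.  Cross-population radii shrink with their target
populations but never below full topographic coverage; the IN→PY
radius is widened to 15 at this scale so that feed-forward inhibition
is spatially uniform across a letter sequence (at a radius of 5 the
inhibition driven by one group truncates exactly at the next group's
border, which silences the second letter and lets waves skip groups).
S1 occupies PY 26–75 (letters A–E), S1* the same neurons reversed, and
S2 a disjoint region.  Default phase durations are tens of seconds
(80 s of S1 training, 100 s of interfering S1* training at a slightly
lower amplitude — the region is already potentiated, so weaker pulses
still fire every group — 30 s of sleep, 15-trial test blocks at
1 trial/s); the full-scale durations of hundreds of seconds remain
reachable through `durations` and `experiment_config()`.  These
problem sizes keep a full interference-plus-sleep protocol around
three minutes of wall time.

What the reduced model reproduces: the awake asynchronous regime with
no network-wide silent period, the N3 slow oscillation (Up-state onset
rate well below 1 Hz with Up durations of one to three hundred ms),
directional STDP footprints of sequence training (forward inter-group
weights up, reverse down), interference from opposite-sequence
training, spontaneous Up-state replay, and the direction of the sleep
effects on weights and recall.  What it does not reproduce: the
quantitative recall-performance levels of the full-size model —
with 100 PY neurons the recall readout is noisy (background spikes
intrude into the 350 ms window and evoked waves occasionally stall or
skip), so performance percentages are lower and more variable than at
full scale, and conclusions should rest on directions of change and on
medians across seeds, which is exactly how the package's own
acceptance checks are written.  One interference phenomenon does not
survive the reduction: in the full-size model the interfering sequence
S1* shows an immediate recall gain right after its own training, before
sleep.  At desk scale, S1* training drives the already-potentiated
region into bilateral weight saturation (the trained forward chain
re-ignites during the reversed stimulation), which damages S1 — the
forgetting direction is reproduced — but leaves no immediately
readable S1* trace; the S1* gain only appears after sleep
de-saturates and orthogonalises the region.  The corresponding
acceptance check is therefore expected to flag this, and the behaviour
is documented here rather than tuned away.

## Numerical choices

Fixed-step integration at dt = 0.02 ms (configurable); exact
exponential updates of gating variables via voltage-indexed lookup
tables (0.05 mV grid, linear interpolation); forward Euler for the
membrane and Ca equations; the algebraic soma solved exactly per step.
Spikes are upward crossings of 0 mV with a 2 ms refractory guard.
Fixed-step integration of a spiking limit cycle accrues phase error, so
the convergence contract (halving dt moves spike times by < 1 ms) is
asserted on the first spikes of a train.  Minis are event-driven
through a binary heap of thinning candidates; determinism is guaranteed
by a private 64-bit generator seeded from the experiment seed, so
identical configurations reproduce rasters bit for bit.  Weight
snapshots and rasters serialise to plain delimited text.

## Known limitations

* One-dimensional topography; no distance-dependent delays.
* The thalamus is minimal: no spindle-frequency resonance is claimed,
  TC/RE serve to shape Up/Down dynamics and awake background drive.
* NMDA/GABA_B kinetic constants are conventional defaults, not fits.
* The cortical K-leak inversion discussed above.
* Recall performance at desk scale is directional evidence, not a
  quantitative reproduction; single seeds can show inverted recall
  differences, which is why the package's checks use ≥ 5 seeds.
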