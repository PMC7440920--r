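# tcreplay

Conductance-based simulation of how slow-wave sleep protects competing
memories from catastrophic forgetting in a thalamocortical network.

Training a spiking network on a new sequence that reuses the neurons of
an old one progressively erases the old memory. `tcreplay` implements,
in R with a compiled core, a four-population thalamocortical circuit
(cortical pyramidal PY and inhibitory IN cells, thalamic relay TC and
reticular RE cells; all Hodgkin–Huxley) whose PY→PY synapses learn by
spike-timing-dependent plasticity,

```
F(Δt) = A₊ e^(−|Δt|/τ₊)   if Δt > 0        g_AMPA ← g_AMPA + g_max·F(Δt)
      = −A₋ e^(−|Δt|/τ−)  if Δt < 0
```

with τ± = 20 ms, balanced A± = 0.002 (A₋ = 0.001 during training).
Switching the neuromodulatory scalars (ACh, histamine, GABA) moves the
network between an awake-like asynchronous state, where sequences are
trained and tested, and an N3 sleep-like state that generates a slow
(< 1 Hz) alternation of Up and Down states with no external input.
During Up states the trained sequences replay spontaneously; STDP then
reshapes the weight matrix — strengthening a lone memory, or
segregating two opposite memories trained over the same neurons into
complementary synaptic subsets (orthogonalisation).

Recall is scored by stimulating only a sequence's first letter group
and string-matching the order of smoothed population-rate peaks against
the ideal word:

```
SM = (2N − Σᵢ |L(S_test, S_sub)ᵢ − i|) / (2·|ideal|),  success ⇔ SM ≥ 0.8
```

The analysis suite also provides Up-state detection (15 ms spike
chaining, 300 ms Down-state rule), full-sequence and per-synapse replay
counting with a 2/3 reliability bar, net left/right synaptic-input
asymmetry with a weight directionality index, first-spike delay
directionality, and recurrent/unidirectional connection classification
at a 0.065 µS threshold.

The intended users are computational neuroscientists studying sleep
consolidation, replay, and continual learning in spiking networks.

## Worked example

A desk-scale run (100 PY / 20 IN / 20 TC / 20 RE) of 30 s of N3 sleep,
followed by Up-state detection over the sequence region:

```r
library(tcreplay)

cfg <- preset_config("n3-spontaneous", seed = 1, durations = list(sleep = 30))
res <- run_experiment(cfg)
ups <- detect_up_states(res$spikes[[1]],
                        neurons = unlist(cfg$sequences$S1$groups))
nrow(ups) / 30          # Up-state onset rate (Hz)
#> [1] 0.5333333
round(mean(ups$end - ups$start))   # mean Up-state duration (ms)
#> [1] 201
```

Sixteen Up states in 30 s — a 0.53 Hz slow oscillation with Up states
around two hundred milliseconds long, alternating with silent Down
states.
The full interference protocol (`preset_config("sequence-overlap")`)
trains S1 (A→B→C→D→E over PY 26–75), then its reversal S1* over the
same neurons, then sleeps; recall scoring, replay tables and weight
analyses operate on the returned per-phase rasters and weight
snapshots:

```r
res  <- run_experiment(preset_config("sequence-overlap", seed = 1))
s1   <- res$config$sequences$S1
tr   <- recall_trials(res$spikes[["test-S1-postsleep"]], s1,
                      res$schedules[["test-S1-postsleep"]]$onset)
performance(tr)         # percent of trials with SM >= 0.8
```

A thin command-line front end wraps the same functions
(`inst/cli/tcreplay.R`, subcommands `run`, `analyze`, `fixtures`,
`presets`), writing rasters, weight snapshots and analysis tables as
delimited text.

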