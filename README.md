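# kv1relay

Conductance-based modelling of intrinsic excitability in thalamic relay
neurons, centred on the dendrotoxin-sensitive D-type (Kv1) potassium
current.

Relay cells of the dorsal lateral geniculate nucleus (dLGN) carry a
low-threshold, slowly inactivating Kv1 current that sets how many
spikes a current step evokes, the rheobase, and the latency and jitter
of the first spike. Activity-dependent regulation of this single
conductance — down after potentiation of intrinsic excitability
(LTP-IE), up after monocular deprivation — retunes the relay without
any synaptic change. `kv1relay` packages that system for simulation and
analysis:

* a **two-compartment Hodgkin–Huxley model** (somato-dendritic +
  axonal) with Na, delayed-rectifier, A-type, Kv1/D-type, T-type Ca,
  HCN and leak currents; each compartment obeys
  `C dV/dt = I_inj − Σ ḡ mᵖhᵠ(V − E) − g_c(V − V_other)`
  with Boltzmann steady-state gating and bell-shaped voltage-dependent
  time constants, integrated by exponential Euler at 0.025 ms;
* **current- and voltage-clamp protocol execution**, including the
  subtraction protocol that isolates the DTx-sensitive current;
* **electrophysiological feature extraction** matching slice-rig
  definitions: spike detection, phase-plot threshold (dV/dt criterion),
  rheobase on a 10-pA grid, input resistance from a −20 pA/250 ms
  pulse, ISI2 − ISI1 adaptation, first-spike latency with optional
  burst skipping, latency jitter (SE), excitability change in % of
  control;
* **differential-evolution calibration** (rand/1/bin) of maximal
  conductances and half-activations against feature targets;
* **in-silico experiments**: control / deprived (gKv1 = 101.7/83 nS) /
  DTx (gKv1 = 0) / LTP-IE (gKv1 halved) / T-block conditions, f–I
  comparisons, and the 40-Hz induction-protocol generator
  (15 pulses at 40 Hz every 10 s for 10 min = 900 pulses);
* a **surrogate-recording generator** (model + seeded Gaussian noise)
  so feature extraction and parameter recovery are testable with no
  laboratory data.

A calibrated reference cell ships with the package
(`inst/extdata/reference_cell.yaml`): it rests at −76 mV with zero
injected current, sits at −69 mV under +13 pA, fires 3 action
potentials for a 47 pA / 800 ms step at the control Kv1 conductance
(41.7 nS soma / 23 nS axon) and 10 for the same step with Kv1 removed.

## Worked example

```r
library(kv1relay)

cell <- reference_cell()
round(resting_potential(cell), 1)
#> [1] -76

tr <- simulate_current_clamp(cell, step_protocol(47, 800, pre = 200,
                                                 post = 100))
extract_features(tr)[c("ap_count", "first_spike_latency", "threshold_v")]
#> $ap_count            3
#> $first_spike_latency 461.375
#> $threshold_v         -46.56925

rep <- compare_conditions(cell, "control", "dtx", currents = c(45, 47, 51))
rep$table[, 1:4]
#>   current_pA ap_a ap_b d_ap
#> 1         45    2    9    7
#> 2         47    3   10    7
#> 3         51    4   11    7
rep$rheobase
#> control     dtx
#>      40      20

dtx_sensitive_current(cell)   # steady DTx-sensitive K+ current, -80 -> -50 mV
#> [1] 91.38724
```

The control cell answers a 47-pA step with three late spikes — the
ramp-and-delay signature of the Kv1 current (first spike at ~461 ms as
its slow inactivation releases the subthreshold clamp). Removing Kv1
(`"dtx"`) more than triples the spike count at matched currents and
halves the rheobase; raising it to the deprived values does the
opposite. `dtx_sensitive_current()` reports the outward current the
in-silico subtraction protocol isolates (~91 pA for a −80 → −50 mV
command).

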