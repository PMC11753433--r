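---
title: "A two-compartment relay-neuron model with a D-type (Kv1) current: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment relay-neuron model with a D-type (Kv1) current: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Relay neurons of the dorsal lateral geniculate nucleus (dLGN) express a
dendrotoxin-sensitive, low-threshold, slowly inactivating potassium
current carried by Kv1 (D-type) channels. Because this current activates
just below spike threshold and inactivates over hundreds of
milliseconds, it controls the cell's intrinsic excitability: how many
spikes a fixed current step evokes, the rheobase, the latency of the
first tonic spike after the initial T-type calcium burst, its trial-to-
trial jitter, and the voltage threshold read off a phase plot.
Experience-dependent regulation of Kv1 — down-regulation after
intrinsic-excitability potentiation (LTP-IE), up-regulation after
monocular deprivation — can therefore retune the thalamic relay without
any synaptic change.

`kv1relay` implements a deliberately small biophysical model of this
system: two isopotential compartments (somato-dendritic and axonal,
the axonal one standing in for the axon initial segment) coupled by a
fixed conductance, each carrying Hodgkin–Huxley currents, with the Kv1
conductance as the experimental dial. Everything else in the package —
protocol execution, feature extraction, differential-evolution
calibration, condition experiments, surrogate recordings — exists to
exercise that model the way a patch-clamp rig would.

## Model equations

Each compartment obeys

$$C \frac{dV}{dt} = I_{\mathrm{inj}} - \sum_c \bar g_c m_c^{p_c} h_c^{q_c} (V - E_c) - g_{\mathrm{couple}} (V - V_{\mathrm{other}}),$$

with conductances in nS, voltages in mV, currents in pA and
capacitances in pF (areas are absorbed into the absolute quantities, so
no geometry is needed). Gates relax exponentially toward Boltzmann
steady states,

$$x_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/k}}, \qquad
\tau_x(V) = \tau_{\min} + \frac{\tau_{\mathrm{amp}}}{e^{(V - V_\tau)/k_1} + e^{-(V - V_\tau)/k_2}},$$

with a $Q_{10}^{(T_{\mathrm{ref}} - T)/10}$ temperature factor; the
default bath temperature is 30 °C, the recording-chamber temperature of
the experiments the model mirrors. A negative slope $k$ encodes a gate
that closes with depolarization; the HCN gate is written this way (as a
`q`-type gate), which keeps the package-wide invariant that every
`p`-type activation curve is monotonically increasing in voltage.

The current inventory and its localization:

| current | gates | soma | axon | role |
|---|---|---|---|---|
| Na | $m^3 h$ | yes | yes | spike generation |
| Kdr | $n^4$ | yes | yes | repolarization |
| A | $m^4 h$ | yes | no | transient K, somato-dendritic only |
| Kv1 | $m\,h$ | yes | yes | D-type; subthreshold clamp, slow inactivation |
| T | $m^2 h$ | yes | no | low-threshold Ca burst |
| H | $h$ | yes | no | resting potential, sag |
| leak | — | yes | yes | passive |

The T current uses a fixed +120 mV reversal rather than a
constant-field flux expression: the model carries no intracellular
calcium state, so a fixed reversal keeps it closed while preserving the
driving-force direction over the physiological range.

## Kinetic constants

The published description of the source model names the currents and
their compartments but leaves the gating equations to supplementary
material; this package therefore adopts standard thalamocortical
kinetics re-expressed in the Boltzmann/bell-τ parametric form above,
and treats the midpoints as calibration targets in exactly the way the
maximal conductances are. The choices that matter, and why they ended
up where they did:

* **Kv1 activation midpoint −44.9 mV, slope 4 mV.** The D-type current
  is conventionally described by the *foot* of its activation curve
  ("threshold ≈ −50 mV"), which for a Boltzmann sits roughly $2k$ below
  the midpoint; the calibrated values put the foot at ≈ −53 mV. The
  steep slope is essential: it lets Kv1 clamp the depolarized plateau
  just below spike takeoff while contributing almost nothing below
  −65 mV — the only way a cell can carry 41.7 nS of Kv1 and still show
  a ~540 MΩ input resistance between −76 and −69 mV. Inactivation
  (midpoint −65 mV, τ up to ~390 ms) slowly releases the clamp, which
  is what converts the step response into the ramp-and-delay phenotype
  with a late first spike.
* **Na activation −42.8 mV / inactivation −50 mV.** With classical
  values near −60 mV for inactivation, a slow Kv1-limited approach to
  threshold inactivates the sodium current completely and the cell can
  never fire from a ramp; −50 mV leaves enough availability near
  takeoff that delayed spikes exist — the phenotype the whole study
  rests on.
* **Slow delayed-rectifier deactivation (τ up to ~45 ms).** The
  potassium tail after each spike is what sets the slow tonic rate
  (~12 Hz near rheobase) that reproduces the published spike counts;
  with a fast classical Kdr the model fires at 25–30 Hz at the same
  drive.
* **T-type kinetics are classical** (activation −57 mV, inactivation
  −81 mV, slow de-inactivation). At the −76 mV working potential the
  T current is largely inactivated, so excitability steps produce
  delayed tonic firing rather than a stereotyped burst; a
  low-threshold spike appears when the cell is held below about
  −85 mV, and holding near −56 mV (the "transmission mode" of the
  deprivation assay) silences the current entirely.

Every constant is exposed in `channel_spec()` / `default_channels()`
and serialized with the cell, so the calibration stage owns the final
values; nothing is hard-wired into the integrator.

## Numerical scheme

Gates are advanced by exponential Euler
($x \leftarrow x_\infty + (x - x_\infty) e^{-\Delta t/\tau}$), voltages
by a forward update, at a fixed `dt = 0.025` ms. This is the standard
compromise for HH systems when bit-for-bit reproducibility matters:
adaptive steppers trade determinism across platforms for speed, and the
gate update is unconditionally stable so the stiff sodium kinetics do
not constrain `dt` beyond the membrane equation itself. Convergence is
asserted by step-halving: subthreshold trajectories agree pointwise to
< 0.5 mV between `dt` and `dt/2`, while spiking trajectories are
compared on spike count and spike times (pointwise voltage comparison
is meaningless across step sizes during an action-potential upstroke,
where a microsecond of timing shift is tens of mV).

Before every protocol the model is settled for 2 s (3 s for resting-
potential reads) at the holding bias, starting from Boltzmann steady
states at −70 mV; settled states are cached by a parameter hash.
`find_holding_current()` inverts the settled voltage–bias map by root
bracketing to 0.1 mV; a non-stationary (spontaneously spiking) settle
is treated as an overshoot so the search backs off, and it is an error
only if the whole bracket spikes.

## Measurement definitions

* **Spike detection**: upward crossings of 0 mV separated by ≥ 2 ms.
  The detection voltage is deliberately far above threshold; it counts
  full spikes only.
* **Threshold**: phase-plot definition — the voltage at the first
  sample before the peak where dV/dt exceeds 20 mV/ms (criterion
  config-exposed; the source experiments do not state theirs).
* **Rheobase**: smallest multiple of 10 pA (scanned upward, cap
  500 pA) evoking ≥ 1 spike in an 800-ms step from a stated holding
  potential (−65 or −56 mV in the deprivation assay). "No spike up to
  the cap" is an explicit `NA`, not an error.
* **Input resistance**: steady deflection over the last 50 ms of a
  −20 pA / 250 ms pulse divided by the injected current.
* **ISI adaptation**: ISI2 − ISI1 (negative = accelerating).
* **First-spike latency**: from stimulus onset; with burst skipping,
  spikes chained by ISIs < 20 ms at the step onset count as the initial
  T burst and the latency of the next spike is reported. The 20-ms cut
  separates burst ISIs (a few ms) from tonic ISIs (tens of ms); a lone
  first spike with no companion within the cut is counted as tonic.
  Latency is measured from stimulus onset (the source's convention is
  not printed; onset is the natural choice for step protocols).
* **Jitter**: standard error of the latency over repeated sweeps.
* **LTP-IE magnitude**: 100 × mean(after)/mean(before) spike counts,
  window means taken per sweep series.

## Calibration

`feature_cost()` is a weighted quadratic,
$\sum_i w_i ((f_i - t_i)/s_i)^2$, with the tolerance $s_i$ as the
per-feature scale; failed simulations or undefined features charge a
fixed penalty of $10^6$ per row so the optimizer routes around
pathological parameter sets instead of aborting. `fit_de()` is the
classic rand/1/bin differential evolution (mutant
$x_{r1} + F(x_{r2} - x_{r3})$, binomial crossover, greedy selection)
with $F = 0.8$, $CR = 0.9$, population 40 and 100 generations by
default — the optimizer named by the source; its hyperparameters are
not published, so canonical textbook values are used and exposed. The
incumbent best is never discarded, hence the non-increasing best-cost
history the tests assert.

The shipped reference cell (`reference_cell()`,
`inst/extdata/reference_cell.yaml`) was calibrated with this machinery
plus a final Newton solve of the passive pair (leak conductance and
leak reversal) against the two potential anchors: resting potential
−76 mV at 0 pA and −69 mV under +13 pA (hence ≈ 540 MΩ input
resistance), three spikes for a 47 pA / 800 ms step at gKv1 =
41.7/23 nS (soma/axon), ten spikes for the same step at gKv1 = 0, with
the deprived (101.7/83 nS) and halved-gKv1 conditions constrained
directionally (fewer/more spikes, ordered rheobase and first-spike
latency). The 47-pA examples are run from the −76 mV / 0 pA holding
regime; the published figure does not state which of its two regimes
(−76 mV / 0 pA or −69 mV / +13 pA) the 3→10 example uses, and the
resting regime is the one consistent with the 45–59 pA series being
taken at −76 mV.

## In-silico experiments

`apply_condition()` realizes the four manipulations as static
conductance changes: `deprived` (gKv1 → 101.7/83 nS), `dtx` (gKv1 → 0),
`ltpie` (gKv1 halved) and `tta_p2` (gT → 0). The LTP-IE condition is
static by design: the underlying PKA/L-type-calcium cascade is only
characterized qualitatively in the source, so no plasticity dynamics
are modelled — the condition is the *expression* end state.
`induction_protocol()` reproduces the induction arithmetic (15 pulses
at 40 Hz per train, trains every 10 s, 10 min → 900 pulses) as a
current-pulse protocol; synaptic conductances are out of scope.
`dtx_sensitive_current()` reproduces the voltage-clamp subtraction that
isolates the D-type current: the steady clamp current with Kv1 intact
minus the same with gKv1 = 0, for a subthreshold command step
(−80 → −50 mV by default).

## Surrogate recordings

`generate_surrogate()` adds iid Gaussian voltage noise (default SD
0.2 mV, a typical whole-cell noise floor; the source does not
characterize its noise) to deterministic model traces, one RNG stream
per sweep derived from a master seed by a counter scheme
(`seed + sweep − 1`). The underlying model reproduces the regular-
spiking repertoire of a relay cell — tonic spiking from depolarized
holding, delayed ramp-and-delay firing near rheobase, a low-threshold
spike from hyperpolarized (below about −85 mV) holding — but the
surrogates emulate *additive recording noise only*: no electrode
artifacts, bridge-balance error, series-resistance filtering, channel
noise or cell-to-cell variability. Tests passing on surrogates
therefore certify the measurement pipeline and parameter-recovery
machinery, not robustness to every failure mode of real recordings.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run everything at desk scale:
3-s settles for resting reads, 800-ms excitability steps, 10-pA
rheobase grids capped at 300–500 pA, a one-parameter recovery fit
(population 40, 10 generations) — sizes chosen so a full run completes
in minutes on one CPU while every quantity is still computed from
scratch. Degenerate inputs have defined behaviour throughout: fewer
than three spikes make ISI adaptation `NA`; no qualifying spike makes
latency `NA`; a zero control-window mean makes the excitability ratio
`NA`; zero-volume fit bounds return the single point; a non-finite
integration state aborts with the first bad time step named.

## Known limitations

* Two isopotential compartments cannot represent dendritic filtering of
  retinal EPSPs or AIS geometry; the axonal compartment is a lumped
  initial segment.
* No calcium dynamics, no calcium-activated or L-type currents: the
  induction cascade of the modelled plasticity is outside the model,
  which captures expression (the gKv1 change) only.
* The kinetic constants are literature-flavoured, calibrated to the
  published feature anchors — not fitted to raw experimental traces,
  which are not available.
* Condition effects are static conductance substitutions; nothing
  time-dependent happens during or after an induction protocol.
* The calibrated cell cannot be held stationary at −56 mV (the
  "transmission mode" potential of the deprivation assay): that value
  lies above the model's spontaneous-firing threshold at every Kv1
  level, so `find_holding_current()` reports it as unreachable.
  Rheobase comparisons are run from −65 mV or from rest, where the
  deprived-versus-control ordering holds as published.
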