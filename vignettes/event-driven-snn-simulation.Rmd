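---
title: "Bit-exact event-driven simulation of a quantized spiking network fabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-exact event-driven simulation of a quantized spiking network fabric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventsnn)
```

## What the package models

`eventsnn` is a behavioral simulator for a small, fully parallel, clock-less
digital spiking neural network fabric of the kind used for always-on
in-sensor inference. Every neuron is a physical integer circuit: a 7-bit
accumulator fed by quantized synaptic weights, with no global clock — spikes
propagate as asynchronous events, serialized by per-layer arbiters. The
simulator reproduces that arithmetic bit-exactly, so a trace computed here
is the trace the hardware would produce.

The package covers six concerns: synthesis-time topology and memory
accounting, the neuron update rule, deterministic event-driven simulation,
rate coding and inter-spike-interval (ISI) readout, conversion of small
ReLU networks to quantized weight tables, and a synthetic FMCW radar
micro-Doppler front end that exercises the whole pipeline without hardware
or recorded data. A closed-form timing calculator for the CMOS-thyristor
delay cell that paces the arbiter rounds out the hardware-facing side.

## Neuron semantics and the mean-rate ReLU identity

The accumulator holds integers 0..63. A spike through weight $w$
(multiplied by 8 when the layer's global scale flag is set) adds to the
accumulator; reaching 64 emits a spike and *wraps* — the accumulator keeps
the overflow residue $s - 64$ rather than resetting to zero — while a
negative sum clamps to zero. Two consequences matter:

* **Exact charge accounting.** While the clamp never fires, every neuron
  satisfies $64\,n_{\text{spikes}} + a_{\text{final}} - a_0 = \sum
  w_{\text{granted}}$, an identity the test suite asserts event-by-event.
* **Mean-rate ReLU.** Under constant input rates $r_i$ the output rate
  converges to $\max(0, \sum_i w_i r_i)/64$. The wrap is what makes this
  exact: a zero-reset neuron would discard residual charge and fire
  systematically slow. This identity is the bridge for ANN-to-SNN
  conversion.

There is no refractory period (the hardware defines none), and leakage is
not a special mechanism: it is an ordinary negative-weight synapse driven
by a clocked input, exposed as `apply_leak_tick()`. With no leak ticks the
neuron holds its state indefinitely.

The per-event sum never leaves $(-64, 128)$ for any representable
configuration (|w| ≤ 7, scale ≤ 8, accumulator ≤ 63), so a single
subtraction realizes the wrap; the simulator still warns if a
configuration could push a full accumulator to 128 or beyond, where the
single-subtraction assumption would break.

## Event ordering

Timestamps are integer nanoseconds: every frequency used in practice has an
exactly representable (rounded) period, and integer time makes traces
reproducible to the bit. Arbitration and propagation delays, physically on
the ns scale against input spike spacings of µs to ms, are modeled as
zero-duration but *strictly ordered*:

* Simultaneous spikes at a layer are serialized by the arbiter: linear
  polling grants in ascending source address; round-robin starts just
  after the last granted address and wraps. Each input line's edge
  detector remembers $H-1$ pending spikes; simultaneous repeats beyond
  that are counted as losses, never reordered.
* Within one timestamp the cascade is delivered breadth-per-layer: a
  layer's pending set is arbitrated and delivered in full, spikes
  generated during delivery are injected into the next layer's pending set
  (and back into the same layer's, for recurrent layers), and the sweep
  repeats until the network is quiescent before time advances. This is one
  consistent serialization of the pipelined hardware flow; how the silicon
  interleaves a recurrent spike arriving mid-arbitration is not specified,
  so the package exposes both polling disciplines to probe ordering
  sensitivity.

The compiled event engine is validated against an independently written
clock-driven reference simulator on 500 random small networks (random
topologies, weights, and periodic inputs): identical spike multisets and
final accumulators, under both polling disciplines. Shuffling the
presentation order of simultaneous input events leaves the trace unchanged
— the arbiter re-imposes order.

Recurrent cascades at one timestamp terminate whenever each neuron's
outgoing positive lateral weight sum is below the threshold 64 (each fire
then dissipates net charge); the engine also enforces a configurable cap
(default $10^6$ events per timestamp) and raises a runaway-recurrence
error beyond it.

## Rate coding and ISI readout

Pixels map linearly to frequencies, $f = f_{\min} + (f_{\max} -
f_{\min})\,p/p_{\max}$, by default [100, 655] kHz over grayscale 0..255;
binary images use 0 Hz / 655 kHz. Spike $k$ of a pixel falls at $t = k/f$
— no spike at $t = 0$, so $p = 0$ and $f = 0$ are continuous limits. Each
spike time is rounded to integer ns *independently* (rather than rounding
the period and tiling it), which keeps the spike count exactly
$\lfloor \text{duration} \cdot f \rfloor$; rounding the period first can
drop a trailing spike at high frequencies. A seeded per-pixel phase jitter
is available because real deployments do not phase-align their inputs;
zero phase is the deterministic default.

The readout takes the output neuron with the shortest ISI. Operationally
the decision fires at the earliest instant any output neuron completes its
second spike — under the hardware's reset-after-two-spikes protocol,
"shortest ISI" and "first to two spikes" coincide, and waiting for all
ISIs would be impossible since the network resets. Ties at the identical
nanosecond go to the smaller neuron index. A presentation with no neuron
reaching two spikes yields an explicit no-decision record. The default
presentation duration (5 ms) is a free configuration parameter, not a
claim: per-sample decision times vary.

## ANN-to-SNN conversion

The trainable model is deliberately minimal: a bias-free 256→64→$C$ ReLU
network (`train_toy_ann()`, full-batch Adam, softmax cross-entropy,
deterministic per seed). Quantization applies **per-network max-abs
normalization** — one shared scale for both layers — then
$w_q = \text{round}(w \cdot (2^{W-1}-1))$ with ties away from zero, so
$[-1, 1]$ maps to $[-7, +7]$ at $W = 4$. A shared scale (rather than
per-layer scales) preserves the relative magnitude of the two layers,
which keeps the mean-rate proportionality end-to-end; per-layer scaling
would distort the hidden layer's operating point relative to the output's.

`ann_snn_rate_agreement()` quantifies conversion fidelity: simulated
output spike rates against the mean-rate prediction on the same quantized
weights. The error is dominated by rate discretization and shrinks with
presentation length (few-percent at 10 ms for the default rates). On the
packaged synthetic fixtures, simulated accuracy is non-decreasing in the
weight bit width (2, 3, 4, 6 bits) — quantization noise at 2–3 bits is the
binding constraint, as expected.

The image fixture for this path (`make_blob_dataset()`) renders per-class
constellations of Gaussian blobs with seeded jitter — four separable
16×16 grayscale classes requiring no download. An IDX reader is included
for users who want to run external digit benchmarks; nothing in the
package or its tests requires one.

## The synthetic radar front end

The generator emulates a low-resolution 8 GHz ultra-wideband FMCW sensor:
192 chirps per frame, 512 ADC samples per chirp, 10-bit ADC, inter-chirp
interval 1.2 ms, chirp duration 41 µs (238 ms per frame), 500 MHz sweep
(30 cm range resolution), three frames per map. A gesture is a point
scatterer with a class-specific radial velocity trajectory:

| class | trajectory | rationale |
|---|---|---|
| hello | 0.6 sin(2π·4 t) m/s | fast, small excursion of a waving hand |
| toward | 2.0 sin(2π·0.8 t) m/s | slow, large approach/retreat |
| horizontal | 1.1 sin(2π·1.8 t) m/s | arm swing, moderate radial component |
| background | 0 | static scene |

All speeds sit well below the unambiguous limit (≈7.5 m/s at this chirp
interval); exceeding it triggers an aliasing warning, not an error. Every
scene also contains a *static clutter return* at the resting range — the
subject's torso and the room — which is both physically unavoidable and
statistically essential (below).

Processing is the standard construction: range FFT per chirp, selection of
the range bin with maximal energy, then a Hann-windowed STFT (64 chirps,
75% overlap) over that bin's complex slow-time series. The map is kept in
**linear magnitude** by default. This was a genuinely open choice, and the
threshold rule decides it: the binarization threshold $\mu + s\sigma$ with
$s = 0.15$ (population moments over all pixels, strictly-above
comparison) separates signal from noise only when strong pixels dominate
the map's moments. On a dB scale the noise distribution is roughly
symmetric, so $\mu + 0.15\sigma$ retains ~40% of pure noise pixels and
the background class binarizes to a nearly full image; on a linear scale
with a clutter ridge, the threshold sits far above the noise bulk and
background images reduce to the zero-Doppler band. A dB map remains
available (`db = TRUE`) for visualization.

Downscaling to 16×16 happens *after* binarization, by OR-pooling over a
16×16 block grid: any set pixel in a block sets the output pixel,
preserving sparse spike semantics.

What the generator does **not** emulate: multiple scatterers per limb and
their interference, angle/antenna effects, subject-to-subject variability,
range migration artifacts of real limbs, and amplitude modulation of real
echoes. Passing the end-to-end classification property on this fixture
therefore demonstrates the correctness and stability of the pipeline —
encoding, conversion, simulation, readout — not field-grade gesture
recognition performance. The packaged reference confusion matrix for the
hardware evaluation of the 4-gesture task ships separately as a plain-text
fixture (`gesture_reference_confusion()`), and its implied accuracy is
computed by the same confusion-matrix utility used for simulated runs.

One documented ambiguity: whether the inter-chirp interval is
start-to-start or the gap between chirps. The implementation follows the
printed frame total — frame = chirps × (T_i + T_d) = 238 ms — treating T_i
as the gap before each chirp's T_d.

## Delay-cell timing

The arbiter's self-timed phases are paced by a delay cell built from two
cross-coupled CMOS thyristors. The closed forms implemented are
$t_{d1} = C_n V_{tn}/I_c$ for the bias-current charging phase and
$t_{d2} = (6 C_n^2 C_p / (\beta_n I_c^2))^{1/3}$ for the NMOS-conduction
phase, with $t_d = t_{d1} + t_{d2}$ and a safe-band check (the fabricated
cell targets 100 ns with margin; `solve_bias_current()` inverts the
monotone $t_d(I_c)$ by root finding). An alternative printed form of
$t_{d2}$ in terms of $V_{tp}$ and a common load $C_L = C_p = C_n$ is
algebraically consistent with the capacitor form only under an implicit
substitution — their ratio is exactly $V_{tp}^{1/3}$ — so
`delay_consistency()` reports both values and the ratio instead of
silently preferring one.

## Numerical and design choices, consolidated

* Integer-ns timestamps everywhere; spike times rounded individually.
* The prototype's recurrent layer uses **exact-count connectivity**
  (19,878 synapses sampled uniformly without replacement from the combined
  forward + lateral candidate pool of 131,072): a density of "about 30%"
  cannot reproduce the printed register totals deterministically, and the
  printed count is compatible with either 30.3% of forward-only or 15.2%
  of combined candidates — the combined pool was chosen, and both density
  modes remain expressible per layer. Density mode keeps independent
  Bernoulli sampling and is validated by a binomial bound.
* Only the linear weight-value arrangement is implemented; a logarithmic
  arrangement is a documented extension point.
* Bias registers exist only on fully connected neurons, one per neuron.
* Underflow clamping applies to the post-sum of a delivery; with
  single-synapse events this is indistinguishable from per-term clamping.
* The scale flag is per layer, matching the hardware's global-scale input.
* Population (divide-by-n) moments and strict `>` in the binarizer.
* Interchange formats are plain text: network specs as versioned JSON,
  weight tables and AER streams as CSV, ANN layers as CSV with a JSON
  manifest.

## Problem sizes used by the test suite

The suite runs entirely from code-generated fixtures: 500 random networks
(≤ 8 neurons/layer, ≤ 3 layers) for the oracle-equivalence property; a
1-second single-neuron run (~11,000 output spikes) for the mean-rate
check; 240 blob images (40 test) for the bit-width monotonicity curve; and
the radar pipeline at its default 40 samples/class with a 30/10 per-class
train/test split. The full suite completes in well under a minute on one
core.

## Known limitations

* The engine models logical AER ordering only — no strobe electrics, no
  event-queue back-pressure, no multi-chip routing.
* Recurrent-layer behavior when a lateral spike arrives mid-arbitration is
  one chosen serialization (breadth-per-layer); hardware interleaving
  could differ at identical timestamps.
* The delay-cell module is closed-form only; no electrical (SPICE-level)
  simulation, no PVT corners beyond parameter sweeps.
* The radar generator is a single-point-scatterer model; see above for
  what that does and does not establish.
* No HDF5 container support; all interchange is CSV/JSON.
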