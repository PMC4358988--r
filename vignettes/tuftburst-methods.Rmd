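---
title: "Coincidence detection and composite-sigmoid analysis in a reduced L5 pyramidal neuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincidence detection and composite-sigmoid analysis in a reduced L5 pyramidal neuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Layer 5 (L5) pyramidal neurons have two spike initiation zones: the soma,
which fires fast Na⁺ action potentials, and the apical dendrite, which can
fire long-lasting Ca²⁺ spikes. Because synaptic input from higher cortical
areas arrives largely at the apical tuft while feed-forward input arrives
at the basal dendrites, the interaction between the two zones lets a single
cell signal the *coincidence* of the two streams by switching from isolated
spikes to a high-frequency burst. `tuftburst` implements a reduced
conductance-based model of this cell class, the electrophysiological
feature extraction used to characterize it (afterdepolarization size,
critical frequency, plateau width, spike statistics), phenomenological
input–output models that summarize the computation (composite,
multiplicative and additive sigmoids), and an orientation-tuning analysis
that compares candidate mechanisms by the circular variance of their
output.

## The reduced biophysical model

The model has three electrical compartments:

* **Soma** (includes the axon initial segment): leak, fast Na⁺ and
  delayed-rectifier K⁺ currents with Wang–Buzsáki-style rate functions, a
  spike-triggered slow AHP (adaptation) conductance, and an M-type slow K⁺
  current.
* **Basal dendrite** (passive): leak plus the basal NMDA/AMPA synapses,
  coupled to the soma by a fixed conductance `g_cb`.
* **Apical dendrite** (trunk + tuft lumped): leak, a low-threshold
  voltage-gated Ca²⁺ current (the Ca²⁺-spike generator), a slow K⁺ current
  that terminates the Ca²⁺ spike, a spatially uniform h-current, and the
  tuft NMDA/AMPA synapses, coupled to the soma by `g_c`.

Units are absolute throughout: mV, ms, pF, nS, pA.

Three design choices deserve explanation, because each was forced by a
failure mode of simpler variants:

**Why three compartments rather than two.** When the basal synapses are
placed directly on the spiking compartment, the voltage dependence of the
NMDA conductance closes a positive feedback loop through the somatic
membrane potential: once mean depolarization rises, the Mg²⁺ block
relieves, which raises depolarization further. The result is bistability —
the soma is either quiet or fires runaway trains at several hundred Hz —
and no parameter setting yields the single action potential that 175 basal
synapses should produce. On a real neuron the NMDA conductance sits on thin
basal branches where the local driving force collapses as the branch
depolarizes. A passive basal compartment restores exactly this saturation:
its local potential approaches the synaptic reversal and the current
transferred to the soma is bounded by `g_cb`.

**Why the soma carries adaptation and an M-current.** The basal barrage
builds a depolarizing envelope over tens of milliseconds. Two slow K⁺
mechanisms shape the somatic response to it: the M-current activates below
spike threshold with an 80 ms time constant and cancels most of the slow
envelope, and the spike-triggered AHP (fast rise during each action
potential, 150 ms decay) raises the threshold for further spikes once one
has fired. Together they make the soma respond to a sustained basal
barrage with one action potential, while leaving brief current pulses and
the large, fast currents of a dendritic Ca²⁺ spike able to drive spikes
through. Both currents are standard equipment of L5 pyramidal neurons,
which show pronounced spike-frequency adaptation.

**How the critical frequency arises.** The apical compartment is given a
large capacitance and a small leak, so that its membrane time constant
(≈10 ms with the coupling load) matches the inter-spike intervals near the
critical frequency. Backpropagating action potentials each deposit a
depolarizing transient in the dendrite; at pulse rates above ~80–90 Hz the
transients summate, and the summed depolarization — amplified by
subthreshold activation of the Ca²⁺ current — is still present at the
afterdepolarization readout time. Below the critical frequency the
transients decay in between. The resulting ADP-versus-frequency curve is
sigmoidal, and its inflection is the model's critical frequency. The full
regenerative Ca²⁺ spike is recruited when the dendrite is additionally
primed by tuft NMDA conductance, which is what converts coincident input
into a burst. We deliberately did not tune the model so that the 3-pulse
protocol itself ignites full Ca²⁺ spikes: in a lumped model that
discrimination sits on a knife edge in parameter space, whereas the
summation mechanism is robust to parameter perturbations and to halving
the integration step.

### Synapses

Each synapse has an NMDA and an AMPA component with maximal conductances
in a fixed 1:1 ratio. The NMDA conductance is voltage dependent,

$$g_{\mathrm{NMDA}}(v, t) = g_{\max}\,
  \frac{e^{-t/70} - e^{-t/3}}{1 + 0.3\, e^{-0.08 v}},$$

with `t` in ms since synapse onset and `v` in mV; the AMPA conductance
rises instantaneously and decays with a 0.5 ms time constant. Inside the
integrator, overlapping events sum linearly: the dual-exponential time
course is carried as two per-compartment kernel states that decay exactly
each step and are incremented at event onsets, which is algebraically
identical to giving every event its own clock. The per-synapse peak
conductance `g_syn` (2.2 nS) is the single global calibration constant —
all synapses have equal postsynaptic conductance.

### The frozen parameter set

The default parameters (`default_params()`, shipped as
`extdata/default_params.yaml`) are frozen: they are the set under which
the calibration suite passes, and every documented number refers to them.
The calibration targets were, in order of tuning priority: (i) the
standard barrage — 100 tuft plus 175 basal synapses at uniform random
times within 100 ms, drawn with the fixed calibration seed 42 — elicits 4
somatic action potentials and a dendritic Ca²⁺ spike; (ii) the basal-only
barrage elicits exactly 1 action potential and the tuft-only barrage none;
(iii) the 3-pulse critical-frequency protocol yields a sigmoidal ADP curve
with inflection inside the experimental band 70–110 Hz (the fitted value
on the frozen set is 93.5 Hz, with an ADP amplitude of ≈4.2 mV); (iv)
halving the Ca²⁺ conductance reduces the burst, and quartering it caps the
full input sweep below 100 Hz. The calibration seed was fixed before
tuning; the calibration procedure adjusts conductances, never the seed.

The default pulse amplitude for the critical-frequency protocol is 7000 pA
for 2 ms: strong enough that every pulse fires exactly one action
potential even through the AHP left by the preceding pulse. Runs in which
a pulse fails to elicit a spike are flagged (`ok = FALSE`), never dropped.

### Numerics

The integrator (written in C++ via Rcpp, since the input sweeps require
thousands of simulations) advances gating variables by exponential Euler
and the three membrane potentials by a linearly implicit update with
conductances frozen over the step. The default step is `dt = 0.025` ms.
Synaptic event onsets are aligned to the step grid (an error of at most
12.5 µs). The test suite verifies that the calibration barrage produces
the same spike count at `dt/2`, and that with zero input both compartments
stay within 0.5 mV of rest after a 200 ms settling period.

## Stimulation protocols and sweeps

`protocol_dc_step()`, `protocol_pulse_train()` and `protocol_barrage()`
describe the three experiment types; `simulate()` returns somatic,
apical-dendritic and basal voltage traces. `run_cf_protocol()` runs the
3-pulse protocol over 10–200 Hz in 10 Hz steps and keeps each trace at
least 250 ms past the last pulse so the ADP can be measured.

`run_sweep()` maps somatic output frequency over basal (0–300) and tuft
(0–200) synapse counts. By default it uses a **nested** seed policy: each
replicate draws one random synapse pool at the maximum counts, and a grid
point uses the first `n` events of the pool. Moving along the grid then
adds synapses to a fixed set, which is the natural reading of
"systematically varying the number of inputs" and keeps response
thresholds smooth along the grid; fully independent barrages per grid
point are available with `seed_policy = "independent"`. Defaults are a
step of 20 synapses and 2 replicates per point; these are choices (the
source experiments do not pin them down), recorded in the run
configuration that the pipeline writes next to its outputs.

Two definitions of output frequency are provided. The default, `"span"`,
is `(N−1)/(t_last − t_first)` — the mean instantaneous rate of the train,
which matches the intuition of a burst frequency and is used for the
calibration criteria and the Ca²⁺-block ceilings. `"count"` is spikes per
window. The span measure is intentionally *not* monotone in input count:
a straggler spike after a burst extends the span and lowers the value.
The monotonicity property of the model (more input, more output) is
therefore stated and tested on the count measure, averaged over 5 seeds,
allowing deviations within one grid step.

## Feature extraction

* `detect_spikes()`: local maxima above −20 mV separated by at least 2 ms
  (the larger of two close peaks wins).
* `isi_cv()`: SD/mean of inter-spike intervals, sample (n−1) denominator,
  requiring at least 3 spikes; all ISIs of the train are used.
* `dp_width()`: longest depolarization sustained at 20% or more above
  baseline during a dendritic injection, with baseline the most
  hyperpolarized potential in the window. "20% above" is read
  fractionally — threshold = baseline + 0.2·(peak − baseline) — because an
  absolute reading is ill-defined for negative potentials.
  Backpropagating-AP contributions are deliberately included.
* `adp_size_at()`: voltage at a fixed latency after the last spike minus
  the pre-protocol baseline. The latency is a convention (the readout
  line on frequency-aligned traces); the default is 10 ms and the
  calibration result stays inside the 70–110 Hz band at 5 and 15 ms.
* `fit_cf_curve()`: least-squares 4-parameter sigmoid of ADP versus pulse
  frequency. The critical frequency is the fitted inflection; the ADP
  size is the plateau difference. Fits are canonicalized to a positive
  slope scale.
* `classify_event_order()`: dendrite-first if the dendritic
  suprathreshold depolarization (fractional 20% rule) begins before the
  first somatic spike.
* `slope_test()`: ordinary least-squares slope with a two-tailed t-test
  against zero (n−2 degrees of freedom), via `stats::lm`.

Sigmoid fitting everywhere uses a profiled multi-start strategy: the
nonlinear pair (midpoint, slope scale) is scanned over a deterministic
grid plus seeded random draws, the linear pair (offset, amplitude) is
solved exactly for each candidate, and the best candidate is polished with
Levenberg–Marquardt (`minpack.lm`). The profiling step keeps the fit
robust for step-like data, where plain nonlinear least squares fails from
most starting points.

## Phenomenological models

Three models map tuft count $n_T$ and basal count $n_B$ to output
frequency. The additive and multiplicative models combine two independent
4-parameter sigmoids, $f(n_T) + g(n_B)$ and $f(n_T)\,g(n_B)$. The
composite model makes the basal sigmoid's maximum and threshold functions
of tuft input:

$$\mathrm{freq}(n_B, n_T) = \frac{M(n_T)}{1 + e^{-(n_B - T(n_T))}},$$

with $M$ and $T$ themselves 4-parameter sigmoids of $n_T$. The basal
exponent has unit slope exactly as defined; an optional slope parameter is
not part of the model. Amplitudes are left free, so fitting decides
whether each sigmoid rises or falls: on the control surface the fitted
$M(n_T)$ rises and $T(n_T)$ falls — more tuft input raises the attainable
burst frequency and lowers the basal threshold, which is the signature of
a coincidence detector.

`fit_surface()` minimizes the residual sum of squares over all grid
points, untransformed, with 50 restarts by default: one data-driven start
(per-row maxima for $M$, per-row half-maximum crossings for $T$, marginal
profiles for the factorized models) plus seeded random starts with
midpoints over the grid ranges and amplitudes within ±2 data ranges.
Variance explained is $100\,(1 - \mathrm{RSS}/\mathrm{TSS})$ about the
grand mean; a constant surface is flagged rather than fitted.
`extract_slice_MT()` provides the second route to the same curves: an
independent sigmoid per tuft-constant slice, reporting the upper plateau
(M) and midpoint (T), with degenerate slices flagged.

**Known limitation.** On the frozen model's control surface the
multiplicative model explains slightly more variance than the composite
model. The reduced model's basal transition is graded over tens of
synapses (single spike, then doublets, then the burst), and the composite
model's fixed unit basal slope pays for that width, while the
multiplicative model's free basal slope absorbs it. The detailed
multicompartmental models this package abstracts have considerably sharper
basal thresholds, which is what favors the composite form there. The
composite fit of the control surface is still well-formed (rising $M$,
falling $T$) and is the fixture used downstream by the tuning analysis;
the model-comparison machinery itself is validated on synthetic surfaces,
where each kind wins on its own data with VE ≥ 99.9%.

## Orientation tuning

Inputs as a function of stimulus orientation follow a von Mises shape
peak-normalized to 90 synapses at the preferred orientation (0 rad):
$n(\theta) = 90\,e^{\kappa(\cos\theta - 1)}$, with compression $\kappa$
from 0.1 to 1 (1/κ is the circular analog of variance). Four mechanisms
are compared: the composite sigmoid (with the frozen parameters fitted to
the control biophysical surface, making this analysis downstream of the
sweep and fit stages), pure multiplication of the two input counts, pure
addition, and a single sigmoid of one stream alone. Outputs are
normalized to a maximum of 1.

The single-sigmoid parameters are a frozen convention — midpoint 45,
slope scale 9 synapses — chosen so the logistic's dynamic range spans a
maximum input of 90. Circular variance uses the standard
response-weighted resultant length over the full period,
$1 - |\sum_j r_j e^{i\theta_j}| / \sum_j r_j$; the orientation-domain
(π-periodic, angle-doubled) variant is available behind a flag but is not
the default, since the input curves are defined on the full circle with a
single preferred orientation. The orientation grid defaults to 360 evenly
spaced points, at which the grid value agrees with the continuum closed
form $1 - I_1(\kappa)/I_0(\kappa)$ to better than $10^{-3}$.

Two exact identities anchor the analysis: the additive mechanism's output
tuning equals its input tuning (so its circular variance equals the input
reference), and multiplying two equal-κ inputs doubles κ. The composite
mechanism yields the lowest circular variance at every κ in the tested
range, and the property is verified to persist under ±25% perturbations
of the frozen mechanism parameters rather than assumed.

## Synthetic data

The generators in this package are first-class, tested code: they produce
inputs with the statistical structure each analysis stage assumes, so
that fitting and feature extraction can be validated against known ground
truth without running the simulator. `gen_surface()` evaluates a
ground-truth composite model on a grid and adds i.i.d. Gaussian noise
truncated at zero; `gen_trace()` composes baseline, Gaussian spike
templates, square plateaus, an exponential ADP and Gaussian noise;
`gen_cf_dataset()` samples a logistic ADP-versus-frequency curve with
noise. Noise is Gaussian throughout with defaults of 5 Hz (surfaces),
0.5 mV (traces) and 0.2 mV (ADP points) — large enough that recovery
tests are non-trivial, small enough that they are stable. Every generator
is deterministic given its seed and exposes its ground truth.

What the generators do *not* emulate: correlated noise across grid
points, electrode artifacts, recorded-cell noise spectra, or the
burst-quantized frequency values the simulator actually produces. Passing
recovery tests on synthetic data therefore validates the estimators, not
the biophysics; the calibration suite on the frozen model covers the
latter.

## Problem sizes

The test suite and acceptance script use: the full 10–200 Hz
critical-frequency protocol (20 simulations); input sweeps at step 20
with 2 replicates (176 grid points per Ca²⁺ condition); monotonicity
checks at step 75 × 100 with 5 replicates; 100 noisy datasets for
CF-recovery; 20 seeds for composite recovery under 5 Hz noise; 2000 null
replicates for the slope-test size. These sizes were chosen as the
package's own verification budget; all of them run on a single CPU in a
few minutes.

## Known limitations

* The model is a point-compartment reduction: no cable filtering, no
  distance-dependent synaptic placement, no NMDA-spike compartmentalization
  within branches. Phenomena that depend on where along the apical trunk a
  signal is measured are outside its scope.
* The basal-input response is strongly adapting by design (one spike per
  barrage at the calibration strength), so sustained-rate coding of pure
  basal input is compressed relative to the detailed models.
* The critical frequency of the frozen set (93.5 Hz) sits in the upper
  half of the experimental band rather than at the detailed-model value of
  84 Hz.
* With a −200 pA holding current the standard barrage remains subthreshold
  and the peak somatic depolarization differs by under 2% between full and
  halved Ca²⁺ conductance; this reproduces the observation that the
  subthreshold response hides the Ca²⁺ contribution that is so prominent
  suprathreshold.
* The multiplicative-versus-composite variance-explained ordering on the
  control surface is inverted relative to the detailed models, as
  discussed above.
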