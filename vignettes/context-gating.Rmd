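---
title: "Context-dependent gating in PPC: models, methods and design choices"
author: "ppcgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent gating in PPC: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ppcgate` implements two tightly coupled things: an analysis stack for
trial-structured calcium-imaging sessions recorded across behavioral
contexts, and a spiking excitatory–inhibitory network model of how
contextual input can gate which sensory signals a cortical population
amplifies. This vignette documents the methods, their assumptions, the
parameters that matter, and the design decisions that were genuinely
open — in the spirit of a methods section rather than a tutorial.

## The data model

A session is a `PPCExperiment`: a neurons × frames dF/F matrix at a
fixed frame rate (30 Hz by default) with per-neuron cell-type labels
(putative pyramidal, SOM+, PV+) and a trial table. Trials belong to
three contexts: *active* (the animal performs an auditory
decision task), *passive* (identical stimuli, no task), and
*spontaneous* (photostimulation of auditory-cortex axons at 10 s
intervals, no sound). Active and passive trials carry frame indices
for three sound-cue onsets, the choice turn, reward, and the
inter-trial interval; a third of them pair the first sound with a
100 ms photostimulation.

## Modulation indices and their significance

All three indices share the normalized-contrast form
$(R_b - R_a)/(R_b + R_a)$ over windowed mean responses:

* **SMI** contrasts the 1 s post-stimulus window against the 300 ms
  pre-stimulus window on sound-only trials, per context.
* **PMI** contrasts the post-stimulus window on sound+photostim trials
  against sound-only trials, per context.
* **EI** contrasts the 300 ms pre-stimulus window between active and
  passive contexts (positive = more pre-stimulus activity when
  engaged). All trials of each context contribute; the spontaneous
  context is excluded.

SMI and PMI are computed separately for left- and right-sound trials
and the side with the larger absolute value is kept, *sign preserved*.
The sign-preserving reading matters: suppressed neurons carry negative
indices that would be erased by a plain maximum.

Significance combines two criteria: the observed index must fall
outside the central 95% of a null distribution obtained by shuffling
the per-trial window means between the two conditions (1000 shuffles,
strict inequality at the percentile — ties are not counted as
exceedance), *and* exceed ±0.1 in magnitude. The magnitude threshold
makes the test deliberately conservative: on planted-null synthetic
sessions the realized false-positive rate is far below the nominal 5%
(the test suite checks ≤ 5% plus binomial tolerance). The shuffle unit
is the per-trial window mean — labels are permuted at the trial level,
never frame by frame, so temporal autocorrelation within trials cannot
leak into the null. Each neuron's shuffle RNG is seeded from the
master seed plus the neuron index, making results independent of
evaluation order.

Functional classes follow the flags: a neuron is *Sound* if
sound-significant in at least one of active/passive and not
photostim-significant (photostim significance is assessed in the
spontaneous context, where no sound confounds it), *Photostim* in the
converse case, *Sound&Photostim* if both, else *Unmodulated*.

## Population axes

A coding axis is the difference between two mean population vectors,
L2-normalized. The engagement axis uses active-minus-passive
pre-stimulus means; the sound axis post-minus-pre on sound-only
trials; the photostim axis stim+sound minus sound-only post windows.
Projections are only ever computed on trials held out from the axis
fit: trials are partitioned into four folds stratified by context and
sound side (stratification guarantees both classes of each contrast in
every training fold), each fold's axis is fit on the other three, and
the held-out projections are concatenated, so every trial is projected
exactly once. Degenerate contrasts (difference norm below 1e-12) are
an error rather than a silently unstable axis.

Per-trial scalars are the mean projection over the 300 ms pre-stimulus
window and the 1 s post-stimulus window, mirroring the index windows.
Engagement scalars are reported in raw projection units (dF/F·weight);
the behavioral-performance binning accepts arbitrary bin edges, and
the pipeline standardizes projections before using the default
−1…2 edge set, since raw units depend on population size. Bins with
fewer than five trials are dropped before the regression of fraction
correct on bin centers.

## Decoding

Population decoding uses a linear max-margin classifier (`e1071::svm`,
linear kernel, cost = box constraint = 1) on non-overlapping 90 ms
bins of the event-aligned tensor. Alignment truncates each
inter-event segment to its minimum length across trials, so bins are
anchored to the same events everywhere. Trials are split 70/30
stratified by label; z-scoring parameters come from the training
partition only (a leak-free choice the tests verify), a stratified
10-fold split within the training partition yields ten classifiers
per bin, and each is evaluated on the held-out 30%. Confound
balancing samples equal trial counts from every cell of the
stimulus × choice (or choice × outcome) table, requiring at least
four per cell — datasets that cannot meet the minimum are flagged
excluded rather than erroring, mirroring how multi-session analyses
drop sessions. A label-shuffled control quantifies chance; on
synthetic two-Gaussian populations at planted d′ the decoder attains
the closed-form Bayes rate Φ(d′/2) within Monte-Carlo error (a test
fixture, since real data offer no such reference).

Single-neuron information uses an instantaneous Bayesian decoder: at
each frame, per-class Gaussian emission densities (Poisson available
for event counts) are fit on training folds, held-out frames are
decoded by maximum posterior under a flat prior, and the per-frame
information is the mutual information of the decoded-vs-true
confusion table accumulated across folds. The choice of
confusion-matrix mutual information as the "bits" summary is a design
decision — it is the information actually transmitted by the decoder's
output — and is validated against a quadrature/closed-form reference
on Gaussian classes (agreement within 0.01 bits). The near-zero
variance case is floored at 1e-9 so that deterministic channels
decode by nearest class mean and yield the full 1 bit. Sound
information peaks are searched only within the stimulus-locked epoch
(S1 onset through S3 offset) to avoid contamination by later choice
and reward signals; choice and outcome use the full trial. A neuron
is informative if its peak exceeds 0.06 bits.

## The synthetic-session generator

The generator plants known structure so that every stage has ground
truth: functional classes in fractions 25% sound, 4% photostim, 2%
dual; 270/14/31 Pyr/SOM/PV neurons; 200 active trials (77.4% planted
accuracy), 150 passive, 90 spontaneous events; photostimulation on a
third of trials. Responses are exponential-decay transients (0.5 s
decay, matching GCaMP6f-like kinetics) added at event frames on a
constant baseline (0.2 dF/F) with i.i.d. Gaussian frame noise
(default sd 0.1). A per-trial engagement state (Gaussian around 1 in
active, 0 in passive trials, sd 0.35) drives three planted effects:
a class-signed baseline shift (positive for sound-responsive,
negative for photostim-responsive and — at half weight — unmodulated
neurons, zero for dual neurons, whose engagement modulation is
empirically ambiguous), a positive engagement→sound response-gain
coupling, and a negative engagement→photostim coupling. Behavioral
correctness follows a logistic function of the engagement state, so
performance-by-engagement has a planted positive slope. The planted
index values are computed analytically from the kernel's window mean,
and `amplitudeForIndex()` inverts that mapping when a test needs an
exact target index.

What the generator does *not* emulate: heavy-tailed and shared
(correlated) noise, slow drift, spike-to-fluorescence nonlinearity,
movement artifacts, and neuron-to-neuron amplitude heterogeneity
beyond class membership. Passing tests therefore demonstrate
correctness of the estimators under the planted model, not robustness
to every pathology of real recordings; the preprocessing module's
percentile baseline and the shuffle tests are the components designed
to absorb such pathologies in practice.

Timing uses a 3 s pre-stimulus period, 1.25 s between sound onsets, a
turn 4 s after S1 and reward 0.5 s later (both jittered by ±10 frames
with a guaranteed minimum gap, keeping event order valid by
construction), and a 3 s (correct) or 5 s (incorrect) inter-trial
interval.

## Preprocessing

Raw-fluorescence pipelines use: neuropil subtraction at scale 0.7;
dF/F against an 8th-percentile rolling baseline spanning 450 frames
before and after each frame (windows clipped at the recording edges —
the alternative of discarding 15 s at each end wastes data; linear
interpolation of the percentile for reproducibility across
implementations); and event extraction by first-difference AR(1)
inversion with the 0.05 a.u. threshold. The AR(1) inversion is a
transparent stand-in for constrained-deconvolution methods: exact on
noiseless AR(1) transients (the tests verify impulse recovery), it
makes no attempt at the noise-adaptive kernel estimation of a full
deconvolver, and the interface accepts any externally computed event
matrix instead. Frames with non-positive baseline become NaN with a
warning rather than silently producing infinite dF/F.

## The network model

8000 neurons in six subpopulations (2040 E1, 2040 E2, 2720 Enon, 360
I1, 360 I2, 480 Inon). Membrane potentials follow
$\tau_m \dot V = -(V - V_{rest}) + I_{ext} + I_{syn}$ with
$\tau_m$ = 20 ms (E) / 10 ms (I), $V_{rest}$ = −60 mV; synaptic
inputs decay with $\tau_{syn}$ = 2 ms and jump by $J_{ij}$ at
presynaptic spikes; rates follow the sigmoid
$r(V) = 30/(1+\exp(-(V - V_{rest} - 15)/3))$ Hz and spikes are
Bernoulli with per-step probability $r\,dt$ (dt = 0.1 ms, forward
Euler). Connectivity is a Bernoulli block model at the E/I level
(W(E←I) = −2.6042 mV at p = 0.1739, W(I←E) = 5.5147 at 0.029,
W(I←I) = −7.8125 at 0.1333, no E←E, no self-connections). Sound input
decays exponentially (500 ms constant, truncated at 500 ms — the
un-truncated tail changes nothing within the 300 ms analysis window
but the truncation matches the stimulus duration); amplitudes are 5
(preferred side) and 4.25 (non-preferred) to E1/I1 vs E2/I2, zero to
Enon/Inon. Photostimulation is a 100 ms boxcar with gamma(7,1)
strengths to half of Enon and half of Inon. Context input, present
only in the active context, adds gamma(5,1) strengths to 2000 neurons
drawn from all subpopulations.

**Input-units convention.** The baseline drive is nominally 5 mV/ms,
which is dimensionally a rate of voltage change, yet the membrane
equation adds it to a voltage. Both readings are implemented:
`inputConvention = "raw"` (drive enters as millivolts) and
`"times_tau"` (drive multiplied by the membrane time constant). The
package defaults to `"raw"`: under it the unconnected fixed point is
$V_{rest} + I$, baseline rates settle near 1 Hz, sound responses span
roughly 2–13 Hz across subpopulations and contexts — the sigmoid's
informative range — and the simulated context-gating deltas match the
model's reference behavior (sound deltas ≈ +0.23/+0.32 Hz,
photostimulation deltas small and negative in the segregated
network), whereas `times_tau` saturates large parts of the network and
produces deltas an order of magnitude off with inverted signs. Under
`raw`, a single presynaptic spike deflects the postsynaptic potential
by about $J\,\tau_{syn}/\tau_m$ (≈ −0.26 mV for an inhibitory synapse
onto E), a physiological PSP scale. The switch is retained for
sensitivity analyses.

Model SMI is the trial-averaged transfer-function rate in the 300 ms
after onset minus the 700 ms before, in the sound-only condition;
model PMI the post-onset difference between sound+photostim and
sound-only conditions. These are rate *differences* in Hz, not
normalized contrasts — the model indices and the imaging indices are
deliberately different statistics. Rates r(V(t)) rather than realized
spike counts enter the indices: in this model spikes exist to drive
synapses, and the rate is the lower-variance estimator of the same
quantity. Spike-level trial noise is controlled by a dedicated
xoshiro256++ stream per trial seeded from the condition seed;
condition seeds depend on the stimulus and side but not the context,
so zeroing the context strengths makes active and passive runs
bitwise identical (a symmetry the tests exploit). Structural
randomness (connectivity, target draws) uses R's RNG under the
structural seed, so variants can share a realization.

Three variants: *segregated* (default; context targets exclude
photostimulation targets), *overlapping* (context targets drawn from
everyone — neurons receiving both inputs flip the sign of the
photostimulation delta, making engagement amplify the irrelevant
input), and *opponent* (segregated targeting plus an opponent
inhibition motif: E1→I1/E2→I2 at p = 0.044, 11 mV and I1→E2/I2→E1 at
p = 0.26, −3.9 mV, which preserves the data-consistent signs with a
weaker excitatory sound delta).

## Problem sizes and numerical choices

The hot loop (8000 neurons × 15 000 Euler steps per trial) is
implemented in C++ with a lookup-table sigmoid (0.01 mV resolution,
linear interpolation) and costs roughly one second per trial on one
core.
The acceptance script simulates 48 trials per stimulus × context
condition and the test suite 20; at these sizes the Monte-Carlo
standard error of the population deltas is well inside the ±0.05
bands being checked, because the summaries average over thousands of
neurons and the continuous-rate indices are far less noisy than
spike counts. Left-sound conditions stand in for both sides in the
summaries: the E1/E2 and I1/I2 subpopulations are symmetric up to the
connectivity realization, so population-level |SMI|/|PMI| statistics
are side-symmetric; `runExperiment(sides = c("left", "right"))`
simulates both and averages per neuron when the per-side structure
matters. Test sessions use tens of neurons and tens of trials —
enough for the planted effects to dominate at the configured noise —
and the few long-running checks share memoized fixtures.

## Known limitations

* The event-extraction stand-in is exact only under the AR(1) forward
  model; it under-splits closely spaced events relative to a
  constrained deconvolver.
* The single-neuron information summary depends on the emission model
  (Gaussian by default); strongly non-Gaussian single-frame activity
  distributions bias it downward.
* The network model's parameters are fixed, not fit; the package
  makes no attempt to estimate connectivity or input strengths from
  data.
* Session containers are plain text for portability and are not
  intended for hour-long raw recordings.
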