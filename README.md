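# ppcgate

Context-dependent gating of sensory responses in posterior parietal
cortex (PPC) populations: analysis pipeline and circuit model.

During active behavior, cortical association areas do not relay all of
their inputs equally — task-relevant sensory responses are enhanced
while physically similar but task-irrelevant inputs are suppressed.
`ppcgate` is an R package for studying this phenomenon in
trial-structured two-photon calcium-imaging data (dF/F traces with
Pyr/SOM/PV cell-type labels across active, passive and spontaneous
contexts) and in a spiking excitatory–inhibitory network model that
reproduces the effect through segregated contextual input. It is aimed
at systems neuroscientists analyzing population recordings from
engagement-modulated sensory tasks, and at modelers probing
gain-modulation circuit mechanisms.

## What the package computes

**Modulation indices.** For each neuron, windowed mean responses R are
contrasted as

    SMI = (R_post − R_pre) / (R_post + R_pre)
    PMI = (R_sound+stim − R_sound) / (R_sound+stim + R_sound)
    EI  = (R_active,pre − R_passive,pre) / (R_active,pre + R_passive,pre)

with a 300 ms pre-stimulus and 1 s post-stimulus window, computed per
sound side (the larger-magnitude side is kept). Significance uses a
label-shuffle null (1000 shuffles, two 2.5% tails) combined with a
±0.1 magnitude threshold; neurons are classified Sound / Photostim /
Sound&Photostim / Unmodulated from the per-context flags.

**Population axes.** Coding directions are L2-normalized differences
of mean population vectors (engagement: active − passive pre-stimulus
means; sound: post − pre; photostim: stim+sound − sound-only), fit and
projected under 4-fold cross-validation so every trial is projected
from held-out axes only. Downstream: trial-by-trial coupling between
pre-stimulus engagement projections and stimulus-response projections,
and behavioral performance as a function of binned engagement.

**Decoding.** Linear max-margin population decoding (box constraint 1)
on 90 ms bins of event-aligned, truncated, z-scored tensors with
balanced subsampling that decorrelates stimulus from choice; and an
instantaneous single-neuron Bayesian decoder whose per-frame mutual
information (bits) feeds the 0.06-bit informativeness rule.

**Network model.** A stochastic 8000-neuron E–I network (subpopulations
E1/E2/Enon, I1/I2/Inon; sigmoidal rate transfer saturating at 30 Hz;
Bernoulli spiking; Euler integration at 0.1 ms) in which sound drives
the selective subpopulations, photostimulation drives half of the
non-selective ones, and a contextual input to 2000 neurons — segregated
from the photostimulation targets — raises pre-stimulus gain in the
active context. Model SMI/PMI are rate differences over 700 ms pre /
300 ms post windows. Three variants (`segregated`, `overlapping`,
`opponent`) expose how the targeting and connectivity motifs control
whether irrelevant-input responses are suppressed or enhanced by
engagement.

**Synthetic sessions.** `generateSession()` builds a full imaging
session with planted functional classes, engagement-linked baselines
and response-gain couplings, and analytically known index values, so
every stage is testable against ground truth.

## Worked example

```r
library(ppcgate)

cfg <- synthConfig(nNeurons = c(Pyr = 40L, SOM = 5L, PV = 8L),
                   nTrials = c(active = 40L, passive = 30L,
                               spontaneous = 12L),
                   noiseSd = 0.08, seed = 3L)
x <- generateSession(cfg)
mod <- computeModulation(x, nShuffles = 300, seed = 11)
table(truth = groundTruth(x)$class, called = mod$functional_class)
#>                   called
#> truth             Sound Photostim Sound&Photostim Unmodulated
#>   Sound              13         0               0           0
#>   Photostim           0         2               0           0
#>   Sound&Photostim     0         0               1           0
#>   Unmodulated         0         0               0          37
```

All 16 planted responsive neurons are recovered in their correct
class and no unmodulated neuron is falsely called, consistent with
the conservative magnitude-thresholded shuffle test. Projecting trials on the
engagement axis and correlating with the sound-axis response
reproduces the planted positive coupling:

```r
eng <- crossvalProject(x, "engagement", seed = 2)
snd <- crossvalProject(x, "sound", seed = 2)
engagementResponseCoupling(eng$trials$pre, snd$trials$post)$r
#> [1] 0.957  (planted coupling is positive)
```

Running the segregated network model and summarizing the
context-dependent change in modulation:

```r
sim <- runExperiment(networkParams("segregated"), nTrials = 48,
                     seed = 1)
modelDeltas(sim)
#>  dSMI_E  dSMI_I  dPMI_E  dPMI_I
#>  0.253   0.335  -0.040  -0.003
```

Engagement raises the mean |sound modulation| of both populations
(deltas ≈ +0.25 E, +0.34 I Hz) while *lowering* the photostimulation
modulation (negative deltas): the contextual input selectively
amplifies the relevant pathway and suppresses the irrelevant one.

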