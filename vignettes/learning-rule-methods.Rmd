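---
title: "A calcium- and dopamine-gated learning rule in a reduced striatal neuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calcium- and dopamine-gated learning rule in a reduced striatal neuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnlearn)
```

## The problem and the model

A direct-pathway striatal projection neuron (dSPN) rests near -85 mV and
fires only when strongly driven.  Its dendrites, however, can produce
NMDA-receptor-dependent plateau potentials: prolonged, regenerative
depolarizations evoked by spatiotemporally clustered glutamatergic input.
`spnlearn` asks whether a single neuron equipped with these nonlinearities
and a biologically grounded, purely local learning rule can solve the
nonlinear feature binding problem (NFBP): spike for the conjunctions
red+strawberry and yellow+banana, stay silent for red+banana and
yellow+strawberry, a task that is linearly non-separable at the level of
single features.

The electrical substrate is a deliberately reduced surrogate, not a
reconstructed morphology: a somatic cylinder plus unbranched tapering
dendrites, passive leak plus an inward-rectifier (KIR) conductance in every
compartment, explicit two-compartment spines (head behind a neck
resistance), and a threshold-type somatic spike mechanism.  The learning
rule consumes only local spine voltage, local calcium and the binary spike
decision, so the full ion-channel repertoire of a detailed dSPN model is
not required; what must be right are (i) the hyperpolarized resting state,
(ii) the location-dependent plateau efficacy, and (iii) the separation of
the calcium signals that the plasticity kernels read.

### Synapses and glutamate spillover

Each excitatory synapse carries saturating AMPA and NMDA conductances on
its spine head, both scaled by one dimensionless weight `w` (the fraction
of the maximal conductance; `w = 0.25` corresponds to 0.625 nS of NMDA
conductance, and NMDA gmax is 2.5 nS).  NMDA current passes through the
standard magnesium-block sigmoid.  Plateaus are produced by glutamate
spillover onto slow extrasynaptic NMDA receptors: when the summed weight of
co-active synapses in a pooling unit reaches 2 (inclusive — eight synapses
at weight 0.25 trigger exactly), a 2.5 nS extrasynaptic conductance with
slow kinetics (rise 10 ms, decay 300 ms) is activated once per stimulus on
the unit's dendritic shaft.  Pooling is per cluster site in the clustered
experiments and per dendritic branch in the distributed ones.  Because the
weights gate the trigger, potentiation lowers the number of synapses needed
for a plateau and depression raises it; this arithmetic — onset at 8
synapses for `w = 0.25`, 5 for `w = 0.4`, 10 for `w = 0.2` — is the
sharpest quantitative anchor of the synapse model and is verified by
simulation in the test suite.

### Calcium pools

Three separated pools are tracked, each with influx, a Michaelis-Menten
pump and first-order decay, and no spatial exchange:

* `[Ca]_NMDA` per spine, fed by the spine's synaptic NMDA current and — for
  synapses of a triggered pooling unit — by the extrasynaptic receptors
  adjacent to the spine.  This spillover contribution is what makes
  plateau trials calcium-distinct at the spine: without it, background
  drive and up-state depolarization leave triggered and non-triggered
  synapses nearly indistinguishable.
* `[Ca]_L-type` per spine, fed by the L-type share of a high-voltage-
  activated (HVA) channel surrogate.
* `[Ca]_v` per dendritic shaft, fed by both the low- and high-voltage-
  activated surrogates; this is the signal the inhibitory rule reads.

The absolute millimolar scale of each pool is unobservable in a surrogate,
so it is anchored to the constants of the learning rule by
`calibrate_calcium()`: a spillover-triggered baseline cluster must produce
peak `[Ca]_NMDA` near the initial LTP-kernel midpoint (0.02 mM), a
sub-threshold cluster must stay below half of it, and plateau trials must
exceed the 70 nM LTD threshold that a silent sub-threshold trial stays
under.  The NMDA and `[Ca]_v` probes run in the task context (with the
feature-unspecific population and background noise), because those anchors
govern calcium as the synapses actually see it during training; the
"silent trial below 70 nM" bound uses a quiet probe, since a silent trial
is only defined without background drive.  The calibrated influx scales are
the package defaults; re-running the calibration reproduces them.

## The excitatory plasticity rule

Plasticity is dispatched once per stimulus at reward-cue time, using each
synapse's peak calcium since stimulus onset, and only for synapses that
received a presynaptic spike during that stimulus:

* **Dopamine peak (+1)** — delivered when the neuron spikes for a relevant
  stimulus.  The weight increment is a bell-shaped kernel over
  `[Ca]_NMDA`: the derivative of a sigmoid with midpoint `theta_ltp`
  (initially 0.02 mM) and steepness 1000/mM, scaled by the LTP rate, the
  50 ms cue duration and a global rate factor.  Simultaneously the kernel
  midpoint slides *downward* along the calcium axis (metaplasticity),
  using a wider kernel (steepness 334/mM) centred at the same midpoint.
* **Dopamine pause (-1)** — delivered when the neuron spikes for an
  irrelevant stimulus.  The weight decrement is linear in peak
  `[Ca]_L-type` above a fixed 70 nM threshold (a near-step sigmoid,
  steepness 1e5/mM) and multiplicative in the current weight, so weights
  cannot cross zero.  The kernel midpoint slides *upward*, four times
  faster than the downward shift.
* **Basal dopamine (0)** — no excitatory plasticity at all.

The update schedule is a design choice the package makes explicit: the
rule's rate constants are per-millisecond, but the quantity the kernels
act on is the per-stimulus *peak* calcium, so the package applies one
event-based update per reward cue, multiplied by the 50 ms cue duration.
A single global `rate_factor` (default 1) is the only scale freedom; the
ratios between the four learning rates are fixed.

Why this combination learns the task: initially every stimulus triggers a
plateau (two co-located feature clusters sum to 2.5) and the neuron spikes
for everything, so peaks and pauses arrive equally often.  Synapses of
relevant conjunctions see kernel-level NMDA calcium on rewarded trials and
potentiate; synapses active only with irrelevant conjunctions see high
L-type calcium on pause trials and weaken; the asymmetric metaplasticity
drives the kernels of pause-correlated synapses up and away, locking them
out of later potentiation.  Feature-unspecific synapses — activated with
all four stimuli to let the hyperpolarized neuron spike at all early on —
are reward-uncorrelated, so they are weakened on average, which is itself
part of the solution: at the end of learning a plateau plus the residual
unspecific drive crosses the somatic threshold only for the stronger,
two-cluster (relevant) plateaus.

## The inhibitory plasticity rule

GABAergic synapses follow a BCM-style rule with no dopamine dependence.
The two-sigmoid function Omega of shaft `[Ca]_v` defines depression and
potentiation zones between two sliding thresholds: a synapse *active*
during the stimulus potentiates when calcium lies between the thresholds
and depresses above the upper one; an *inactive* synapse mirrors this.
Soft bounds `w (w_max - w)` freeze weights at 0 and at 5 nS.  The upper
threshold slides toward the highest observed calcium and the lower one
toward a level beneath it (the offset `c` makes the two threshold-update
curves cross zero together).  The intended effect is contrast enhancement:
inhibition grows for features that do not drive the local branch strongly
and shrinks for the features of the branch's learned conjunction.

The initial thresholds (0.1 and 0.5 uM) sit above the resting `[Ca]_v`
baseline and below evoked peaks; the rule's constants do not determine
either the initial values or the behavior at threshold crossing, so the
package clips the lower threshold to stay below the upper one by at least
1e-5 mM.

## Numerical choices

* **Integrator.**  One backward-Euler step of the cable system per `dt`,
  solved along the tree in O(N) with conductances frozen at the previous
  voltage.  Explicit spine heads (0.01 pF behind 500 Mohm) have
  microsecond time constants, so an explicit or exponential-Euler scheme
  diverges at any usable step; the implicit tree solve is unconditionally
  stable for the whole allowed range (`dt` 0.01-0.5 ms).  Training runs
  use 0.5 ms; characterization and calibration 0.1-0.25 ms.
* **Spike mechanism.**  Somatic threshold -40 mV with reset to -65 mV,
  10 ms refractory period, a back-propagating depolarization of 25 mV
  (decaying with length constant 120 um) injected into the dendrites on
  each spike, and a lumped after-spike K conductance at the soma (10 nS
  per spike, decaying with 80 ms).  The adaptation conductance stands in
  for the strong somatic K currents of these neurons; without it the
  surrogate fires continuously through the stimulus window and the
  resulting global depolarization floods every spine with calcium,
  erasing the plateau selectivity the rule depends on.
* **Geometry and passive parameters.**  The clustered setup uses 12
  dendrites of 200 um (10 segments), diameter tapering 1.0 to 0.25 um,
  axial resistivity 80 ohm cm, leak 0.08 mS/cm2 at -80 mV and KIR
  0.25 mS/cm2 (resting potential -86 mV).  These are calibration
  outcomes, chosen so that (i) the 108 feature-unspecific synapses are
  diluted over enough membrane that they depolarize without igniting
  tree-wide NMDA regeneration, (ii) distal input impedance is high enough
  for plateau ignition, and (iii) a plateau's somatic footprint is large
  enough to move the spike decision.  Background noise (Poisson, 8 Hz
  excitatory / 8 Hz inhibitory per dendritic compartment at 0.1/0.2 nS)
  keeps the membrane fluctuating without firing in the absence of input.
* **Per-stimulus reset.**  The protocol's 800 ms inter-stimulus interval
  exists to let all state decay to baseline; the training loop therefore
  simulates the 350 ms stimulus-plus-feedback window and resets to
  baseline between stimuli.  A dedicated test simulates the full interval
  and verifies the within-1% return that justifies the shortcut.

## What the generator emulates — and what it does not

The synthetic experiments reproduce the *structure* of the study: the four
feature-conjunction stimuli in shuffled blocks of 12 (each stimulus three
times per block), one randomly timed spike per stimulus synapse in 20 ms,
unspecific input over 50 ms, inhibitory input over 100 ms, the 50 ms reward
cue 300 ms after onset, spike-gated dopamine, and the clustered (5
synapses per feature per dendrite + 108/144 unspecific) and distributed
(200 synapses over 30 dendrites, branch-wide spillover) arrangements with
their stated initial-weight distributions.

They do not emulate a real neuron's channel repertoire, morphological
diversity, or calcium buffering; the surrogate's plateaus live in the
"soft boosting" regime rather than being fully all-or-none, and all
calcium scales are anchored to the rule's constants rather than to imaging
data.  Passing tests therefore demonstrate that the *learning rule* with
its standard constants solves the task given plateau-capable dendrites —
not that the surrogate is an electrophysiological replica.

## Problem sizes and expectations at desk scale

Training runs here use 480-960 stimuli (the study's protocol lengths are
960-1400) with the global rate factor left at 1.  At these sizes:

```{r sizes, eval = FALSE}
# the example three-feature configuration, excitatory-only:
model <- build_clustered_setup(fig3_configuration(), seed = 11)
tr <- run_training(model, training_protocol(n_stimuli = 480, dt = 0.5),
                   plasticity = list(exc = TRUE, inh = FALSE), seed = 11)
tr$final_performance
```

typical final-window performance for the two-or-three-feature clustered
configurations is 90-100% with a minority of runs stalling near 60-80%
(one conjunction learned, or partial separation); the mean over the 18
such configurations is about 89% at 480 stimuli, and a 960-stimulus run
trades a slightly lower mean for one more solved configuration as
continued depression erodes the feature-unspecific drive.  The no-metaplasticity control fails (the
kernels cannot retreat from pause-correlated synapses, so relevant and
irrelevant conjunctions never separate), frozen plasticity stays flat, and
the linearly separable single-conjunction task with randomly distributed
synapses exceeds 90%.  The subthreshold variant of the linear task — where
feedback arrives without spiking — needs the metaplasticity kernel to
travel into the sub-threshold calcium range before any weight moves, which
takes more reward events than a desk-scale run delivers; it reaches ~75%
at 480 stimuli and is included as a mechanism, not as a desk-scale claim.

In the distributed arrangement the excitatory-only rule reaches a moderate
mean (~65%), and adding plastic inhibition moves the distribution toward
the 75% mode with a tail of near-100% runs — inhibition helps most where
excitation alone cannot compartmentalize the branches.

## Known limitations

* The somatic gate between "one strong feature cluster" and "two strong
  feature clusters" is only a few millivolts wide; performance is
  therefore sensitive to the background-noise calibration, and individual
  seeds can stall at the one-conjunction solution (75%) as in the source
  study's harder configurations.
* The L-type pool's near-step LTD threshold (70 nM with steepness 1e5/mM)
  is soft in absolute terms (the product of threshold and steepness is 7),
  so small sub-threshold decrements exist; tests assert the two-orders-of-
  magnitude contrast rather than an absolute zero.
* Inhibitory threshold dynamics take steps of ~0.05 mM per stimulus (the
  threshold rates times the 50 ms window), so thresholds track the evoked
  calcium scale only because `[Ca]_v` is calibrated to the 0.1-0.3 mM
  range; at other scales the thresholds would oscillate too coarsely.
* The 9- and 25-combination task variants are provided as generators
  only; no accuracy claims are made or tested for them.
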