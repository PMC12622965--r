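# spnlearn

Reward-gated dendritic plasticity in a reduced striatal projection neuron
model.

## What this package is for

Striatal projection neurons (SPNs) rest very hyperpolarized and decide
whether to spike largely through NMDA-dependent dendritic plateau
potentials — prolonged regenerative depolarizations evoked by clustered
glutamatergic input.  `spnlearn` simulates, at desk scale, whether a single
model neuron with such dendrites and a purely local, biologically grounded
learning rule can solve the **nonlinear feature binding problem (NFBP)**:
respond by spiking to two "relevant" feature conjunctions (red+strawberry,
yellow+banana) while staying silent for the two complementary
"irrelevant" ones — a task that is linearly non-separable at the level of
single features.

The package is aimed at computational neuroscientists who want a compact,
fully scriptable R implementation of:

* a cable-equation surrogate of a dSPN (soma + tapering dendrites, leak +
  inward-rectifier membrane, explicit two-compartment spines, threshold
  spike mechanism with back-propagating depolarization), integrated by an
  implicit Hines-style solver in C++;
* saturating AMPA/NMDA synapses with **glutamate spillover**: when the
  summed weight `w` of co-active synapses in a cluster (or branch) reaches
  the threshold value 2, a slow 2.5 nS extrasynaptic NMDA conductance is
  activated and a plateau forms;
* three separated calcium pools per synapse site ([Ca]_NMDA, [Ca]_L-type,
  [Ca]_v), each with pump extrusion and first-order decay;
* the three-factor **excitatory plasticity rule**: on a dopamine peak the
  weight change is a bell-shaped kernel over peak NMDA calcium,
  `Δw = η_ltp σ'([Ca]_NMDA, θ_ltp, β_ltp)`; on a dopamine pause it is a
  thresholded linear function of L-type calcium,
  `Δw = η_ltd [Ca]_L σ([Ca]_L, θ_ltd, β_ltd) w`; under basal dopamine
  nothing changes.  **Metaplasticity** slides the kernel midpoint θ_ltp
  down after peaks and up (4× faster) after pauses:
  `Δθ_ltp = η_s σ'([Ca]_NMDA, θ_ltp, β_mp)`;
* the BCM-style **inhibitory rule** with the two-sigmoid Ω function and
  sliding thresholds θ_inh,low / θ_inh,high, driven by shaft [Ca]_v and
  independent of dopamine;
* the full training protocol (block-shuffled stimuli, 20 ms stimulus,
  reward cue at +300 ms for 50 ms, spike-gated dopamine feedback,
  continuous learning) and the clustered / distributed experiment suites.

## A worked example

Train the three-feature example configuration (dendrite 1: yellow, banana,
red; dendrite 2: red, strawberry, yellow; five clustered synapses per
feature plus 108 feature-unspecific synapses) with excitatory-only
plasticity:

```r
library(spnlearn)
model <- build_clustered_setup(fig3_configuration(), distance = 140,
                               seed = 11)
proto <- training_protocol(n_stimuli = 480, dt = 0.5)
tr <- run_training(model, proto, plasticity = list(exc = TRUE, inh = FALSE),
                   seed = 11)
tr
#> spn_training: 480 stimuli; final-window performance 93.8% (solved)
per_type_performance(tr)
#>                  id percent
#> 1        red+banana     100
#> 2    red+strawberry     100
#> 3     yellow+banana      80
#> 4 yellow+strawberry      95
```

Performance is the percentage of correct responses (spike for relevant,
silence for irrelevant) over the trailing 160 stimuli; the task counts as
solved above 87.5%.  Here the neuron has learned both conjunctions: it
spikes reliably for red+strawberry and most of the time for yellow+banana
while staying almost silent for the two irrelevant pairings — during learning the
synapses for each dendrite's irrelevant feature were weakened below the
spillover threshold while the relevant conjunction's clusters kept their
plateaus.

Useful entry points:

```r
enumerate_clustered_configurations()   # the 31 feature-to-dendrite layouts
spillover_onset_size(w = 0.25)         # plateau onset: 8 synapses at w=0.25
experiment_cluster_size_sweep()        # somatic/spine/calcium vs cluster size
experiment_configuration_sweep()       # train all 31 configurations
experiment_distance_sweep()            # performance vs cluster distance
experiment_distributed()               # 200 synapses over 30 dendrites
experiment_linear_task()               # linearly separable control
calibrate_calcium()                    # re-derive the calcium influx scales
write_results(tr, "out/")              # CSV + JSON reproducibility manifest
```

The methods vignette (`vignettes/learning-rule-methods.Rmd`) documents the
model equations, parameter tables, calibration logic and numerical
choices.

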