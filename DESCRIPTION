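Package: spnlearn
Title: Reward-Gated Dendritic Plasticity in a Reduced Striatal Projection
    Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates calcium- and dopamine-gated synaptic learning in a
    reduced compartmental surrogate of a direct-pathway striatal projection
    neuron. The model produces NMDA/glutamate-spillover dendritic plateau
    potentials, tracks separated NMDA, L-type and voltage-gated calcium
    pools per synapse site, and implements a three-factor excitatory
    plasticity rule (bell-shaped LTP kernel, thresholded linear LTD,
    sliding-kernel metaplasticity) together with a BCM-style
    calcium-threshold inhibitory rule. Includes the nonlinear feature
    binding task: stimulus sequencing, dopamine feedback, performance
    scoring, and the clustered and distributed training experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
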