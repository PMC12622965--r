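# Shared fixtures, built once per test run.  Kept deliberately small: a
# two-dendrite tree for membrane-level checks and a single-cluster model
# for synapse/calcium checks.

tiny_morph <- function(membrane = membrane_params()) {
  build_surrogate_morphology(2, 200, 10, membrane = membrane)
}

# single cluster of n synapses at `distance` on dendrite 1, noise off
cluster_model <- function(n = 8, w = 0.25, distance = 140,
                          morphology = tiny_morph(),
                          syn = synapse_params(), ca = calcium_params()) {
  seg_len <- morphology$dendrite_length / morphology$segments_per_dendrite
  d <- seq(distance - 8, distance + 8, length.out = n)
  seg <- pmin(pmax(ceiling(d / seg_len), 1), morphology$segments_per_dendrite)
  exc <- data.frame(comp = 1L + seg, dist = d, feature = "yellow",
                    cluster = 1L, w = w)
  build_model(morphology, exc, spill_mode = "cluster", syn = syn, ca = ca,
              noise = FALSE)
}

# events co-activating the first k synapses of a cluster model at time t
coactivate <- function(model, k, t = 10) {
  rows <- c(model$pack$map$ampa[seq_len(k)], model$pack$map$nmda[seq_len(k)])
  cbind(rep(t, 2 * k), rows)
}
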