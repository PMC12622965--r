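#' Enumerate the clustered input configurations
#'
#' Assignments of the four features to the two dendrites used in the
#' clustered experiments.  A dendrite carries a feature subset of size
#' 2-4 that must contain at least one full relevant conjunction, and the
#' two relevant conjunctions must both be represented (each fully on some
#' dendrite).  The two dendrites are physically distinct, so assignments
#' are ordered.  This yields 31 configurations: 18 in which no dendrite
#' carries more than three features and 13 in which at least one dendrite
#' carries all four.
#'
#' @return list of configurations, each a list with `d1`, `d2` (feature
#'   character vectors), `id` and `group` (`"le3"` or `"four"`).
#' @export
enumerate_clustered_configurations <- function() {
  feats <- c("red", "yellow", "strawberry", "banana")
  rel <- list(c("red", "strawberry"), c("yellow", "banana"))
  subsets <- list()
  for (k in 2:4) {
    cmb <- utils::combn(feats, k, simplify = FALSE)
    subsets <- c(subsets, Filter(function(s)
      any(vapply(rel, function(r) all(r %in% s), logical(1))), cmb))
  }
  out <- list()
  for (a in subsets) for (b in subsets) {
    covered <- vapply(rel, function(r)
      all(r %in% a) || all(r %in% b), logical(1))
    if (!all(covered)) next
    grp <- if (length(a) == 4 || length(b) == 4) "four" else "le3"
    out[[length(out) + 1]] <- list(
      d1 = a, d2 = b,
      id = paste(paste(substr(sort(a), 1, 2), collapse = ""),
                 paste(substr(sort(b), 1, 2), collapse = ""), sep = "|"),
      group = grp)
  }
  out
}

#' The three-feature example configuration
#'
#' Dendrite 1 carries yellow, banana and red; dendrite 2 carries red,
#' strawberry and yellow — one relevant and one irrelevant conjunction per
#' dendrite, with the relevant conjunction unique to each dendrite.
#'
#' @return a configuration list as in
#'   [enumerate_clustered_configurations()].
#' @export
fig3_configuration <- function() {
  list(d1 = c("yellow", "banana", "red"),
       d2 = c("red", "strawberry", "yellow"),
       id = "bareye|restye", group = "le3")
}

#' Build the clustered two-dendrite setup
#'
#' Places five excitatory synapses per assigned feature per dendrite,
#' clustered within +/- 10 um of `distance`, plus 108 feature-unspecific
#' synapses distributed over the tree (144 when inhibitory plasticity is
#' included).  Initial weights are drawn uniformly from 0.25 +/- 0.05 (or
#' from a normal with matching conductance mean/sd when
#' `weight_dist = "normal"`).  With inhibition, one inhibitory synapse per
#' feature (all four) is placed at each dendrite's cluster site with
#' initial conductance 0.1 +/- 0.01 nS.  Spillover pools per cluster site
#' (one pooling unit per dendrite).
#'
#' @param config a configuration from
#'   [enumerate_clustered_configurations()] or [fig3_configuration()].
#' @param distance cluster somatic distance (um).
#' @param with_inhibition include plastic inhibitory synapses.
#' @param weight_dist `"uniform"` (default) or `"normal"` initial-weight
#'   distribution.
#' @param n_unspecific count of feature-unspecific synapses; defaults to
#'   108, or 144 with inhibition.
#' @param morphology optional `spn_morphology` (defaults to the standard
#'   two-dendrite surrogate).
#' @param syn,ca parameter sets.
#' @param seed optional; if given, seeds the R RNG before placement.
#' @return an `spn_model`.
#' @export
build_clustered_setup <- function(config = fig3_configuration(),
                                  distance = 140,
                                  with_inhibition = FALSE,
                                  weight_dist = c("uniform", "normal"),
                                  n_unspecific = NULL,
                                  morphology = NULL,
                                  syn = synapse_params(),
                                  ca = calcium_params(),
                                  seed = NULL) {
  weight_dist <- match.arg(weight_dist)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(morphology)) morphology <- build_surrogate_morphology(12, 200, 10)
  if (is.null(n_unspecific)) n_unspecific <- if (with_inhibition) 144 else 108
  L <- morphology$dendrite_length
  if (distance < 20 || distance > L - 10) {
    stop("invalid cluster distance: ", distance, " um")
  }
  sets <- list(config$d1, config$d2)
  if (!all(unlist(sets) %in% c("red", "yellow", "strawberry", "banana"))) {
    stop("invalid configuration feature labels")
  }

  nseg <- morphology$segments_per_dendrite
  place <- function(dend, d_um) {
    seg <- pmin(pmax(ceiling(d_um / (L / nseg)), 1), nseg)
    1L + (dend - 1L) * nseg + seg  # compartment id, vectorized over dend
  }
  draw_w <- function(n) {
    if (weight_dist == "uniform") stats::runif(n, 0.2, 0.3)
    else pmax(stats::rnorm(n, 0.25, 0.05), 0)
  }

  exc <- do.call(rbind, lapply(1:2, function(dd) {
    fs <- sets[[dd]]
    d_um <- stats::runif(5 * length(fs), distance - 10, distance + 10)
    data.frame(comp = place(dd, d_um), dist = d_um,
               feature = rep(fs, each = 5), cluster = dd,
               w = draw_w(5 * length(fs)))
  }))
  d_un <- stats::runif(n_unspecific, 10, L)
  exc <- rbind(exc, data.frame(
    comp = place(sample(morphology$n_dendrites, n_unspecific, replace = TRUE),
                 d_un),
    dist = d_un, feature = "unspecific", cluster = NA_integer_,
    w = draw_w(n_unspecific)))

  inh <- NULL
  if (with_inhibition) {
    feats <- c("red", "yellow", "strawberry", "banana")
    inh <- do.call(rbind, lapply(1:2, function(dd) {
      data.frame(comp = place(dd, rep(distance, 4)), dist = distance,
                 feature = feats,
                 w = stats::runif(4, 0.09e-3, 0.11e-3))
    }))
  }
  build_model(morphology, exc, inh, spill_mode = "cluster", syn = syn,
              ca = ca)
}

#' Build the distributed-synapse setup
#'
#' 200 excitatory synapses (40 per feature plus 40 feature-unspecific)
#' placed uniformly at random over 30 dendrites, with branch-wide
#' spillover pooling.  Initial weights 0.3 +/- 0.1 without inhibition or
#' 0.45 +/- 0.1 with it; with inhibition, 60 inhibitory synapses (15 per
#' feature) are dispersed randomly.
#'
#' @param with_inhibition include plastic inhibitory synapses.
#' @param n_per_feature excitatory synapses per feature.
#' @param n_unspecific feature-unspecific excitatory synapses.
#' @param n_inh_per_feature inhibitory synapses per feature.
#' @param morphology optional morphology (defaults to 30 dendrites).
#' @param syn,ca parameter sets.
#' @param seed optional RNG seed.
#' @param features feature labels (extended tasks may pass more).
#' @return an `spn_model` in branch-spillover mode.
#' @export
build_distributed_setup <- function(with_inhibition = FALSE,
                                    n_per_feature = 40,
                                    n_unspecific = 40,
                                    n_inh_per_feature = 15,
                                    morphology = NULL,
                                    syn = synapse_params(),
                                    ca = calcium_params(),
                                    seed = NULL,
                                    features = c("red", "yellow",
                                                 "strawberry", "banana")) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(morphology)) {
    morphology <- build_surrogate_morphology(30, 200, 10)
  }
  stopifnot(morphology$n_dendrites >= 30 || morphology$n_dendrites >= 2)
  L <- morphology$dendrite_length
  nd <- morphology$n_dendrites
  nseg <- morphology$segments_per_dendrite
  place <- function(dend, d_um) {
    seg <- pmin(pmax(ceiling(d_um / (L / nseg)), 1), nseg)
    1L + (dend - 1L) * nseg + seg
  }
  w_mean <- if (with_inhibition) 0.45 else 0.3
  n_exc <- n_per_feature * length(features) + n_unspecific
  d_um <- stats::runif(n_exc, 10, L)
  dend <- sample(nd, n_exc, replace = TRUE)
  exc <- data.frame(
    comp = place(dend, d_um), dist = d_um,
    feature = c(rep(features, each = n_per_feature),
                rep("unspecific", n_unspecific)),
    cluster = NA_integer_,
    w = pmax(stats::runif(n_exc, w_mean - 0.1, w_mean + 0.1), 0))
  inh <- NULL
  if (with_inhibition) {
    n_i <- n_inh_per_feature * length(features)
    d_i <- stats::runif(n_i, 10, L)
    inh <- data.frame(comp = place(sample(nd, n_i, replace = TRUE), d_i),
                      dist = d_i,
                      feature = rep(features, each = n_inh_per_feature),
                      w = stats::runif(n_i, 0.09e-3, 0.11e-3))
  }
  build_model(morphology, exc, inh, spill_mode = "branch", syn = syn,
              ca = ca)
}

#' Smallest co-active cluster size that triggers spillover
#'
#' Places a cluster of `n_max` synapses at fixed weight on one dendrite,
#' co-activates the first k of them for k = 1..n_max (one simultaneous
#' spike each, background noise off) and reports the smallest k for which
#' the spillover unit triggers during simulation.
#'
#' @param w synaptic weight of every cluster synapse.
#' @param n_max cluster size to build.
#' @param distance cluster somatic distance (um).
#' @param syn,ca parameter sets.
#' @param dt integration step (ms).
#' @return list with `onset` (smallest triggering size, NA if none) and
#'   `triggered` (logical per size).
#' @export
spillover_onset_size <- function(w = 0.25, n_max = 20, distance = 140,
                                 syn = synapse_params(),
                                 ca = calcium_params(), dt = 0.1) {
  set.seed(1)
  model <- calibration_reference(n_syn = n_max, w = w, distance = distance,
                                 ca = ca, syn = syn)
  triggered <- logical(n_max)
  for (k in seq_len(n_max)) {
    rows <- c(model$pack$map$ampa[seq_len(k)], model$pack$map$nmda[seq_len(k)])
    ev <- cbind(rep(10, length(rows)), rows)
    sim <- simulate_window(model, ev, duration = 60, dt = dt)
    triggered[k] <- is.finite(sim$trigger_time[1])
  }
  list(onset = if (any(triggered)) min(which(triggered)) else NA_integer_,
       triggered = triggered)
}

#' Cluster-size characterization sweep
#'
#' For each synaptic weight, activates clusters of increasing size and
#' records the peak somatic voltage, spine-head voltage, NMDA calcium and
#' L-type calcium (averaged over the active spines), averaged over
#' dendrites and trials with background noise on.  The discontinuous jump
#' of the response at the spillover trigger size is the plateau onset.
#'
#' @param weights cluster synaptic weights to test.
#' @param sizes cluster sizes (co-active synapse counts).
#' @param n_dendrites dendrites to average over.
#' @param n_trials trials per dendrite.
#' @param distance cluster somatic distance (um).
#' @param syn,ca parameter sets.
#' @param dt integration step (ms).
#' @param seed RNG seed.
#' @return data.frame with mean peak measures and the trigger fraction per
#'   (weight, size), plus an `onset` attribute with the plateau onset size
#'   per weight.
#' @export
experiment_cluster_size_sweep <- function(weights = c(0.25, 0.4, 0.2),
                                          sizes = 1:20,
                                          n_dendrites = 10, n_trials = 10,
                                          distance = 140,
                                          syn = synapse_params(),
                                          ca = calcium_params(),
                                          dt = 0.1, seed = 1) {
  set.seed(seed)
  morph <- build_surrogate_morphology(max(n_dendrites, 2), 200, 10)
  n_max <- max(sizes)
  res <- list()
  for (w in weights) {
    acc <- array(0, dim = c(length(sizes), 5))
    for (dd in seq_len(n_dendrites)) {
      d_um <- stats::runif(n_max, distance - 10, distance + 10)
      seg_len <- morph$dendrite_length / morph$segments_per_dendrite
      seg <- pmin(pmax(ceiling(d_um / seg_len), 1),
                  morph$segments_per_dendrite)
      comp <- morph$comp$id[morph$comp$dendrite == dd][seg]
      exc <- data.frame(comp = comp, dist = d_um, feature = "yellow",
                        cluster = 1L, w = w)
      model <- build_model(morph, exc, spill_mode = "cluster", syn = syn,
                           ca = ca, noise = TRUE)
      for (tr in seq_len(n_trials)) {
        for (si in seq_along(sizes)) {
          k <- sizes[si]
          act <- seq_len(k)
          t_sp <- stats::runif(k, 0, 5)
          ev <- cbind(rep(t_sp, 2),
                      c(model$pack$map$ampa[act], model$pack$map$nmda[act]))
          ne <- generate_background_noise(model$syn$noise_rate_exc, 300,
                                          model$pack$map$n_noise)
          ni <- generate_background_noise(model$syn$noise_rate_inh, 300,
                                          model$pack$map$n_noise)
          ev <- rbind(ev,
                      cbind(unlist(ne), rep(model$pack$map$noise_exc,
                                            lengths(ne))),
                      cbind(unlist(ni), rep(model$pack$map$noise_inh,
                                            lengths(ni))))
          sim <- simulate_window(model, ev, duration = 300, dt = dt)
          heads <- model$pack$map$head[act]
          acc[si, ] <- acc[si, ] + c(
            sim$v_peak[1], mean(sim$v_peak[heads]),
            mean(sim$ca_nmda_peak[act]), mean(sim$ca_ltype_peak[act]),
            is.finite(sim$trigger_time[1]))
        }
      }
    }
    acc <- acc / (n_dendrites * n_trials)
    res[[length(res) + 1]] <- data.frame(
      weight = w, size = sizes, v_soma_peak = acc[, 1],
      v_spine_peak = acc[, 2], ca_nmda_peak = acc[, 3],
      ca_ltype_peak = acc[, 4], trigger_fraction = acc[, 5])
  }
  out <- do.call(rbind, res)
  onset <- vapply(weights, function(w) {
    tf <- out$trigger_fraction[out$weight == w]
    if (any(tf > 0.5)) sizes[min(which(tf > 0.5))] else NA_integer_
  }, numeric(1))
  attr(out, "onset") <- stats::setNames(onset, weights)
  out
}

#' Train every clustered input configuration
#'
#' Runs the training protocol once per configuration and reports the
#' final-window performance, the solved flag and the subgroup (at most
#' three features per dendrite vs. a four-feature dendrite).
#'
#' @param configs configurations to run; defaults to all 31.
#' @param with_inhibition train with plastic inhibitory synapses.
#' @param protocol a [training_protocol()].
#' @param exc_params,inh_params plasticity parameter sets.
#' @param syn,ca model parameter sets.
#' @param distance cluster somatic distance (um).
#' @param seed base seed; run i uses `seed + i`.
#' @return data.frame with one row per configuration.
#' @export
experiment_configuration_sweep <- function(configs =
                                             enumerate_clustered_configurations(),
                                           with_inhibition = FALSE,
                                           protocol = training_protocol(),
                                           exc_params = exc_plasticity_params(),
                                           inh_params = inh_plasticity_params(),
                                           syn = synapse_params(),
                                           ca = calcium_params(),
                                           distance = 140, seed = 1) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    set.seed(seed + i)
    model <- build_clustered_setup(cfg, distance = distance,
                                   with_inhibition = with_inhibition,
                                   syn = syn, ca = ca)
    tr <- run_training(model, protocol, exc_params, inh_params,
                       plasticity = list(exc = TRUE, inh = with_inhibition),
                       seed = seed + i)
    data.frame(config = cfg$id, group = cfg$group,
               performance = tr$final_performance, solved = tr$solved)
  })
  do.call(rbind, rows)
}

#' Cluster-distance sweep
#'
#' Trains the three-feature example configuration with its clusters placed
#' at random somatic distances, jittering the passive parameters by +/-10%
#' per arrangement to emulate dendrite-pair variability, and fits the
#' performance-vs-distance relation with an ordinary least-squares
#' quadratic.
#'
#' @param n_arrangements number of random arrangements.
#' @param distance_range sampled distance range (um).
#' @param with_inhibition train with inhibitory plasticity.
#' @param protocol,exc_params,inh_params,syn,ca parameter sets.
#' @param seed base seed.
#' @return list with the per-arrangement data.frame (`data`), the fitted
#'   quadratic coefficients (`fit`), and the interior argmax of the fit
#'   (`optimum_um`).
#' @export
experiment_distance_sweep <- function(n_arrangements = 60,
                                      distance_range = c(20, 190),
                                      with_inhibition = FALSE,
                                      protocol = training_protocol(),
                                      exc_params = exc_plasticity_params(),
                                      inh_params = inh_plasticity_params(),
                                      syn = synapse_params(),
                                      ca = calcium_params(),
                                      seed = 1) {
  rows <- lapply(seq_len(n_arrangements), function(i) {
    set.seed(seed + 1000 + i)
    d <- stats::runif(1, distance_range[1], distance_range[2])
    mb <- membrane_params()
    jit <- stats::runif(2, 0.9, 1.1)
    mb$g_pas <- mb$g_pas * jit[1]
    mb$g_kir_dens <- mb$g_kir_dens * jit[2]
    morph <- build_surrogate_morphology(2, 200, 10, membrane = mb)
    model <- build_clustered_setup(fig3_configuration(), distance = d,
                                   with_inhibition = with_inhibition,
                                   morphology = morph, syn = syn, ca = ca)
    tr <- run_training(model, protocol, exc_params, inh_params,
                       plasticity = list(exc = TRUE, inh = with_inhibition),
                       seed = seed + 2000 + i)
    data.frame(arrangement = i, distance = d,
               performance = tr$final_performance)
  })
  dat <- do.call(rbind, rows)
  fit <- stats::lm(performance ~ distance + I(distance^2), data = dat)
  cf <- stats::coef(fit)
  opt <- if (!anyNA(cf) && cf[3] < 0) -cf[2] / (2 * cf[3]) else NA_real_
  list(data = dat, fit = cf, optimum_um = unname(opt))
}

#' Distributed-synapse training runs
#'
#' Trains `n_distributions` independent random synapse distributions over
#' 30 dendrites (branch-wide spillover) and reports final performances and
#' their distribution over the bands around 75%, between 75 and 100%, and
#' near 100%.
#'
#' @param n_distributions number of random placements.
#' @param with_inhibition include inhibitory plasticity.
#' @param protocol,exc_params,inh_params,syn,ca parameter sets.
#' @param seed base seed.
#' @return list with the per-run data.frame (`data`), mean performance and
#'   band counts.
#' @export
experiment_distributed <- function(n_distributions = 31,
                                   with_inhibition = FALSE,
                                   protocol = training_protocol(),
                                   exc_params = exc_plasticity_params(),
                                   inh_params = inh_plasticity_params(),
                                   syn = synapse_params(),
                                   ca = calcium_params(),
                                   seed = 1) {
  rows <- lapply(seq_len(n_distributions), function(i) {
    model <- build_distributed_setup(with_inhibition = with_inhibition,
                                     syn = syn, ca = ca,
                                     seed = seed + 3000 + i)
    tr <- run_training(model, protocol, exc_params, inh_params,
                       plasticity = list(exc = TRUE, inh = with_inhibition),
                       seed = seed + 4000 + i)
    data.frame(distribution = i, performance = tr$final_performance,
               solved = tr$solved)
  })
  dat <- do.call(rbind, rows)
  list(data = dat, mean_performance = mean(dat$performance),
       bands = c(near_75 = sum(abs(dat$performance - 75) <= 7.5),
                 mid = sum(dat$performance > 82.5 & dat$performance < 92.5),
                 near_100 = sum(dat$performance >= 92.5)))
}

#' Linearly separable control task
#'
#' Trains a random distributed placement to respond to a single rewarded
#' conjunction (default red+strawberry); the other three conjunctions are
#' irrelevant.  Supports the subthreshold variant in which feedback is
#' delivered even without somatic spiking.
#'
#' @param subthreshold use subthreshold feedback delivery.
#' @param relevant the single rewarded stimulus id.
#' @param with_inhibition include inhibitory plasticity.
#' @param protocol,exc_params,inh_params,syn,ca parameter sets.
#' @param plasticity_off control run with all plasticity frozen.
#' @param seed RNG seed.
#' @return the `spn_training` result.
#' @export
experiment_linear_task <- function(subthreshold = FALSE,
                                   relevant = "red+strawberry",
                                   with_inhibition = FALSE,
                                   protocol = training_protocol(),
                                   exc_params = exc_plasticity_params(),
                                   inh_params = inh_plasticity_params(),
                                   syn = synapse_params(),
                                   ca = calcium_params(),
                                   plasticity_off = FALSE,
                                   seed = 1) {
  protocol$subthreshold_mode <- subthreshold
  stimuli <- nfbp_stimuli(relevant = relevant)
  model <- build_distributed_setup(with_inhibition = with_inhibition,
                                   syn = syn, ca = ca, seed = seed + 5000)
  run_training(model, protocol, exc_params, inh_params,
               plasticity = list(exc = !plasticity_off,
                                 inh = with_inhibition && !plasticity_off),
               stimuli = stimuli, seed = seed + 6000)
}
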