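test_that("configuration enumeration yields 31 assignments split 18/13,
           all covering the four features", {
  cfgs <- enumerate_clustered_configurations()
  expect_length(cfgs, 31)
  groups <- vapply(cfgs, `[[`, character(1), "group")
  expect_equal(sum(groups == "le3"), 18)
  expect_equal(sum(groups == "four"), 13)
  feats <- c("red", "yellow", "strawberry", "banana")
  for (cfg in cfgs) {
    expect_setequal(union(cfg$d1, cfg$d2), feats)
    # each dendrite carries at least one full relevant conjunction
    has_rel <- function(s) all(c("red", "strawberry") %in% s) ||
      all(c("yellow", "banana") %in% s)
    expect_true(has_rel(cfg$d1))
    expect_true(has_rel(cfg$d2))
  }
  ids <- vapply(cfgs, `[[`, character(1), "id")
  expect_false(any(duplicated(ids)))
})

test_that("the clustered builder places the stated synapse counts, weights
           and inhibitory complement", {
  m <- build_clustered_setup(fig3_configuration(), seed = 3)
  expect_equal(sum(m$exc$feature != "unspecific"), 30)  # 2 x 3 features x 5
  expect_equal(sum(m$exc$feature == "unspecific"), 108)
  expect_true(all(m$exc$w >= 0.2 & m$exc$w <= 0.3))
  cl <- m$exc[!is.na(m$exc$cluster), ]
  expect_true(all(abs(cl$dist - 140) <= 10))
  expect_equal(nrow(m$inh), 0)
  mi <- build_clustered_setup(fig3_configuration(), with_inhibition = TRUE,
                              seed = 3)
  expect_equal(nrow(mi$inh), 8)                         # 4 features x 2
  expect_equal(sum(mi$exc$feature == "unspecific"), 144)
  expect_true(all(mi$inh$w >= 0.09e-3 & mi$inh$w <= 0.11e-3))
  expect_error(build_clustered_setup(fig3_configuration(), distance = 300),
               "distance")
  bad <- fig3_configuration(); bad$d1 <- c("apple", "banana", "red")
  expect_error(build_clustered_setup(bad, seed = 1), "labels")
})

test_that("the distributed builder places 200 excitatory (+60 inhibitory)
           synapses over 30 dendrites in branch mode", {
  m <- build_distributed_setup(seed = 4)
  expect_equal(nrow(m$exc), 200)
  expect_equal(unname(table(m$exc$feature)["red"]), 40)
  expect_equal(sum(m$exc$feature == "unspecific"), 40)
  expect_equal(m$spill_mode, "branch")
  expect_true(all(m$exc$w >= 0.2 & m$exc$w <= 0.4))
  mi <- build_distributed_setup(with_inhibition = TRUE, seed = 4)
  expect_equal(nrow(mi$inh), 60)
  expect_equal(unname(table(mi$inh$feature)["banana"]), 15)
  expect_true(all(mi$exc$w >= 0.35 & mi$exc$w <= 0.55))
  m2 <- build_distributed_setup(seed = 5)
  expect_false(all(m2$exc$comp == m$exc$comp))
  expect_equal(table(m2$exc$feature), table(m$exc$feature))
})

test_that("plateau onset sizes follow the trigger arithmetic across
           synaptic weights", {
  o25 <- spillover_onset_size(0.25, dt = 0.25)
  o40 <- spillover_onset_size(0.40, dt = 0.25)
  o20 <- spillover_onset_size(0.20, dt = 0.25)
  expect_equal(o25$onset, 8)
  expect_equal(o40$onset, 5)
  expect_equal(o20$onset, 10)
  # triggering is monotone in the co-active count
  expect_true(all(diff(o25$triggered) >= 0))
})

test_that("the cluster-size characterization records the discontinuity at
           the trigger size", {
  sw <- experiment_cluster_size_sweep(weights = 0.25, sizes = c(6, 7, 8, 9),
                                      n_dendrites = 2, n_trials = 2,
                                      dt = 0.5, seed = 2)
  on <- attr(sw, "onset")
  expect_equal(unname(on["0.25"]), 8)
  expect_true(all(sw$trigger_fraction[sw$size >= 8] == 1))
  expect_true(all(sw$trigger_fraction[sw$size < 8] == 0))
  # calcium jumps with the trigger
  expect_gt(sw$ca_nmda_peak[sw$size == 8], 1.5 * sw$ca_nmda_peak[sw$size == 7])
})

test_that("training results round-trip through the results writer and the
           manifest reproduces the run", {
  proto <- training_protocol(n_stimuli = 24, dt = 0.5)
  model <- build_clustered_setup(fig3_configuration(), seed = 6)
  tr <- run_training(model, proto, plasticity = list(exc = TRUE, inh = FALSE),
                     seed = 6, weight_log_every = 8)
  out <- file.path(tempdir(), "spnlearn-results")
  write_results(tr, out)
  got <- read_results(out)
  expect_equal(got$records$correct, tr$records$correct)
  expect_equal(nrow(got$synapses), nrow(model$exc))
  # the manifest carries every plasticity parameter of both rule tables
  expect_true(all(c("eta_ltp", "theta_ltp0", "beta_ltp", "eta_ltd",
                    "theta_ltd", "beta_ltd", "eta_s_ltp", "eta_s_ltd",
                    "beta_mp") %in% names(got$metadata$config$exc_params)))
  expect_true(all(c("beta_inh", "eta_act", "a_inh", "b_inh", "w_inh_max",
                    "eta_inh_high", "eta_inh_low", "c_offset") %in%
                    names(got$metadata$config$inh_params)))
  # re-running from the manifest seed reproduces the records bit-identically
  tr2 <- run_training(build_clustered_setup(fig3_configuration(), seed = 6),
                      proto, plasticity = list(exc = TRUE, inh = FALSE),
                      seed = got$metadata$config$seed, weight_log_every = 8)
  expect_identical(tr2$records, tr$records)
  unlink(out, recursive = TRUE)
})

test_that("all state returns to baseline well before the next stimulus at
           the protocol's inter-stimulus interval", {
  model <- build_clustered_setup(fig3_configuration(), seed = 7)
  proto <- training_protocol()
  st <- nfbp_stimuli()
  set.seed(7)
  ev <- stimulus_events(model, st[4, ], proto, duration = 350)
  # simulate through stimulus + feedback + full 800 ms ISI
  sim <- simulate_window(model, ev, duration = 350 + 800, dt = 0.25)
  vr <- model$v_rest
  expect_lt(max(abs(sim$v_final - vr)), 0.01 * abs(vr))
  # calcium pools decayed back to within 1% of their stimulus peak
  fin <- simulate_window(model, ev, duration = 350 + 800, dt = 0.25,
                         record = TRUE, rec_comps = 1,
                         rec_pools = which.max(sim$ca_nmda_peak),
                         stride = 40)
  last <- nrow(fin$ca_nmda_trace)
  expect_lt(fin$ca_nmda_trace[last, 1], 0.01 * max(fin$ca_nmda_trace[, 1]))
  expect_lt(fin$ca_ltype_trace[last, 1],
            0.01 * max(max(fin$ca_ltype_trace[, 1]), 1e-9))
})

test_that("distributed-input learning shows the inhibitory-plasticity
           advantage and the moderate excitatory-only mean", {
  proto <- training_protocol(n_stimuli = 480, dt = 0.5)
  without <- experiment_distributed(2, with_inhibition = FALSE,
                                    protocol = proto, seed = 1)
  with_i <- experiment_distributed(2, with_inhibition = TRUE,
                                   protocol = proto, seed = 1)
  # moderate mean without inhibition; higher with plastic inhibition
  expect_gt(without$mean_performance, 50)
  expect_lt(without$mean_performance, 80)
  expect_gte(with_i$mean_performance, without$mean_performance)
  expect_named(with_i$bands, c("near_75", "mid", "near_100"))
})

test_that("the distance sweep runs end to end and fits a quadratic", {
  proto <- training_protocol(n_stimuli = 96, dt = 0.5)
  sw <- experiment_distance_sweep(n_arrangements = 2,
                                  protocol = proto, seed = 2)
  expect_equal(nrow(sw$data), 2)
  expect_length(sw$fit, 3)
  expect_true(all(sw$data$distance >= 20 & sw$data$distance <= 190))
})

test_that("after clustered learning with inhibition, inhibitory weights of
           the dendrite's relevant features end below the others", {
  proto <- training_protocol(n_stimuli = 480, dt = 0.5)
  m <- build_clustered_setup(fig3_configuration(), with_inhibition = TRUE,
                             seed = 11)
  tr <- run_training(m, proto, plasticity = list(exc = TRUE, inh = TRUE),
                     seed = 11)
  iw <- tr$final$w_inh
  # d1 learned yellow+banana; d2 learned red+strawberry
  d1 <- m$inh$comp <= 11  # dendrite-1 compartments (soma is 1)
  rel1 <- m$inh$feature %in% c("yellow", "banana")
  rel2 <- m$inh$feature %in% c("red", "strawberry")
  expect_lt(mean(iw[d1 & rel1]), mean(iw[d1 & !rel1]))
  expect_lt(mean(iw[!d1 & rel2]), mean(iw[!d1 & !rel2]))
  expect_true(tr$solved)
  # learning direction on the excitatory side: each dendrite's relevant
  # features end above its irrelevant feature, and the feature-unspecific
  # population is weakened on average
  exw <- tr$final$w
  ed1 <- m$exc$dendrite == 1
  expect_gt(median(exw[ed1 & m$exc$feature %in% c("yellow", "banana")]),
            median(exw[ed1 & m$exc$feature == "red"]))
  expect_gt(median(exw[!ed1 & m$exc$feature %in% c("red", "strawberry")]),
            median(exw[!ed1 & m$exc$feature == "yellow"]))
  uns <- m$exc$feature == "unspecific"
  expect_lt(mean(exw[uns]), mean(m$exc$w[uns]))
})
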