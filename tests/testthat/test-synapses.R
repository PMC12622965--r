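test_that("saturating gates are bounded by 1, monotone under repeated
           spikes, and decay away", {
  g1 <- saturating_gate(10, duration = 800, dt = 0.1)
  expect_lte(max(g1), 1)
  g2 <- saturating_gate(c(10, 11), duration = 800, dt = 0.1)
  expect_lte(max(g2), 1)
  expect_gte(max(g2), max(g1))
  # after 10 decay constants the gate is below 1% of its peak
  tg <- seq(0, 800, by = 0.1)
  expect_lt(g2[which.min(abs(tg - (11 + 10 * 70)))], 0.01 * max(g2))
  expect_error(advance_gate(gate_state(), -1), "backwards")
})

test_that("the C++ gate matches the event-driven R reference", {
  model <- cluster_model(n = 2)
  r <- model$pack$map$nmda[1]
  ev <- cbind(c(10, 15), c(r, r))
  sim <- simulate_window(model, ev, duration = 200, dt = 0.1)
  ref <- saturating_gate(c(10, 15), duration = 200, dt = 0.1,
                         tau_rise = model$syn$tau_nmda[1],
                         tau_decay = model$syn$tau_nmda[2])
  expect_equal(sim$gate_peak[r], max(ref), tolerance = 0.02)
})

test_that("magnesium block is sigmoidal, monotone increasing, with the
           stated limits", {
  expect_lt(mg_block(-120), 0.05)
  expect_gt(mg_block(40), 0.9)
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(mg_block(v)) > 0))
  expect_true(all(mg_block(v) > 0 & mg_block(v) < 1))
  # NMDA current: zero at the reversal, inward below it
  expect_equal(nmda_current(0, 0.5, 0.25), 0)
  expect_lt(nmda_current(-40, 0.5, 0.25), 0)
  expect_error(nmda_current(NaN, 1, 1), "finite")
})

test_that("the spillover trigger implements the inclusive weight-sum rule", {
  # the worked example: 8 synapses of weight 0.25 trigger exactly
  expect_true(check_spillover(rep(0.25, 8), 1:8))
  expect_false(check_spillover(rep(0.25, 8), 1:7))     # sum 1.75
  expect_true(check_spillover(rep(0.4, 5), 1:5))       # sum 2.0
  expect_false(check_spillover(rep(0.2, 20), 1:9))     # sum 1.8
  expect_true(check_spillover(rep(0.2, 20), 1:10))     # sum 2.0
  # monotone: any superset of a triggering set triggers
  w <- runif(20, 0.1, 0.3)
  a <- which(cumsum(w) >= 2)[1]
  expect_true(check_spillover(w, 1:a))
  expect_true(check_spillover(w, 1:(a + 3)))
})

test_that("spillover pooling is per cluster in clustered mode and per
           branch in distributed mode", {
  morph <- tiny_morph()
  # 8 synapses scattered along dendrite 1 (comps 2..9)
  exc <- data.frame(comp = 2:9, dist = seq(10, 170, length.out = 8),
                    feature = "yellow", cluster = NA_integer_, w = 0.25)
  mb <- build_model(morph, exc, spill_mode = "branch", noise = FALSE)
  s <- spillover_weight_sums(mb, 1:8)
  expect_true(s$triggered[s$unit == 1])
  # same synapses split 4 + 4 across the two branches: neither triggers
  exc2 <- exc
  exc2$comp[5:8] <- exc2$comp[5:8] + 10   # move to dendrite 2
  mb2 <- build_model(morph, exc2, spill_mode = "branch", noise = FALSE)
  s2 <- spillover_weight_sums(mb2, 1:8)
  expect_false(any(s2$triggered))
  # clustered mode with the same scattered placement: no cluster, no unit
  mc <- build_model(morph, exc, spill_mode = "cluster", noise = FALSE)
  expect_equal(nrow(spillover_weight_sums(mc, 1:8)), 0)
  # and the simulated trigger agrees with the arithmetic
  ev <- cbind(rep(10, 16), c(mb$pack$map$ampa, mb$pack$map$nmda))
  sim <- simulate_window(mb, ev, duration = 50, dt = 0.1)
  expect_true(is.finite(sim$trigger_time[1]))
  sim2 <- simulate_window(mb2, ev, duration = 50, dt = 0.1)
  expect_false(any(is.finite(sim2$trigger_time)))
})

test_that("weight coupling: doubling w doubles both AMPA and NMDA
           conductances in the compiled model", {
  model <- cluster_model(n = 2, w = 0.2)
  g1 <- model$pack$syn_g[c(model$pack$map$ampa[1], model$pack$map$nmda[1])]
  model$exc$w <- model$exc$w * 2
  model <- spnlearn:::sync_weights(model)
  g2 <- model$pack$syn_g[c(model$pack$map$ampa[1], model$pack$map$nmda[1])]
  expect_equal(g2, 2 * g1)
})

test_that("background noise trains are Poisson with the requested rate and
           reproducible under a seed", {
  set.seed(4)
  expect_identical(generate_background_noise(0, 1000, 3),
                   list(numeric(0), numeric(0), numeric(0)))
  set.seed(4)
  a <- generate_background_noise(5, 2000, 10)
  set.seed(4)
  b <- generate_background_noise(5, 2000, 10)
  expect_identical(a, b)
  # mean count over 100 draws within 3 sigma of rate x duration
  set.seed(5)
  n <- lengths(generate_background_noise(8, 1000, 100))
  lambda <- 8 * 1000 / 1000
  expect_lt(abs(mean(n) - lambda), 3 * sqrt(lambda / 100))
})

test_that("supralinearity: the somatic response jumps at the spillover
           trigger size", {
  model <- cluster_model(n = 10, w = 0.25)
  peaks <- vapply(c(4, 7, 8, 10), function(k) {
    sim <- simulate_window(model, coactivate(model, k), duration = 300,
                           dt = 0.25)
    sim$v_peak[1]
  }, numeric(1))
  # below trigger, somatic growth per added synapse is modest; the jump
  # from 7 to 8 synapses (the trigger) clearly exceeds it
  per_size_below <- (peaks[2] - peaks[1]) / 3
  expect_gt(peaks[3] - peaks[2], 2 * per_size_below)
  expect_gte(peaks[4], peaks[3] - 1)
})

test_that("an active inhibitory synapse near a triggered cluster reduces
           the plateau peak", {
  morph <- tiny_morph()
  seg <- 8
  exc <- data.frame(comp = 1L + seg, dist = 150, feature = "yellow",
                    cluster = 1L, w = rep(0.3, 8))
  inh <- data.frame(comp = 1L + seg, dist = 150, feature = "yellow",
                    w = 4e-3)
  m_inh <- build_model(morph, exc, inh, spill_mode = "cluster", noise = FALSE)
  ev0 <- coactivate(m_inh, 8)
  sim0 <- simulate_window(m_inh, ev0, duration = 300, dt = 0.1)
  ev1 <- rbind(ev0, cbind(10, m_inh$pack$map$gaba[1]))
  sim1 <- simulate_window(m_inh, ev1, duration = 300, dt = 0.1)
  expect_lt(sim1$v_peak[1 + seg], sim0$v_peak[1 + seg])
})
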