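test_that("surrogate construction arithmetic and guards", {
  m2 <- build_surrogate_morphology(2, 200, 10, taper = 0.7)
  expect_equal(nrow(m2$comp), 21)
  expect_equal(max(m2$comp$somatic_distance), 190)  # distal midpoint
  m30 <- build_surrogate_morphology(30, 200, 10, taper = 0.7)
  expect_equal(nrow(m30$comp), 301)
  # exactly one root; parent structure is a tree in construction order
  expect_equal(sum(is.na(m2$comp$parent)), 1)
  expect_true(all(m2$comp$parent[-1] < m2$comp$id[-1]))
  # dendritic diameter is non-increasing with distance along each path
  for (d in 1:2) {
    dd <- m2$comp[m2$comp$dendrite == d, ]
    expect_true(all(diff(dd$diameter[order(dd$somatic_distance)]) <= 0))
  }
  expect_error(build_surrogate_morphology(1, 200, 10), "n_dendrites")
  expect_error(build_surrogate_morphology(2, 100, 10), "dendrite_length")
  expect_error(build_surrogate_morphology(2, 200, 4), "40 um")
  expect_error(build_surrogate_morphology(2, 200, 10, taper = 0), "taper")
})

test_that("resting potential sits in the hyperpolarized band and is the
           fixed point of the integrator", {
  m <- tiny_morph()
  vr <- resting_potential(m)
  expect_gt(vr, -90)
  expect_lt(vr, -80)
  model <- cluster_model(n = 2, morphology = m)
  st <- membrane_state(model)
  st2 <- step_membrane(model, st, dt = 0.1)
  expect_lt(max(abs(st2$v - st$v)), 1e-9)
  # and stays there over a long quiet window
  sim <- simulate_window(model, NULL, duration = 500, dt = 0.5)
  expect_lt(max(abs(sim$v_final - vr)), 1e-6)
})

test_that("input impedance grows with somatic distance and brute-force
           scanning confirms the extremes", {
  m <- tiny_morph()
  z <- vapply(m$comp$id, function(i) input_impedance(m, i), numeric(1))
  expect_equal(which.min(z), 1)                      # soma smallest
  d1 <- m$comp$id[m$comp$dendrite == 1]
  expect_equal(d1[which.max(z[d1])], max(d1))        # tip largest on path
  expect_true(all(diff(z[d1]) >= 0))                 # monotone along branch
  expect_error(input_impedance(m, 999), "unknown site")
})

test_that("passive-limit steady state matches the linear-system oracle to
           within 0.1%", {
  mb <- membrane_params(g_kir_dens = 0)
  m <- tiny_morph(membrane = mb)
  # the obligatory spine sits on the far dendrite so its (tiny) leak load
  # does not perturb the measured branch
  model <- build_model(m, data.frame(comp = 21, dist = 190,
                                     feature = "yellow", cluster = 1L,
                                     w = 0), noise = FALSE)
  site <- 8
  inj <- cbind(site, -0.1, 0, 2000)
  sim <- simulate_window(model, NULL, duration = 2000, dt = 0.25, inj = inj)
  # oracle: G v = i on the morphology compartments
  G <- spnlearn:::conductance_matrix(m, kir_on = FALSE)
  i <- numeric(nrow(m$comp)); i[site] <- -0.1
  v_pred <- mb$e_pas + solve(G, i)
  got <- sim$v_final[seq_len(nrow(m$comp))]
  expect_lt(max(abs(got - v_pred)) / max(abs(v_pred - mb$e_pas)), 1e-3)
  # local deflection magnitude equals current x input impedance
  expect_equal(sim$v_final[site] - mb$e_pas,
               -0.1 * input_impedance(m, site, kir_on = FALSE),
               tolerance = 1e-3)
})

test_that("a step current hyperpolarizes and the membrane relaxes back to
           rest within a few time constants", {
  model <- cluster_model(n = 2)
  vr <- model$v_rest
  inj <- cbind(1, -0.1, 10, 300)
  sim <- simulate_window(model, NULL, duration = 800, dt = 0.25, inj = inj,
                         record = TRUE, rec_comps = 1, stride = 4)
  v_on <- sim$v_trace[sim$t > 250 & sim$t < 300, 1]
  expect_lt(mean(v_on), vr - 1)        # steady hyperpolarization
  # back to rest well before the end (5 membrane time constants ~ 60 ms)
  expect_lt(abs(sim$v_final[1] - vr), 0.05)
})

test_that("charge conservation with all channels off and sealed ends", {
  mb <- membrane_params(g_pas = 1e-9, g_kir_dens = 0)
  m <- tiny_morph(membrane = mb)
  model <- build_model(m, data.frame(comp = 11, dist = 190,
                                     feature = "yellow", cluster = 1L,
                                     w = 0), noise = FALSE)
  q_in <- -0.05 * 100                      # nA * ms = pC (hyperpolarizing,
  inj <- cbind(5, -0.05, 0, 100)           # so the spike mechanism stays out)
  sim <- simulate_window(model, NULL, duration = 400, dt = 0.1, inj = inj)
  cap <- model$pack$cap
  q_stored <- sum(cap * (sim$v_final - model$v_rest))  # nF * mV = pC
  expect_equal(q_stored, q_in, tolerance = 1e-3)
})

test_that("somatic spike detection finds threshold crossings with the
           refractory rule", {
  expect_length(detect_somatic_spikes(rep(-85, 1000)), 0)
  ramp <- seq(-85, -20, length.out = 200)
  expect_equal(detect_somatic_spikes(ramp, threshold = -40),
               which(ramp >= -40)[1] - 1)
  # two crossings 3 ms apart with 5 ms refractory -> one spike
  tr <- rep(-80, 20)
  tr[c(5, 8)] <- -30
  expect_length(detect_somatic_spikes(tr, refractory = 5), 1)
  tr2 <- rep(-80, 20)
  tr2[c(5, 12)] <- -30
  expect_length(detect_somatic_spikes(tr2, refractory = 5), 2)
  expect_length(detect_somatic_spikes(numeric(0)), 0)
})

test_that("integration is stable over long windows at both ends of the
           allowed step range", {
  model <- cluster_model(n = 4)
  set.seed(1)
  ev <- coactivate(model, 4)
  for (dt in c(0.5, 0.1)) {
    sim <- simulate_window(model, ev, duration = 10000, dt = dt)
    expect_true(all(is.finite(sim$v_final)))
  }
  expect_error(simulate_window(model, NULL, duration = 10, dt = 1), "dt")
})

test_that("morphology JSON serialization round-trips", {
  m <- build_surrogate_morphology(3, 220, 11, taper = 0.5)
  path <- tempfile(fileext = ".json")
  morphology_to_json(m, path)
  m2 <- morphology_from_json(path)
  expect_equal(m2$comp, m$comp, tolerance = 1e-12)
  expect_equal(m2$n_dendrites, 3)
  expect_equal(resting_potential(m2), resting_potential(m))
  unlink(path)
})
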