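test_that("stimulus sequence is block-balanced and seed-reproducible", {
  st <- nfbp_stimuli()
  set.seed(1)
  s12 <- make_stimulus_sequence(training_protocol(n_stimuli = 12))
  expect_equal(as.vector(table(s12)), rep(3, 4))
  set.seed(1)
  s960 <- make_stimulus_sequence(training_protocol(n_stimuli = 960))
  expect_equal(as.vector(table(s960)), rep(240, 4))
  # any whole number of blocks is balanced per type
  for (b in c(1, 5, 40)) {
    expect_equal(as.vector(table(s960[seq_len(12 * b)])), rep(3 * b, 4))
  }
  set.seed(2)
  s2 <- make_stimulus_sequence(training_protocol(n_stimuli = 960))
  expect_false(all(s2 == s960))
  expect_equal(as.vector(table(s2)), as.vector(table(s960)))
})

test_that("dopamine feedback implements the reward contingency, including
           the subthreshold variant", {
  expect_identical(dopamine_feedback(TRUE, TRUE), 1L)
  expect_identical(dopamine_feedback(TRUE, FALSE), -1L)
  expect_identical(dopamine_feedback(FALSE, TRUE), 0L)
  expect_identical(dopamine_feedback(FALSE, FALSE), 0L)
  expect_identical(dopamine_feedback(FALSE, TRUE, subthreshold_mode = TRUE), 1L)
  expect_identical(dopamine_feedback(FALSE, FALSE, subthreshold_mode = TRUE), -1L)
})

test_that("the performance metric reproduces the worked response profiles", {
  # balanced window of 160: 40 per type
  mk <- function(correct_by_type) {
    data.frame(correct = rep(correct_by_type, each = 40))
  }
  # one relevant always right (spikes), other three silent:
  # relevant A correct, relevant B wrong (silent), irrelevants correct
  expect_equal(performance(mk(c(TRUE, FALSE, TRUE, TRUE))), 75)
  # spikes for all four: relevants correct, irrelevants wrong
  expect_equal(performance(mk(c(TRUE, TRUE, FALSE, FALSE))), 50)
  expect_equal(performance(mk(c(TRUE, TRUE, TRUE, TRUE))), 100)
  # boundary: relevant B correct on exactly half its presentations
  rec <- data.frame(correct = c(rep(TRUE, 40), rep(c(TRUE, FALSE), 20),
                                rep(TRUE, 80)))
  expect_equal(performance(rec), 87.5)
  expect_false(solved_criterion(87.5))
  expect_true(solved_criterion(90))
  expect_false(solved_criterion(75))
  expect_error(performance(data.frame(correct = logical(0))), "empty")
})

test_that("stimulus delivery activates exactly the feature-matching and
           unspecific synapses, deterministically under a seed", {
  model <- build_clustered_setup(fig3_configuration(), seed = 5)
  st <- nfbp_stimuli()
  proto <- training_protocol()
  yb <- st[st$id == "yellow+banana", ]
  set.seed(9)
  ev <- stimulus_events(model, yb, proto)
  act <- attr(ev, "active_exc")
  feats <- model$exc$feature[act]
  expect_true(all(feats %in% c("yellow", "banana", "unspecific")))
  expect_setequal(which(model$exc$feature %in% c("yellow", "banana", "unspecific")),
                  act)
  # red and strawberry synapses silent
  expect_false(any(model$exc$feature[act] %in% c("red", "strawberry")))
  # unspecific synapses are activated for every one of the four stimuli
  for (s in 1:4) {
    set.seed(s)
    e <- stimulus_events(model, st[s, ], proto)
    expect_true(all(which(model$exc$feature == "unspecific") %in%
                      attr(e, "active_exc")))
  }
  set.seed(9)
  ev2 <- stimulus_events(model, yb, proto)
  expect_identical(ev, ev2)
  # feature events confined to the stimulus window, unspecific to theirs
  f_rows <- model$pack$map$nmda[which(model$exc$feature %in%
                                        c("yellow", "banana"))]
  expect_true(all(ev[ev[, 2] %in% f_rows, 1] <= proto$stimulus_duration))
})

test_that("extended task generator produces the 9- and 25-combination sets
           and degenerates to the standard four", {
  expect_equal(nrow(extended_task_generator(3)), 9)
  expect_equal(nrow(extended_task_generator(5)), 25)
  std <- extended_task_generator(2)
  expect_equal(nrow(std), 4)
  expect_setequal(std$id[std$relevant], c("red+strawberry", "yellow+banana"))
  expect_equal(sum(extended_task_generator(3)$relevant), 2)
  expect_equal(sum(extended_task_generator(5)$relevant), 3)
})

test_that("training with all plasticity off leaves weights constant, and a
           neuron that cannot spike gets no excitatory plasticity", {
  proto <- training_protocol(n_stimuli = 24, dt = 0.5)
  model <- build_clustered_setup(fig3_configuration(), with_inhibition = TRUE,
                                 seed = 5)
  tr0 <- run_training(model, proto, plasticity = list(exc = FALSE, inh = FALSE),
                      seed = 3)
  expect_identical(tr0$final$w, model$exc$w)
  expect_identical(tr0$final$w_inh, model$inh$w)
  # spike threshold out of reach: dopamine stays basal, so excitatory
  # weights are untouched while the inhibitory rule still runs
  mb <- membrane_params(spike_threshold = 100)
  morph <- build_surrogate_morphology(12, 200, 10, membrane = mb)
  m2 <- build_clustered_setup(fig3_configuration(), with_inhibition = TRUE,
                              morphology = morph, seed = 5)
  tr1 <- run_training(m2, proto, plasticity = list(exc = TRUE, inh = TRUE),
                      seed = 3)
  expect_identical(tr1$final$w, m2$exc$w)
  expect_false(identical(tr1$final$w_inh, m2$inh$w))
  expect_true(all(tr1$records$dopamine == 0L))
})

test_that("identical seed and configuration reproduce the response stream
           bit-identically", {
  proto <- training_protocol(n_stimuli = 24, dt = 0.5)
  r1 <- run_training(build_clustered_setup(fig3_configuration(), seed = 5),
                     proto, seed = 3, plasticity = list(exc = TRUE, inh = FALSE))
  r2 <- run_training(build_clustered_setup(fig3_configuration(), seed = 5),
                     proto, seed = 3, plasticity = list(exc = TRUE, inh = FALSE))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$final, r2$final)
})
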