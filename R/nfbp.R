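#' The four feature-combination stimuli of the nonlinear feature binding
#' problem
#'
#' Two colors (red, yellow) crossed with two shapes (strawberry, banana).
#' The relevant conjunctions — the ones the neuron should spike for — are
#' red+strawberry and yellow+banana; the complementary pairings are
#' irrelevant.  The task is linearly non-separable at the level of single
#' features.
#'
#' @param relevant character vector of relevant stimulus ids; defaults to
#'   the standard pair.  Supplying a single id (e.g. `"red+strawberry"`)
#'   turns the task into the linearly separable single-stimulus variant.
#' @return data.frame with columns `id`, `color`, `shape`, `relevant`.
#' @export
nfbp_stimuli <- function(relevant = c("red+strawberry", "yellow+banana")) {
  g <- expand.grid(color = c("red", "yellow"),
                   shape = c("strawberry", "banana"),
                   stringsAsFactors = FALSE)
  g$id <- paste(g$color, g$shape, sep = "+")
  stopifnot(all(relevant %in% g$id))
  g$relevant <- g$id %in% relevant
  g[, c("id", "color", "shape", "relevant")]
}

#' Extended feature sets with more values per feature
#'
#' Generator hook for the harder task variants: `n_values_per_feature`
#' colors crossed with the same number of shapes gives 9 (n = 3) or 25
#' (n = 5) combinations; the diagonal conjunctions are marked relevant
#' (the standard four-stimulus task is the degenerate n = 2 case).
#'
#' @param n_values_per_feature 2, 3 or 5 values per feature.
#' @return data.frame as in [nfbp_stimuli()].
#' @export
extended_task_generator <- function(n_values_per_feature = 3) {
  n <- n_values_per_feature
  stopifnot(n %in% c(2, 3, 5))
  if (n == 2) return(nfbp_stimuli())
  colors <- paste0("color", seq_len(n))
  shapes <- paste0("shape", seq_len(n))
  g <- expand.grid(color = colors, shape = shapes, stringsAsFactors = FALSE)
  g$id <- paste(g$color, g$shape, sep = "+")
  n_rel <- if (n == 3) 2 else 3
  rel <- paste(colors[seq_len(n_rel)], shapes[seq_len(n_rel)], sep = "+")
  g$relevant <- g$id %in% rel
  g[, c("id", "color", "shape", "relevant")]
}

#' Block-shuffled stimulus sequence
#'
#' Concatenates independently shuffled blocks in which each of the four
#' stimulus types appears exactly `block_size / 4` times (three times per
#' block of 12), so any whole number of blocks is balanced across types.
#' Deterministic under the R random seed in force.
#'
#' @param protocol a [training_protocol()].
#' @param stimuli stimulus table from [nfbp_stimuli()].
#' @return integer vector of row indices into `stimuli`, length
#'   `protocol$n_stimuli`.
#' @export
make_stimulus_sequence <- function(protocol = training_protocol(),
                                   stimuli = nfbp_stimuli()) {
  per_block <- protocol$block_size / nrow(stimuli)
  stopifnot(per_block == round(per_block))
  n_blocks <- protocol$n_stimuli / protocol$block_size
  unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(seq_len(nrow(stimuli)), per_block))
  }))
}

#' Dopamine feedback for one stimulus outcome
#'
#' Standard mode: a dopamine peak (+1) for a relevant stimulus the neuron
#' spiked to, a pause (-1) for an irrelevant stimulus it spiked to, and
#' basal level (0) whenever the neuron stayed silent.  In subthreshold
#' mode the cue is delivered regardless of spiking: +1 for relevant, -1
#' for irrelevant.
#'
#' @param spiked logical: somatic spike in the response window.
#' @param relevant logical: is the stimulus a relevant conjunction.
#' @param subthreshold_mode logical.
#' @return integer in {-1, 0, +1}.
#' @export
dopamine_feedback <- function(spiked, relevant, subthreshold_mode = FALSE) {
  if (subthreshold_mode) return(if (relevant) 1L else -1L)
  if (!spiked) return(0L)
  if (relevant) 1L else -1L
}

#' Trailing-window task performance
#'
#' Percentage of correct responses (spike for relevant, silence for
#' irrelevant) over the last `window` stimuli.  100% means the neuron
#' spikes exclusively for relevant stimuli; 50% typically means it spikes
#' for all four (or none); 75% reflects intermediate behavior such as
#' spiking for one relevant combination and staying silent for the other
#' three.
#'
#' @param records data.frame with logical column `correct` (one row per
#'   stimulus, in presentation order).
#' @param window trailing window length; default 160 stimuli.
#' @return performance in percent.
#' @export
performance <- function(records, window = 160) {
  n <- nrow(records)
  if (n == 0) stop("empty record list")
  if (window > n) stop("window longer than the record list")
  100 * mean(records$correct[(n - window + 1):n])
}

#' Is the nonlinear feature binding problem solved?
#'
#' The task counts as solved when performance strictly exceeds 87.5%,
#' e.g. consistent spiking for one relevant combination plus spiking at
#' least half the time for the other while ignoring irrelevant stimuli.
#'
#' @param perf performance in percent.
#' @return logical.
#' @export
solved_criterion <- function(perf) {
  stopifnot(perf >= 0, perf <= 100)
  perf > 87.5
}

#' Train the model on the feature-binding task
#'
#' Runs the full continuous-learning protocol: for each stimulus of the
#' block-shuffled sequence the model is simulated from baseline over the
#' stimulus plus feedback window with background noise, the somatic spike
#' decision is taken over [onset, onset + reward delay], dopamine feedback
#' is computed, the excitatory rule is applied at reward time to the
#' synapses activated by that stimulus, and the inhibitory rule to every
#' inhibitory synapse.  There is no separate test phase; the rules stay on
#' throughout.  Fully reproducible given `seed`.
#'
#' Between stimuli the model state is reset to baseline: the 800 ms
#' inter-stimulus interval of the protocol is long enough for voltages and
#' calcium pools to decay back to rest (see the package tests for the
#' explicit relaxation check), so the relaxation itself is not simulated.
#'
#' @param model an `spn_model`.
#' @param protocol a [training_protocol()].
#' @param exc_params [exc_plasticity_params()]; its
#'   `metaplasticity_enabled` flag controls the metaplasticity toggle.
#' @param inh_params [inh_plasticity_params()].
#' @param plasticity list of logical flags `exc`, `inh`.
#' @param stimuli stimulus table; defaults to the standard four.
#' @param seed integer seed for all randomness of the run.
#' @param weight_log_every log weights every k stimuli (0 = never).
#' @return an object of class `spn_training`: `records` (per-stimulus
#'   outcome table with running performance), `final` weights and kernel
#'   state, `weight_log` matrices, and the configuration used.
#' @export
run_training <- function(model, protocol = training_protocol(),
                         exc_params = exc_plasticity_params(),
                         inh_params = inh_plasticity_params(),
                         plasticity = list(exc = TRUE, inh = TRUE),
                         stimuli = nfbp_stimuli(), seed = 1,
                         weight_log_every = 20) {
  set.seed(seed)
  seq_idx <- make_stimulus_sequence(protocol, stimuli)
  n <- length(seq_idx)
  n_exc <- nrow(model$exc)
  n_inh <- nrow(model$inh)
  theta_ltp <- rep(exc_params$theta_ltp0, n_exc)
  theta_low <- rep(inh_params$theta_low0, n_inh)
  theta_high <- rep(inh_params$theta_high0, n_inh)
  inh_comp_idx <- if (n_inh > 0) match(model$inh$comp, model$morph$comp$id)
                  else integer(0)
  duration <- protocol$reward_delay + protocol$reward_duration

  rec <- data.frame(stimulus = seq_len(n), id = stimuli$id[seq_idx],
                    relevant = stimuli$relevant[seq_idx], spiked = FALSE,
                    dopamine = 0L, correct = FALSE, performance = NA_real_)
  log_idx <- if (weight_log_every > 0) seq(weight_log_every, n,
                                           by = weight_log_every) else integer(0)
  w_log <- matrix(NA_real_, length(log_idx), n_exc)
  wi_log <- matrix(NA_real_, length(log_idx), n_inh)
  th_log <- matrix(NA_real_, length(log_idx), n_exc)
  li <- 1L

  for (k in seq_len(n)) {
    st <- stimuli[seq_idx[k], ]
    model <- sync_weights(model)
    ev <- stimulus_events(model, st, protocol, duration)
    sim <- simulate_window(model, ev, duration = duration, dt = protocol$dt)
    spiked <- length(sim$spikes) > 0 &&
      any(sim$spikes <= protocol$reward_delay)
    dop <- dopamine_feedback(spiked, st$relevant, protocol$subthreshold_mode)

    if (isTRUE(plasticity$exc)) {
      upd <- apply_excitatory_feedback(model$exc$w, theta_ltp,
                                       sim$ca_nmda_peak, sim$ca_ltype_peak,
                                       attr(ev, "active_exc"), dop,
                                       exc_params)
      model$exc$w <- upd$w
      theta_ltp <- upd$theta_ltp
    }
    if (isTRUE(plasticity$inh) && n_inh > 0) {
      ca_v <- sim$ca_v_peak[inh_comp_idx]
      active <- seq_len(n_inh) %in% attr(ev, "active_inh")
      updi <- apply_inhibitory_update(model$inh$w, theta_low, theta_high,
                                      ca_v, active, inh_params)
      model$inh$w <- updi$w_inh
      theta_low <- updi$theta_low
      theta_high <- updi$theta_high
    }

    rec$spiked[k] <- spiked
    rec$dopamine[k] <- dop
    rec$correct[k] <- (st$relevant && spiked) || (!st$relevant && !spiked)
    if (k >= protocol$window) {
      rec$performance[k] <-
        100 * mean(rec$correct[(k - protocol$window + 1):k])
    }
    if (li <= length(log_idx) && k == log_idx[li]) {
      w_log[li, ] <- model$exc$w
      th_log[li, ] <- theta_ltp
      if (n_inh > 0) wi_log[li, ] <- model$inh$w
      li <- li + 1L
    }
  }

  final_perf <- performance(rec, min(protocol$window, n))
  structure(list(records = rec,
                 final_performance = final_perf,
                 solved = solved_criterion(final_perf),
                 final = list(w = model$exc$w, theta_ltp = theta_ltp,
                              w_inh = model$inh$w, theta_low = theta_low,
                              theta_high = theta_high),
                 weight_log = list(at = log_idx, w = w_log, w_inh = wi_log,
                                   theta_ltp = th_log),
                 config = list(protocol = unclass(protocol),
                               exc_params = unclass(exc_params),
                               inh_params = unclass(inh_params),
                               plasticity = plasticity, seed = seed),
                 model = model),
            class = "spn_training")
}

#' @export
print.spn_training <- function(x, ...) {
  cat("spn_training:", nrow(x$records), "stimuli; final-window performance",
      sprintf("%.1f%%", x$final_performance),
      if (x$solved) "(solved)" else "(not solved)", "\n")
  invisible(x)
}

#' Per-stimulus-type performance over the final window
#'
#' @param training an `spn_training`.
#' @param window trailing window (stimuli).
#' @return data.frame with per-type percent-correct over the window.
#' @export
per_type_performance <- function(training, window = 160) {
  rec <- training$records
  n <- nrow(rec)
  tail_rec <- rec[max(1, n - window + 1):n, ]
  agg <- stats::aggregate(correct ~ id, data = tail_rec, FUN = mean)
  agg$percent <- 100 * agg$correct
  agg[, c("id", "percent")]
}
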