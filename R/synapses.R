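#' Saturating synaptic gate
#'
#' Reference implementation of the saturating activation used by every
#' synapse class: a presynaptic spike opens a transmitter window of length
#' `t_on` during which the gating variable rises exponentially toward 1
#' (never exceeding it); outside the window it decays exponentially.
#' Repeated spikes extend the window and saturate rather than summate.
#'
#' `saturating_gate()` evaluates the gate on a regular grid given spike
#' times; `deliver_presynaptic_spike()` and `advance_gate()` expose the
#' event-driven state machine.
#'
#' @param spike_times presynaptic spike times (ms).
#' @param duration trace length (ms).
#' @param dt grid step (ms).
#' @param tau_rise,tau_decay time constants (ms).
#' @param t_on transmitter-on window (ms); default twice `tau_rise`.
#' @return numeric gating trace on `seq(0, duration, by = dt)`.
#' @export
saturating_gate <- function(spike_times, duration, dt = 0.1,
                            tau_rise = 3, tau_decay = 70,
                            t_on = 2 * tau_rise) {
  st <- gate_state(tau_rise, tau_decay, t_on)
  tg <- seq(0, duration, by = dt)
  out <- numeric(length(tg))
  spike_times <- sort(spike_times)
  for (i in seq_along(tg)) {
    while (length(spike_times) && spike_times[1] <= tg[i]) {
      st <- deliver_presynaptic_spike(st, spike_times[1])
      spike_times <- spike_times[-1]
    }
    st <- advance_gate(st, tg[i])
    out[i] <- st$s
  }
  out
}

#' @rdname saturating_gate
#' @export
gate_state <- function(tau_rise = 3, tau_decay = 70, t_on = 2 * tau_rise) {
  list(s = 0, time = 0, on_until = -Inf,
       tau_rise = tau_rise, tau_decay = tau_decay, t_on = t_on)
}

#' @rdname saturating_gate
#' @param state a gate state from [gate_state()].
#' @param t event time (ms), not before `state$time`.
#' @export
deliver_presynaptic_spike <- function(state, t) {
  state <- advance_gate(state, t)
  state$on_until <- t + state$t_on
  state
}

#' @rdname saturating_gate
#' @param t_to time to advance to (ms).
#' @export
advance_gate <- function(state, t_to) {
  t <- state$time
  if (t_to < t - 1e-12) stop("cannot advance a gate backwards in time")
  if (t < state$on_until) {
    t1 <- min(t_to, state$on_until)
    state$s <- 1 - (1 - state$s) * exp(-(t1 - t) / state$tau_rise)
    t <- t1
  }
  if (t_to > t) state$s <- state$s * exp(-(t_to - t) / state$tau_decay)
  state$time <- t_to
  state
}

#' Magnesium block and NMDA current
#'
#' `mg_block()` is the sigmoidal voltage dependence of NMDA-receptor
#' unblock (Jahr-Stevens form, 1 mM Mg, slope 0.062/mV, half-unblock near
#' -20 mV), increasing in V and bounded in (0, 1).  `nmda_current()`
#' returns the NMDA current `I = w * g_max * gating * B(V) * (V - E)` with
#' E = 0 mV, in nA (negative = inward).
#'
#' @param v membrane potential (mV).
#' @return `mg_block`: unblock fraction in (0, 1).
#' @export
mg_block <- function(v) {
  1 / (1 + exp(-0.062 * v) / 3.57)
}

#' @rdname mg_block
#' @param gating dimensionless gating in [0, 1].
#' @param w dimensionless synaptic weight.
#' @param gmax maximal conductance (uS).
#' @export
nmda_current <- function(v, gating, w, gmax = 2.5e-3) {
  stopifnot(all(is.finite(v)))
  w * gmax * gating * mg_block(v) * (v - 0)
}

#' Glutamate-spillover trigger
#'
#' Spillover of glutamate onto slow extrasynaptic NMDA receptors is
#' triggered when the summed weight of co-active excitatory synapses in a
#' pooling unit (a synaptic cluster, or a whole dendritic branch in the
#' distributed mode) reaches the threshold of 2.  The comparison is
#' inclusive: eight co-activated synapses of weight 0.25 trigger exactly.
#'
#' @param weights weight vector of the unit's synapses.
#' @param active indices (or logical mask) of co-active synapses.
#' @param threshold trigger threshold (weight sum).
#' @return logical: does the active set trigger spillover?
#' @export
check_spillover <- function(weights, active, threshold = 2) {
  sum(weights[active]) >= threshold - 1e-12
}

#' Per-unit spillover weight sums for an active synapse set
#'
#' Pure arithmetic mirror of the trigger rule applied during simulation:
#' groups the model's excitatory synapses into its spillover units (cluster
#' or branch pooling, per `model$spill_mode`) and reports the active weight
#' sum and trigger flag per unit.
#'
#' @param model an `spn_model`.
#' @param active_ids excitatory synapse ids counted as co-active.
#' @return data.frame with unit id, weight sum and `triggered`.
#' @export
spillover_weight_sums <- function(model, active_ids) {
  exc <- model$exc
  stopifnot(all(active_ids %in% exc$id))
  if (model$spill_mode == "cluster") {
    grp <- exc$cluster
  } else {
    grp <- exc$dendrite
  }
  units <- sort(unique(grp[!is.na(grp)]))
  act <- exc$id %in% active_ids
  sums <- vapply(units, function(u)
    sum(exc$w[act & !is.na(grp) & grp == u]), numeric(1))
  data.frame(unit = units, wsum = sums,
             triggered = sums >= model$syn$spill_threshold - 1e-12)
}

#' Generate background-noise event trains
#'
#' Homogeneous Poisson event trains for the fixed-weight background
#' synapses that keep the membrane fluctuating in an in-vivo-like range.
#' Deterministic given the R random seed in force.
#'
#' @param rate event rate (Hz).
#' @param duration window (ms).
#' @param n number of independent trains.
#' @return list of `n` numeric vectors of event times (ms).
#' @export
generate_background_noise <- function(rate, duration, n = 1) {
  stopifnot(rate >= 0, duration > 0)
  lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, rate * duration / 1000)
    sort(stats::runif(k, 0, duration))
  })
}

#' Presynaptic events for one stimulus presentation
#'
#' Builds the event matrix consumed by [simulate_window()]: every
#' excitatory synapse whose feature belongs to the stimulus receives one
#' spike uniformly in the 20 ms stimulus window; feature-unspecific
#' synapses one spike in their 50 ms window; inhibitory synapses of the
#' stimulus features one spike in their 100 ms window; and the
#' background-noise synapses receive Poisson events over the whole window.
#' Times are drawn from the R random stream in force.
#'
#' @param model an `spn_model`.
#' @param stimulus a row of [nfbp_stimuli()] (or any list with `color`,
#'   `shape`).
#' @param protocol a [training_protocol()].
#' @param duration simulated window (ms); defaults to stimulus + feedback.
#' @return two-column matrix (time, synapse row) plus an
#'   `active_exc`/`active_inh` attribute with the stimulated synapse ids.
#' @export
stimulus_events <- function(model, stimulus, protocol = training_protocol(),
                            duration = NULL) {
  if (is.null(duration)) {
    duration <- protocol$reward_delay + protocol$reward_duration
  }
  m <- model$pack$map
  feats <- c(stimulus$color, stimulus$shape)
  exc_f <- which(model$exc$feature %in% feats)
  exc_u <- which(model$exc$feature == "unspecific")
  t_f <- stats::runif(length(exc_f), 0, protocol$stimulus_duration)
  t_u <- stats::runif(length(exc_u), 0, protocol$unspecific_window)
  act <- c(exc_f, exc_u)
  tt <- c(t_f, t_u)
  ev <- cbind(c(tt, tt), c(m$ampa[act], m$nmda[act]))
  inh_a <- integer(0)
  if (nrow(model$inh) > 0) {
    inh_a <- which(model$inh$feature %in% feats)
    if (length(inh_a)) {
      ti <- stats::runif(length(inh_a), 0, protocol$inhibitory_window)
      ev <- rbind(ev, cbind(ti, m$gaba[inh_a]))
    }
  }
  if (model$noise && m$n_noise > 0) {
    ne <- generate_background_noise(model$syn$noise_rate_exc, duration,
                                    m$n_noise)
    ni <- generate_background_noise(model$syn$noise_rate_inh, duration,
                                    m$n_noise)
    kn <- lengths(ne)
    ki <- lengths(ni)
    ev <- rbind(ev,
                cbind(unlist(ne), rep(m$noise_exc, kn)),
                cbind(unlist(ni), rep(m$noise_inh, ki)))
  }
  colnames(ev) <- c("time", "row")
  attr(ev, "active_exc") <- act
  attr(ev, "active_inh") <- inh_a
  ev
}
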