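#' Sigmoid and its derivative over the calcium axis
#'
#' `ca_sigmoid()` maps a calcium concentration into (0, 1):
#' `1 / (1 + exp(-beta (ca - theta)))`, numerically stable for arbitrarily
#' large `|beta (ca - theta)|`.  Its derivative `ca_sigmoid_deriv()`,
#' `beta * s * (1 - s)`, is the bell-shaped LTP kernel: maximal (`beta/4`)
#' at the midpoint `theta` and symmetric about it.
#'
#' @param ca calcium concentration (mM), vectorized.
#' @param theta midpoint (mM).
#' @param beta steepness (per mM).
#' @return sigmoid value in (0, 1), or its derivative (per mM).
#' @export
ca_sigmoid <- function(ca, theta, beta) {
  stats::plogis(beta * (ca - theta))
}

#' @rdname ca_sigmoid
#' @export
ca_sigmoid_deriv <- function(ca, theta, beta) {
  s <- stats::plogis(beta * (ca - theta))
  beta * s * (1 - s)
}

#' LTP weight increment
#'
#' Weight change applied to an active synapse on a dopamine peak: the
#' bell-shaped kernel evaluated at the per-stimulus peak NMDA calcium,
#' scaled by the LTP rate, the feedback duration and the global rate
#' factor.  Always non-negative; the caller adds it to `w` and clamps at
#' the weight cap.
#'
#' @param ca_nmda_peak peak NMDA-pool calcium since stimulus onset (mM).
#' @param theta_ltp current LTP-kernel midpoint(s) (mM).
#' @param params [exc_plasticity_params()].
#' @return non-negative weight increment(s).
#' @export
ltp_delta <- function(ca_nmda_peak, theta_ltp, params) {
  if (any(ca_nmda_peak < 0)) stop("negative calcium")
  params$eta_ltp * ca_sigmoid_deriv(ca_nmda_peak, theta_ltp, params$beta_ltp) *
    params$feedback_duration * params$rate_factor
}

#' LTD weight decrement
#'
#' Weight change applied to an active synapse on a dopamine pause: above
#' the fixed 70 nM threshold (implemented as a near-step sigmoid) the
#' decrement grows linearly with the peak L-type calcium and
#' multiplicatively with the current weight, so zero weights cannot go
#' negative.  Always non-negative; the caller subtracts it and floors at 0.
#'
#' @param ca_ltype_peak peak L-type calcium since stimulus onset (mM).
#' @param w current weight(s).
#' @param params [exc_plasticity_params()].
#' @return non-negative weight decrement(s).
#' @export
ltd_delta <- function(ca_ltype_peak, w, params) {
  if (any(ca_ltype_peak < 0)) stop("negative calcium")
  params$eta_ltd * ca_ltype_peak *
    ca_sigmoid(ca_ltype_peak, params$theta_ltd, params$beta_ltd) * w *
    params$feedback_duration * params$rate_factor
}

#' Metaplasticity shift of the LTP-kernel midpoint
#'
#' After each dopamine event the LTP kernel slides along the calcium axis:
#' downward (toward the observed calcium) after a peak, upward after a
#' pause, with the pause shift four times faster.  The shift magnitude is
#' a wider bell-shaped kernel (`beta_mp`) sharing the LTP midpoint, so
#' both kernels stay centred on the same calcium level.
#'
#' @param ca_nmda_peak peak NMDA calcium since stimulus onset (mM).
#' @param theta_ltp current midpoint(s) (mM).
#' @param dopamine +1 (peak) or -1 (pause).
#' @param params [exc_plasticity_params()].
#' @return signed midpoint change (mM): negative for a peak, positive for
#'   a pause; zero if metaplasticity is disabled.
#' @export
metaplasticity_shift <- function(ca_nmda_peak, theta_ltp, dopamine, params) {
  if (dopamine == 0) return(rep(0, length(ca_nmda_peak)))
  if (!params$metaplasticity_enabled) return(rep(0, length(ca_nmda_peak)))
  eta_s <- if (dopamine > 0) params$eta_s_ltp else params$eta_s_ltd
  mag <- eta_s * ca_sigmoid_deriv(ca_nmda_peak, theta_ltp, params$beta_mp) *
    params$feedback_duration * params$rate_factor
  if (dopamine > 0) -mag else mag
}

#' Apply one excitatory feedback event
#'
#' Dispatches the excitatory rule once per stimulus at reward-cue time
#' (Algorithm: dopamine +1 applies LTP and the downward kernel shift;
#' -1 applies LTD and the upward shift; 0 changes nothing).  Only synapses
#' that received a presynaptic spike during the stimulus are eligible.
#' Weights are kept in [0, w_cap] and kernel midpoints strictly positive.
#'
#' @param w weight vector (all excitatory synapses).
#' @param theta_ltp kernel midpoint vector (mM).
#' @param ca_nmda_peak,ca_ltype_peak per-synapse peak calcium since
#'   stimulus onset (mM).
#' @param active indices (or logical mask) of synapses stimulated during
#'   this stimulus.
#' @param dopamine dopamine level in {-1, 0, +1}.
#' @param params [exc_plasticity_params()].
#' @return list with updated `w` and `theta_ltp`.
#' @export
apply_excitatory_feedback <- function(w, theta_ltp, ca_nmda_peak,
                                      ca_ltype_peak, active, dopamine,
                                      params) {
  stopifnot(dopamine %in% c(-1, 0, 1))
  if (dopamine == 0 || length(active) == 0) {
    return(list(w = w, theta_ltp = theta_ltp))
  }
  a <- active
  if (dopamine > 0) {
    w[a] <- pmin(w[a] + ltp_delta(ca_nmda_peak[a], theta_ltp[a], params),
                 params$w_cap)
  } else {
    w[a] <- pmax(w[a] - ltd_delta(ca_ltype_peak[a], w[a], params), 0)
  }
  theta_ltp[a] <- pmax(theta_ltp[a] +
                         metaplasticity_shift(ca_nmda_peak[a], theta_ltp[a],
                                              dopamine, params), 1e-6)
  list(w = w, theta_ltp = theta_ltp)
}
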