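#' Two-sigmoid Omega function of the inhibitory rule
#'
#' `Omega(ca) = a * sigma(ca - theta_low) + b * sigma(ca - theta_high)`
#' with shared steepness `beta`.  With the weight-update coefficients
#' (a = -1, b = 3) it is ~0 below the lower threshold, ~-1 between the
#' thresholds and ~2 above the upper threshold, defining the depression/
#' potentiation zones of the BCM-style rule.
#'
#' @param ca calcium concentration (mM), vectorized.
#' @param theta_low,theta_high sliding thresholds (mM).
#' @param a,b sigmoid coefficients.
#' @param beta steepness (per mM).
#' @return dimensionless Omega value(s).
#' @export
omega <- function(ca, theta_low, theta_high, a = -1, b = 3, beta = 2.5e3) {
  a * stats::plogis(beta * (ca - theta_low)) +
    b * stats::plogis(beta * (ca - theta_high))
}

#' Inhibitory weight update
#'
#' Signed weight change of one inhibitory synapse for a stimulus, from the
#' peak all-VGCC calcium at its dendritic-shaft site.  Synapses active
#' during the stimulus use the negative rate (so calcium between the
#' thresholds, where Omega is about -1, potentiates; calcium above the
#' upper threshold depresses); inactive synapses use the positive rate and
#' mirror the pattern.  The soft-bound factor `w (w_max - w)` freezes
#' weights exactly at both bounds.
#'
#' @param ca_v_peak peak all-VGCC calcium since stimulus onset (mM).
#' @param w_inh current weight (uS).
#' @param active logical: did the synapse receive a presynaptic event
#'   during the stimulus window?
#' @param theta_low,theta_high current thresholds (mM).
#' @param params [inh_plasticity_params()].
#' @return signed weight change (uS); caller clamps to [0, w_inh_max].
#' @export
inh_weight_delta <- function(ca_v_peak, w_inh, active, theta_low, theta_high,
                             params) {
  eta <- ifelse(active, -params$eta_act, params$eta_act) * params$rate_factor
  eta * omega(ca_v_peak, theta_low, theta_high, params$a_inh, params$b_inh,
              params$beta_inh) *
    w_inh * (params$w_inh_max - w_inh) * params$update_window
}

#' Sliding-threshold updates of the inhibitory rule
#'
#' The upper threshold shifts toward the highest observed calcium level
#' (its Omega coefficients make the update positive above `theta_high` and
#' negative between the thresholds); the lower threshold tracks a level
#' below the maximum, with the calcium offset `c_offset` placing the zero
#' crossing of its update where the upper-threshold update also vanishes.
#'
#' @param ca_v_peak peak all-VGCC calcium since stimulus onset (mM).
#' @param theta_low,theta_high current thresholds (mM).
#' @param params [inh_plasticity_params()].
#' @return threshold change (mM).
#' @export
update_theta_high <- function(ca_v_peak, theta_low, theta_high, params) {
  params$eta_inh_high * params$rate_factor *
    omega(ca_v_peak, theta_low, theta_high, params$a_inh_high,
          params$b_inh_high, params$beta_inh) * params$update_window
}

#' @rdname update_theta_high
#' @export
update_theta_low <- function(ca_v_peak, theta_low, theta_high, params) {
  params$eta_inh_low * params$rate_factor *
    omega(ca_v_peak + params$c_offset, theta_low, theta_high,
          params$a_inh_low, params$b_inh_low, params$beta_inh) *
    params$update_window
}

#' Apply the inhibitory rule after one stimulus
#'
#' Updates every inhibitory synapse (active or inactive branch — unlike
#' the excitatory rule there is no eligibility restriction and no dopamine
#' dependence): first the weight via [inh_weight_delta()], then both
#' sliding thresholds.  A guard keeps `theta_low <= theta_high - eps` by
#' clipping the lower threshold, and both thresholds strictly positive.
#'
#' @param w_inh weight vector (uS).
#' @param theta_low,theta_high threshold vectors (mM).
#' @param ca_v_peak per-synapse peak all-VGCC calcium at the synapse's
#'   shaft site (mM).
#' @param active logical vector: received an event during this stimulus.
#' @param params [inh_plasticity_params()].
#' @return list with updated `w_inh`, `theta_low`, `theta_high`.
#' @export
apply_inhibitory_update <- function(w_inh, theta_low, theta_high, ca_v_peak,
                                    active, params) {
  if (length(w_inh) == 0) {
    return(list(w_inh = w_inh, theta_low = theta_low,
                theta_high = theta_high))
  }
  dw <- inh_weight_delta(ca_v_peak, w_inh, active, theta_low, theta_high,
                         params)
  w_inh <- pmin(pmax(w_inh + dw, 0), params$w_inh_max)
  th <- theta_high + update_theta_high(ca_v_peak, theta_low, theta_high,
                                       params)
  tl <- theta_low + update_theta_low(ca_v_peak, theta_low, theta_high,
                                     params)
  th <- pmax(th, params$guard_eps * 2)
  tl <- pmax(pmin(tl, th - params$guard_eps), 1e-7)
  list(w_inh = w_inh, theta_low = tl, theta_high = th)
}
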