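#' Excitatory plasticity parameters
#'
#' Parameter set for the dopamine-gated excitatory rule: the bell-shaped LTP
#' kernel (derivative of a sigmoid over the NMDA-calcium axis), the
#' thresholded linear LTD rule driven by L-type calcium, and the sliding
#' metaplasticity kernel that moves the LTP midpoint after each feedback
#' event.
#'
#' Weight updates are event-based: once per reward cue, using the peak
#' calcium since stimulus onset, scaled by the 50 ms feedback duration and a
#' single global `rate_factor` that compresses learning into shortened
#' training runs while keeping all rate ratios fixed.
#'
#' @param eta_ltp LTP learning rate (weight units per mM per ms).
#' @param theta_ltp0 initial LTP-kernel midpoint (mM).
#' @param beta_ltp LTP-kernel steepness (per mM); controls kernel width.
#' @param eta_ltd LTD learning rate (per ms per mM).
#' @param theta_ltd fixed LTD calcium threshold (mM); 70 nM.
#' @param beta_ltd LTD threshold steepness (per mM); large, so the sigmoid
#'   approximates a step.
#' @param eta_s_ltp metaplasticity shift rate after a dopamine peak
#'   (mM^2/ms).
#' @param eta_s_ltd metaplasticity shift rate after a dopamine pause; four
#'   times `eta_s_ltp` (loss-averse asymmetry).
#' @param beta_mp metaplasticity-kernel steepness (per mM); smaller than
#'   `beta_ltp`, i.e. a wider kernel sharing the same midpoint.
#' @param feedback_duration duration of the reward cue (ms).
#' @param w_cap hard ceiling on the dimensionless weight.
#' @param rate_factor global multiplier on all four learning rates.
#' @param metaplasticity_enabled logical; disable to freeze the kernel
#'   midpoint (control experiment).
#' @return a list of class `exc_plasticity_params`.
#' @export
exc_plasticity_params <- function(eta_ltp = 1.5e-5,
                                  theta_ltp0 = 0.02,
                                  beta_ltp = 1.0e3,
                                  eta_ltd = 3e-3,
                                  theta_ltd = 7e-5,
                                  beta_ltd = 1.0e5,
                                  eta_s_ltp = 1e-7,
                                  eta_s_ltd = 4e-7,
                                  beta_mp = 334,
                                  feedback_duration = 50,
                                  w_cap = 1.0,
                                  rate_factor = 1.0,
                                  metaplasticity_enabled = TRUE) {
  stopifnot(eta_ltp >= 0, eta_ltd >= 0, eta_s_ltp >= 0, eta_s_ltd >= 0,
            theta_ltp0 > 0, beta_mp < beta_ltp, w_cap > 0, rate_factor > 0)
  structure(list(eta_ltp = eta_ltp, theta_ltp0 = theta_ltp0,
                 beta_ltp = beta_ltp, eta_ltd = eta_ltd,
                 theta_ltd = theta_ltd, beta_ltd = beta_ltd,
                 eta_s_ltp = eta_s_ltp, eta_s_ltd = eta_s_ltd,
                 beta_mp = beta_mp, feedback_duration = feedback_duration,
                 w_cap = w_cap, rate_factor = rate_factor,
                 metaplasticity_enabled = metaplasticity_enabled),
            class = "exc_plasticity_params")
}

#' Inhibitory plasticity parameters
#'
#' Parameter set for the BCM-style calcium-threshold rule on GABAergic
#' synapses: the two-sigmoid Omega function with sliding thresholds
#' `theta_inh_low` / `theta_inh_high`, soft weight bounds, and no dopamine
#' dependence.
#'
#' @param beta_inh steepness of both sigmoids (per mM).
#' @param eta_act learning-rate magnitude; applied with negative sign for
#'   synapses active during the stimulus and positive sign for inactive ones
#'   (per uS per ms).
#' @param a_inh,b_inh Omega coefficients for the weight update.
#' @param w_inh_max maximum inhibitory conductance (uS).
#' @param eta_inh_high,a_inh_high,b_inh_high rate and Omega coefficients for
#'   the upper-threshold update (mM/ms).
#' @param eta_inh_low,a_inh_low,b_inh_low rate and Omega coefficients for
#'   the lower-threshold update (mM/ms).
#' @param c_offset calcium offset added in the lower-threshold update so the
#'   two threshold-update curves intersect at zero (mM).
#' @param update_window per-stimulus event window equivalent (ms), mirroring
#'   the excitatory feedback duration.
#' @param theta_low0,theta_high0 initial thresholds (mM).
#' @param guard_eps minimum separation kept between the two thresholds (mM).
#' @param rate_factor global multiplier shared with the excitatory rule.
#' @return a list of class `inh_plasticity_params`.
#' @export
inh_plasticity_params <- function(beta_inh = 2.5e3,
                                  eta_act = 0.055,
                                  a_inh = -1, b_inh = 3,
                                  w_inh_max = 0.005,
                                  eta_inh_high = 9e-4,
                                  a_inh_high = -1, b_inh_high = 3,
                                  eta_inh_low = -5e-5,
                                  a_inh_low = -2, b_inh_low = 3,
                                  c_offset = 6e-4,
                                  update_window = 50,
                                  theta_low0 = 1e-4,
                                  theta_high0 = 5e-4,
                                  guard_eps = 1e-5,
                                  rate_factor = 1.0) {
  stopifnot(w_inh_max > 0, theta_low0 > 0, theta_high0 > theta_low0,
            eta_act >= 0, rate_factor > 0)
  structure(list(beta_inh = beta_inh, eta_act = eta_act,
                 a_inh = a_inh, b_inh = b_inh, w_inh_max = w_inh_max,
                 eta_inh_high = eta_inh_high, a_inh_high = a_inh_high,
                 b_inh_high = b_inh_high, eta_inh_low = eta_inh_low,
                 a_inh_low = a_inh_low, b_inh_low = b_inh_low,
                 c_offset = c_offset, update_window = update_window,
                 theta_low0 = theta_low0, theta_high0 = theta_high0,
                 guard_eps = guard_eps, rate_factor = rate_factor),
            class = "inh_plasticity_params")
}

#' Synapse model parameters
#'
#' Kinetic and conductance constants for the saturating AMPA/NMDA synapses
#' on spines, the slow extrasynaptic NMDA (glutamate spillover) units on
#' dendritic shafts, GABA synapses, and the fixed-weight background-noise
#' synapses.  The dimensionless weight `w` scales AMPA and NMDA maximal
#' conductances together; `w = 0.25` corresponds to 0.625 nS of NMDA
#' conductance.  The spillover threshold is a weight sum of 2 per cluster
#' (or per branch in the distributed mode), compared inclusively.
#'
#' @param gmax_ampa maximal AMPA conductance at `w = 1` (uS).
#' @param gmax_nmda maximal synaptic NMDA conductance at `w = 1` (uS).
#' @param gmax_extrasyn maximal extrasynaptic NMDA conductance (uS), not
#'   scaled by `w`.
#' @param spill_threshold weight sum of co-active synapses needed to trigger
#'   spillover (inclusive comparison).
#' @param tau_ampa,tau_nmda,tau_extrasyn,tau_gaba rise/decay time-constant
#'   pairs (ms).  The transmitter-on window of each saturating gate is twice
#'   its rise constant.
#' @param e_gaba GABA reversal potential (mV).
#' @param noise_g_exc,noise_g_inh fixed conductances of the per-compartment
#'   background-noise synapses (uS).
#' @param noise_rate_exc,noise_rate_inh Poisson event rates per dendritic
#'   compartment (Hz).
#' @return a list of class `synapse_params`.
#' @export
synapse_params <- function(gmax_ampa = 1.0e-3,
                           gmax_nmda = 2.5e-3,
                           gmax_extrasyn = 2.5e-3,
                           spill_threshold = 2.0,
                           tau_ampa = c(0.5, 5),
                           tau_nmda = c(3, 70),
                           tau_extrasyn = c(10, 300),
                           tau_gaba = c(0.5, 10),
                           e_gaba = -60,
                           noise_g_exc = 0.1e-3,
                           noise_g_inh = 0.2e-3,
                           noise_rate_exc = 8.0,
                           noise_rate_inh = 2.0) {
  stopifnot(gmax_ampa >= 0, gmax_nmda >= 0, gmax_extrasyn > 0,
            spill_threshold > 0, noise_rate_exc >= 0, noise_rate_inh >= 0)
  structure(list(gmax_ampa = gmax_ampa, gmax_nmda = gmax_nmda,
                 gmax_extrasyn = gmax_extrasyn,
                 spill_threshold = spill_threshold,
                 tau_ampa = tau_ampa, tau_nmda = tau_nmda,
                 tau_extrasyn = tau_extrasyn, tau_gaba = tau_gaba,
                 e_gaba = e_gaba, noise_g_exc = noise_g_exc,
                 noise_g_inh = noise_g_inh,
                 noise_rate_exc = noise_rate_exc,
                 noise_rate_inh = noise_rate_inh),
            class = "synapse_params")
}

#' Calcium pool and voltage-gated channel parameters
#'
#' Three separated pools are tracked per synapse site: NMDA-evoked calcium
#' in each spine, L-type calcium in each spine, and calcium from all
#' voltage-gated channels at dendritic-shaft sites.  Each pool has influx
#' scaling, Michaelis-Menten pump extrusion and first-order decay; there is
#' no spatial diffusion between pools.  The T/R/N/L channel families are
#' collapsed into low-voltage-activated (LVA) and high-voltage-activated
#' (HVA) surrogate conductances; a fixed fraction of the HVA current is the
#' L-type share feeding the L-type pool.
#'
#' The influx scales (`phi_*`) are calibration outputs of
#' [calibrate_calcium()]: the millimolar scale of each pool is anchored to
#' the plasticity-rule constants (LTP midpoint 0.02 mM, LTD threshold
#' 7e-5 mM) rather than to absolute channel flux.
#'
#' @param phi_nmda NMDA-pool influx scale (mM per nA ms); the NMDA calcium
#'   influx is a fixed 10 percent fraction of the NMDA current, folded into
#'   this factor.
#' @param phi_ltype,phi_v influx scales of the L-type and all-VGCC pools.
#' @param tau_nmda,tau_ltype,tau_v pool decay constants (ms).
#' @param pump_vmax_nmda,pump_vmax_ltype,pump_vmax_v calcium-pump maximum
#'   rates per pool (mM/ms).  The L-type pump is deliberately strong
#'   relative to sub-threshold influx: it saturates under plateau-level
#'   influx but clears weaker transients, which sharpens the contrast
#'   between plateau and non-plateau trials around the 70 nM LTD threshold.
#' @param pump_km pump affinity (mM), shared across pools.
#' @param base_v resting level of the all-VGCC shaft pool (mM); the two
#'   spine pools represent stimulus-evoked increments and decay to 0.
#' @param g_lva_dens,g_hva_dens surrogate channel densities (mS/cm2) on
#'   dendritic shafts; spine heads use `spine_vgcc_factor` times these.
#' @param spine_vgcc_factor density multiplier for spine heads.
#' @param lva_vh,lva_k,lva_tau LVA Boltzmann midpoint (mV), slope (mV) and
#'   activation time constant (ms); LVA activates at least 10 mV more
#'   negative than HVA.
#' @param hva_vh,hva_k,hva_tau HVA activation parameters.
#' @param e_ca calcium reversal used for the ohmic driving force (mV).
#' @param frac_l L-type fraction of the HVA conductance.
#' @return a list of class `calcium_params`.
#' @export
calcium_params <- function(phi_nmda = 0.0282,
                           phi_ltype = 6.31,
                           phi_v = 0.225,
                           tau_nmda = 50,
                           tau_ltype = 80,
                           tau_v = 80,
                           pump_vmax_nmda = 1e-6,
                           pump_vmax_ltype = 2e-3,
                           pump_vmax_v = 1e-6,
                           pump_km = 5e-4,
                           base_v = 5e-5,
                           g_lva_dens = 0.3,
                           g_hva_dens = 0.6,
                           spine_vgcc_factor = 10,
                           lva_vh = -55, lva_k = 6, lva_tau = 5,
                           hva_vh = -40, hva_k = 6, hva_tau = 2,
                           e_ca = 30, frac_l = 0.5) {
  stopifnot(hva_vh - lva_vh >= 10, frac_l >= 0, frac_l <= 1,
            tau_nmda > 0, tau_ltype > 0, tau_v > 0)
  structure(list(phi_nmda = phi_nmda, phi_ltype = phi_ltype, phi_v = phi_v,
                 tau_nmda = tau_nmda, tau_ltype = tau_ltype, tau_v = tau_v,
                 pump_vmax_nmda = pump_vmax_nmda,
                 pump_vmax_ltype = pump_vmax_ltype,
                 pump_vmax_v = pump_vmax_v,
                 pump_km = pump_km, base_v = base_v,
                 g_lva_dens = g_lva_dens, g_hva_dens = g_hva_dens,
                 spine_vgcc_factor = spine_vgcc_factor,
                 lva_vh = lva_vh, lva_k = lva_k, lva_tau = lva_tau,
                 hva_vh = hva_vh, hva_k = hva_k, hva_tau = hva_tau,
                 e_ca = e_ca, frac_l = frac_l),
            class = "calcium_params")
}

#' Membrane and spike-mechanism parameters
#'
#' Passive cable constants plus the inward-rectifier (KIR) conductance that
#' holds the surrogate at the hyperpolarized resting potential typical of
#' striatal projection neurons, and the somatic spike mechanism: threshold
#' detection with reset and a stereotyped back-propagating depolarization
#' whose amplitude decays exponentially with somatic distance.
#'
#' @param cm specific membrane capacitance (uF/cm2).
#' @param ra axial resistivity (ohm cm).
#' @param g_pas passive leak density (mS/cm2).
#' @param e_pas leak reversal (mV).
#' @param g_kir_dens KIR density (mS/cm2); the KIR activation is an
#'   instantaneous Boltzmann that closes with depolarization, boosting
#'   plateau potentials.
#' @param e_k potassium reversal (mV).
#' @param kir_vh,kir_k KIR half-activation (mV) and slope (mV).
#' @param spike_threshold somatic spike-detection threshold (mV).
#' @param v_reset somatic after-spike reset (mV).
#' @param refractory minimum spike separation (ms).
#' @param bap_amp back-propagating depolarization amplitude at the soma
#'   boundary (mV).
#' @param bap_lambda exponential length constant of bAP attenuation (um).
#' @param ahp_inc after-spike adaptation: somatic K conductance added per
#'   spike (uS); lumped stand-in for the strong somatic K currents that
#'   limit up-state firing in these neurons.
#' @param ahp_tau decay constant of the adaptation conductance (ms).
#' @param spine_neck_r spine neck resistance (Mohm).
#' @param spine_head_area spine head membrane area (um2).
#' @param soma_l,soma_diam somatic cylinder geometry (um).
#' @return a list of class `membrane_params`.
#' @export
membrane_params <- function(cm = 1.0,
                            ra = 80,
                            g_pas = 0.08,
                            e_pas = -80,
                            g_kir_dens = 0.25,
                            e_k = -90,
                            kir_vh = -80, kir_k = 12,
                            spike_threshold = -40,
                            v_reset = -65,
                            refractory = 10,
                            bap_amp = 25,
                            bap_lambda = 120,
                            ahp_inc = 0.01,
                            ahp_tau = 80,
                            spine_neck_r = 500,
                            spine_head_area = 1.0,
                            soma_l = 16, soma_diam = 16) {
  stopifnot(cm > 0, ra > 0, g_pas >= 0, spine_neck_r > 0,
            spine_head_area > 0, refractory >= 0)
  structure(list(cm = cm, ra = ra, g_pas = g_pas, e_pas = e_pas,
                 g_kir_dens = g_kir_dens, e_k = e_k,
                 kir_vh = kir_vh, kir_k = kir_k,
                 spike_threshold = spike_threshold, v_reset = v_reset,
                 refractory = refractory, bap_amp = bap_amp,
                 bap_lambda = bap_lambda, ahp_inc = ahp_inc,
                 ahp_tau = ahp_tau, spine_neck_r = spine_neck_r,
                 spine_head_area = spine_head_area,
                 soma_l = soma_l, soma_diam = soma_diam),
            class = "membrane_params")
}

#' Training protocol for the nonlinear feature binding task
#'
#' Timing and sequencing constants of the training procedure: 20 ms
#' stimuli with one randomly timed spike per stimulus-related synapse,
#' feature-unspecific input over a 50 ms window, inhibitory input within a
#' 100 ms window, a 50 ms reward cue arriving 300 ms after stimulus onset,
#' 800 ms between stimuli, and block-shuffled stimulus order (each of the
#' four feature combinations three times per block of 12).
#'
#' @param n_stimuli number of training stimuli; rounded down to a whole
#'   number of blocks with a warning if needed.
#' @param stimulus_duration stimulus window (ms).
#' @param unspecific_window activation window of feature-unspecific
#'   synapses (ms).
#' @param inhibitory_window activation window of inhibitory synapses (ms).
#' @param reward_delay delay from stimulus onset to the reward cue (ms).
#' @param reward_duration duration of the reward cue (ms).
#' @param inter_stimulus_interval time between stimulus onsets minus the
#'   stimulus itself (ms); long enough for all state to return to baseline.
#' @param block_size stimuli per shuffled block.
#' @param window trailing window length (stimuli) for the performance
#'   metric.
#' @param subthreshold_mode logical; deliver dopamine feedback even without
#'   somatic spiking.
#' @param dt integration step for training simulations (ms).
#' @return a list of class `training_protocol`.
#' @export
training_protocol <- function(n_stimuli = 960,
                              stimulus_duration = 20,
                              unspecific_window = 50,
                              inhibitory_window = 100,
                              reward_delay = 300,
                              reward_duration = 50,
                              inter_stimulus_interval = 800,
                              block_size = 12,
                              window = 160,
                              subthreshold_mode = FALSE,
                              dt = 0.5) {
  stopifnot(n_stimuli >= block_size, block_size %% 4 == 0,
            dt >= 0.01, dt <= 0.5)
  if (n_stimuli %% block_size != 0) {
    n_stimuli <- (n_stimuli %/% block_size) * block_size
    warning("n_stimuli rounded down to a whole number of blocks: ", n_stimuli)
  }
  structure(list(n_stimuli = n_stimuli,
                 stimulus_duration = stimulus_duration,
                 unspecific_window = unspecific_window,
                 inhibitory_window = inhibitory_window,
                 reward_delay = reward_delay,
                 reward_duration = reward_duration,
                 inter_stimulus_interval = inter_stimulus_interval,
                 block_size = block_size, window = window,
                 subthreshold_mode = subthreshold_mode, dt = dt),
            class = "training_protocol")
}
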