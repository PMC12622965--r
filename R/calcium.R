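#' Single calcium-pool update
#'
#' Reference integrator for one calcium pool:
#' `d[Ca]/dt = phi * I - vmax * e/(e + km) - ([Ca] - base)/tau` with
#' `e = max([Ca] - base, 0)`, i.e. influx proportional to the (inward)
#' calcium current, Michaelis-Menten pump extrusion of the evoked calcium
#' above baseline (so the baseline is an exact fixed point), and
#' first-order decay to baseline, with the concentration floored at zero.  The simulation core applies exactly this
#' update per step; this function is the stand-alone oracle used in tests
#' and for exploring pool kinetics.
#'
#' @param ca current concentration (mM).
#' @param influx_current calcium current magnitude (nA, inward positive
#'   here); may be a vector giving the current at each step.
#' @param dt step (ms).
#' @param phi influx scale (mM per nA ms).
#' @param vmax,km pump maximum rate (mM/ms) and affinity (mM).
#' @param tau decay constant (ms).
#' @param base baseline concentration (mM).
#' @return concentration trace (mM), one value per step, starting after the
#'   first update.
#' @export
update_pool <- function(ca, influx_current, dt, phi = 1, vmax = 1e-6,
                        km = 5e-4, tau = 50, base = 0) {
  if (any(!is.finite(influx_current))) stop("non-finite influx current")
  out <- numeric(length(influx_current))
  for (i in seq_along(influx_current)) {
    ev <- max(ca - base, 0)
    ca <- ca + dt * (phi * influx_current[i] - vmax * ev / (ev + km) -
                       (ca - base) / tau)
    ca <- max(ca, 0)
    out[i] <- ca
  }
  out
}

#' Voltage-gated calcium surrogate activation and current
#'
#' The model collapses the T/R/N/L channel families into a low-voltage-
#' activated (LVA) and a high-voltage-activated (HVA) surrogate, each with
#' Boltzmann steady-state activation (LVA at least 10 mV more negative than
#' HVA) and first-order kinetics; a fixed fraction of the HVA conductance
#' is the L-type share feeding the L-type spine pool, while all sources
#' feed the shaft all-VGCC pool.  `vgcc_activation()` returns the
#' steady-state activations; `vgcc_current()` the ohmic currents for given
#' activation states (nA; negative = inward below the calcium reversal).
#'
#' @param v membrane potential (mV), vectorized.
#' @param ca [calcium_params()].
#' @return `vgcc_activation`: list with `lva` and `hva` activations in
#'   [0, 1].
#' @export
vgcc_activation <- function(v, ca = calcium_params()) {
  list(lva = 1 / (1 + exp((ca$lva_vh - v) / ca$lva_k)),
       hva = 1 / (1 + exp((ca$hva_vh - v) / ca$hva_k)))
}

#' @rdname vgcc_activation
#' @param m_lva,m_hva activation states in [0, 1].
#' @param g_lva,g_hva conductances (uS).
#' @export
vgcc_current <- function(v, m_lva, m_hva, g_lva, g_hva,
                         ca = calcium_params()) {
  stopifnot(all(is.finite(v)))
  drive <- pmin(v - ca$e_ca, 0)
  list(lva = g_lva * m_lva * drive,
       hva = g_hva * m_hva * drive,
       ltype = ca$frac_l * g_hva * m_hva * drive)
}

# Reference clustered configuration used for calcium calibration: one
# cluster of n_syn baseline-weight synapses at `distance` on dendrite 1 of
# the default surrogate, optionally with the feature-unspecific synapse
# population and background noise of the task context.
calibration_reference <- function(n_syn = 8, w = 0.25, distance = 140,
                                  ca = calcium_params(),
                                  syn = synapse_params(),
                                  task_context = FALSE) {
  morph <- build_surrogate_morphology(12, 200, 10)
  seg_len <- morph$dendrite_length / morph$segments_per_dendrite
  d <- stats::runif(n_syn, distance - 10, distance + 10)
  seg <- pmin(pmax(ceiling(d / seg_len), 1), morph$segments_per_dendrite)
  comp <- morph$comp$id[morph$comp$dendrite == 1][seg]
  exc <- data.frame(comp = comp, dist = d, feature = "yellow",
                    cluster = 1L, w = w)
  if (task_context) {
    nseg <- morph$segments_per_dendrite
    d_un <- stats::runif(108, 10, morph$dendrite_length)
    seg_un <- pmin(pmax(ceiling(d_un / seg_len), 1), nseg)
    dend_un <- sample(morph$n_dendrites, 108, replace = TRUE)
    exc <- rbind(exc, data.frame(
      comp = 1L + (dend_un - 1L) * nseg + seg_un, dist = d_un,
      feature = "unspecific", cluster = NA_integer_,
      w = stats::runif(108, 0.2, 0.3)))
  }
  build_model(morph, exc, spill_mode = "cluster", syn = syn, ca = ca,
              noise = task_context)
}

# Calibration probes.  The quiet probe activates only the cluster synapses
# in a noise-free model (used for the silent L-type bound); the task probe
# adds the feature-unspecific population and background noise so that the
# measured peaks match what synapses see during training trials.
calibration_probe <- function(ca, n_active, force_spike, dt = 0.1,
                              syn = synapse_params(), task_context = FALSE,
                              n_rep = if (task_context) 3 else 1) {
  set.seed(20260101)
  model <- calibration_reference(ca = ca, syn = syn,
                                 task_context = task_context)
  acc <- c(ca_nmda = 0, ca_ltype = 0, ca_v = 0)
  trig <- spiked <- TRUE
  for (r in seq_len(n_rep)) {
    rows <- c(model$pack$map$ampa[seq_len(n_active)],
              model$pack$map$nmda[seq_len(n_active)])
    ev <- cbind(stats::runif(2 * n_active, 10, 30), rows)
    if (task_context) {
      uns <- which(model$exc$feature == "unspecific")
      tu <- stats::runif(length(uns), 10, 60)
      ev <- rbind(ev, cbind(rep(tu, 2), c(model$pack$map$ampa[uns],
                                          model$pack$map$nmda[uns])))
      m <- model$pack$map
      ne <- generate_background_noise(syn$noise_rate_exc, 400, m$n_noise)
      ni <- generate_background_noise(syn$noise_rate_inh, 400, m$n_noise)
      ev <- rbind(ev, cbind(unlist(ne), rep(m$noise_exc, lengths(ne))),
                  cbind(unlist(ni), rep(m$noise_inh, lengths(ni))))
    }
    inj <- if (force_spike) cbind(1, 2.0, 60, 63) else NULL
    sim <- simulate_window(model, ev, duration = 400, dt = dt, inj = inj)
    act <- seq_len(n_active)
    acc <- acc + c(mean(sim$ca_nmda_peak[act]), mean(sim$ca_ltype_peak[act]),
                   max(sim$ca_v_peak[2:model$pack$map$n_mc])) / n_rep
    trig <- trig && is.finite(sim$trigger_time[1])
    spiked <- spiked && length(sim$spikes) > 0
  }
  list(ca_nmda = acc[["ca_nmda"]], ca_ltype = acc[["ca_ltype"]],
       ca_v = acc[["ca_v"]], triggered = trig, spiked = spiked)
}

#' Calibrate calcium influx scales against the plasticity-rule anchors
#'
#' The millimolar scale of each calcium pool is not observable in the
#' surrogate; it is anchored to the constants of the learning rules.  This
#' routine finds influx scales such that, in the baseline clustered
#' reference (a cluster of 8 synapses at weight 0.25, probed in the task
#' context with the feature-unspecific population and background noise):
#' \itemize{
#'   \item a spillover-triggered stimulus yields a mean peak spine NMDA
#'     calcium within a factor of two of the initial LTP-kernel midpoint
#'     (0.02 mM),
#'   \item a sub-threshold stimulus (4 synapses, no spillover) yields a
#'     peak below half the midpoint,
#'   \item a plateau with a somatic spike yields peak L-type calcium above
#'     the 70 nM LTD threshold while a silent sub-threshold stimulus (quiet
#'     probe, no background drive) stays below it, and
#'   \item the evoked shaft all-VGCC peak lands at the working scale of
#'     the inhibitory-rule thresholds (`target_cav`).
#' }
#' The search fails loudly if no scale in the bounded range satisfies all
#' targets.
#'
#' @param ca starting [calcium_params()].
#' @param syn [synapse_params()].
#' @param target_nmda target triggered-cluster NMDA peak (mM), placed at
#'   the initial LTP-kernel midpoint so triggered synapses are eligible
#'   for potentiation from the first rewards.
#' @param target_ltype target plateau-plus-spike L-type peak (mM) in the
#'   task context; sets the per-pause depression magnitude.
#' @param target_cav target plateau shaft all-VGCC peak (mM).
#' @param dt probe integration step (ms).
#' @param theta_ltp0,theta_ltd plasticity anchors (mM).
#' @return a `calcium_params` object with calibrated `phi_*` scales and a
#'   `calibration` attribute reporting achieved peaks and per-target
#'   pass/fail.
#' @export
calibrate_calcium <- function(ca = calcium_params(), syn = synapse_params(),
                              target_nmda = 0.022, target_ltype = 0.3,
                              target_cav = 0.15, dt = 0.1,
                              theta_ltp0 = 0.02, theta_ltd = 7e-5) {
  # --- NMDA pool: near-linear in phi, fixed-point refinement -------------
  for (it in 1:3) {
    p8 <- calibration_probe(ca, 8, force_spike = FALSE, dt = dt, syn = syn,
                            task_context = TRUE)
    ca$phi_nmda <- ca$phi_nmda * target_nmda / p8$ca_nmda
  }
  p8 <- calibration_probe(ca, 8, force_spike = FALSE, dt = dt, syn = syn,
                          task_context = TRUE)
  p4 <- calibration_probe(ca, 4, force_spike = FALSE, dt = dt, syn = syn,
                          task_context = TRUE)
  if (!p8$triggered) stop("calibration reference failed to trigger spillover")
  if (p4$triggered) stop("sub-threshold calibration probe triggered spillover")
  if (p4$ca_nmda >= 0.5 * theta_ltp0) {
    stop("triggered/sub-threshold NMDA calcium contrast too small: ",
         "sub-threshold peak ", signif(p4$ca_nmda, 3),
         " not below half the kernel midpoint")
  }

  # --- L-type pool: scale on the task-context plateau, constrained by the
  # --- quiet silent probe staying below the 70 nM LTD threshold ----------
  for (it in 1:6) {
    a <- calibration_probe(ca, 8, force_spike = FALSE, dt = dt, syn = syn,
                           task_context = TRUE)
    ca$phi_ltype <- ca$phi_ltype * target_ltype / a$ca_ltype
  }
  qa <- calibration_probe(ca, 8, force_spike = TRUE, dt = dt, syn = syn)
  qb <- calibration_probe(ca, 4, force_spike = FALSE, dt = dt, syn = syn)
  while (qb$ca_ltype >= theta_ltd && ca$phi_ltype > 1e-4) {
    # trade plateau amplitude for the silent bound
    ca$phi_ltype <- ca$phi_ltype * 0.7
    qb <- calibration_probe(ca, 4, force_spike = FALSE, dt = dt, syn = syn)
  }
  qa <- calibration_probe(ca, 8, force_spike = TRUE, dt = dt, syn = syn)
  if (!(qa$ca_ltype > theta_ltd && qb$ca_ltype < theta_ltd)) {
    stop("no L-type influx scale separates plateau from silent ",
         "sub-threshold stimuli around the 70 nM LTD threshold")
  }

  # --- all-VGCC pool: linear scale to the task-context plateau peak ------
  pa <- calibration_probe(ca, 8, force_spike = FALSE, dt = dt, syn = syn,
                          task_context = TRUE)
  ca$phi_v <- ca$phi_v * target_cav / max(pa$ca_v - ca$base_v, 1e-12)

  pa <- calibration_probe(ca, 8, force_spike = FALSE, dt = dt, syn = syn,
                          task_context = TRUE)
  pb <- calibration_probe(ca, 4, force_spike = FALSE, dt = dt, syn = syn,
                          task_context = TRUE)
  report <- list(
    phi_nmda = ca$phi_nmda, phi_ltype = ca$phi_ltype, phi_v = ca$phi_v,
    triggered_nmda_peak = pa$ca_nmda, subthreshold_nmda_peak = pb$ca_nmda,
    triggered_ltype_peak = pa$ca_ltype,
    silent_ltype_peak = qb$ca_ltype,
    plateau_spike_ltype_peak = qa$ca_ltype,
    triggered_cav_peak = pa$ca_v,
    pass = c(
      nmda_in_band = pa$ca_nmda >= 0.5 * theta_ltp0 &&
        pa$ca_nmda <= 2 * theta_ltp0,
      nmda_subthreshold = pb$ca_nmda < 0.5 * theta_ltp0,
      ltype_above_ltd_threshold = qa$ca_ltype > theta_ltd,
      ltype_silent_below = qb$ca_ltype < theta_ltd))
  if (!all(report$pass)) {
    stop("calcium calibration failed: ",
         paste(names(report$pass)[!report$pass], collapse = ", "))
  }
  attr(ca, "calibration") <- report
  ca
}

#' Write a calcium calibration report as JSON
#'
#' @param ca a calibrated `calcium_params` (from [calibrate_calcium()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(ca, path) {
  rep <- attr(ca, "calibration")
  if (is.null(rep)) stop("parameters carry no calibration report")
  rep$pass <- as.list(rep$pass)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
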