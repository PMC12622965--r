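#' Assemble a simulatable neuron model from morphology and synapse tables
#'
#' Combines a surrogate morphology with excitatory and inhibitory synapse
#' placement tables into a compiled model ready for simulation.  Every
#' excitatory synapse gets an explicit spine (head compartment behind the
#' neck resistance) carrying its AMPA/NMDA conductances and its private
#' NMDA and L-type calcium pools; dendritic shafts carry the all-VGCC
#' calcium pools used by the inhibitory rule.  Spillover pooling is either
#' per synaptic cluster (clustered setups) or per dendritic branch
#' (distributed setups).
#'
#' @param morphology an `spn_morphology` from
#'   [build_surrogate_morphology()].
#' @param exc excitatory synapse table: columns `comp` (shaft compartment
#'   id), `dist` (um), `feature` (one of yellow, red, banana, strawberry,
#'   unspecific), `cluster` (integer id or NA) and `w` (dimensionless
#'   initial weight).
#' @param inh optional inhibitory synapse table: columns `comp`, `dist`,
#'   `feature`, `w` (uS).
#' @param spill_mode `"cluster"` (spillover unit per cluster id) or
#'   `"branch"` (all co-activated excitatory synapses on a dendrite pool
#'   toward one unit per branch).
#' @param syn [synapse_params()].
#' @param ca [calcium_params()].
#' @param noise logical; include background-noise synapses.
#' @return an object of class `spn_model`.
#' @export
build_model <- function(morphology, exc, inh = NULL,
                        spill_mode = c("cluster", "branch"),
                        syn = synapse_params(), ca = calcium_params(),
                        noise = TRUE) {
  spill_mode <- match.arg(spill_mode)
  comp <- morphology$comp
  stopifnot(all(exc$comp %in% comp$id), all(exc$w >= 0))
  if (!is.null(inh) && nrow(inh) > 0) {
    stopifnot(all(inh$comp %in% comp$id), all(inh$w >= 0),
              all(inh$w <= inh_plasticity_params()$w_inh_max + 1e-12))
  } else {
    inh <- data.frame(comp = integer(0), dist = numeric(0),
                      feature = character(0), w = numeric(0))
  }
  exc$id <- seq_len(nrow(exc))
  if (nrow(inh) > 0) inh$id <- seq_len(nrow(inh))
  exc$dendrite <- comp$dendrite[match(exc$comp, comp$id)]
  model <- structure(list(morph = morphology, exc = exc, inh = inh,
                          spill_mode = spill_mode, syn = syn, ca = ca,
                          noise = noise,
                          v_rest = resting_potential(morphology)),
                     class = "spn_model")
  model$pack <- compile_model(model)
  model
}

#' @export
print.spn_model <- function(x, ...) {
  cat("spn_model:", nrow(x$morph$comp), "compartments +", nrow(x$exc),
      "spines;", nrow(x$exc), "excitatory /", nrow(x$inh),
      "inhibitory synapses; spillover mode:", x$spill_mode, "\n")
  invisible(x)
}

# Compile the model into flat arrays for the C++ integrator.  Compartment
# order: morphology compartments (Hines order) then one spine head per
# excitatory synapse.  Synapse-row order: AMPA rows, NMDA rows, spillover
# unit rows, GABA rows, excitatory noise rows, inhibitory noise rows.
compile_model <- function(model) {
  comp <- model$morph$comp
  mb <- model$morph$membrane
  syn <- model$syn
  ca <- model$ca
  exc <- model$exc
  inh <- model$inh
  n_mc <- nrow(comp)
  n_exc <- nrow(exc)
  n_inh <- nrow(inh)

  area <- comp_area_cm2(comp$length, comp$diameter)
  head_area <- mb$spine_head_area * 1e-8  # um2 -> cm2
  all_area <- c(area, rep(head_area, n_exc))
  exc_comp_idx <- match(exc$comp, comp$id)
  parent <- c(0L, match(comp$parent[-1], comp$id), exc_comp_idx) - 1L
  g_ax <- numeric(n_mc + n_exc)
  for (i in seq_len(n_mc)[-1]) {
    p <- match(comp$parent[i], comp$id)
    g_ax[i] <- 1 / (half_axial_mohm(comp$length[i], comp$diameter[i], mb$ra) +
                      half_axial_mohm(comp$length[p], comp$diameter[p], mb$ra))
  }
  if (n_exc > 0) g_ax[n_mc + seq_len(n_exc)] <- 1 / mb$spine_neck_r

  vg_fac <- c(rep(1, n_mc), rep(ca$spine_vgcc_factor, n_exc))
  lpool <- c(rep(-1L, n_mc), seq_len(n_exc) - 1L)
  dist_all <- c(comp$somatic_distance, exc$dist)

  # ---- spillover units ------------------------------------------------
  if (model$spill_mode == "cluster") {
    cl_ids <- sort(unique(exc$cluster[!is.na(exc$cluster)]))
    unit_of_exc <- match(exc$cluster, cl_ids)  # NA for non-cluster synapses
    unit_comp <- vapply(cl_ids, function(cl) {
      cc <- exc$comp[!is.na(exc$cluster) & exc$cluster == cl]
      as.integer(stats::median(cc))
    }, integer(1))
  } else {
    dend <- comp$dendrite[exc_comp_idx]
    cl_ids <- sort(unique(dend[dend > 0]))
    unit_of_exc <- match(dend, cl_ids)
    mid_seg <- ceiling(model$morph$segments_per_dendrite / 2)
    unit_comp <- vapply(cl_ids, function(d)
      comp$id[comp$dendrite == d & comp$seg == mid_seg], integer(1))
  }
  n_unit <- length(cl_ids)

  noise_comps <- if (model$noise) comp$id[comp$dendrite > 0] else integer(0)
  n_noise <- length(noise_comps)

  # ---- synapse rows ---------------------------------------------------
  ampa <- seq_len(n_exc)
  nmda <- n_exc + seq_len(n_exc)
  urow <- 2L * n_exc + seq_len(n_unit)
  grow <- 2L * n_exc + n_unit + seq_len(n_inh)
  nexr <- 2L * n_exc + n_unit + n_inh + seq_len(n_noise)
  ninr <- 2L * n_exc + n_unit + n_inh + n_noise + seq_len(n_noise)
  n_row <- 2L * n_exc + n_unit + n_inh + 2L * n_noise

  head_idx0 <- n_mc + seq_len(n_exc) - 1L  # 0-based spine-head compartments
  syn_comp <- integer(n_row)
  syn_g <- syn_e <- syn_tr <- syn_td <- syn_ton <- syn_wsp <- numeric(n_row)
  syn_mg <- integer(n_row)
  syn_pool <- rep(-1L, n_row)
  syn_unit <- rep(-1L, n_row)

  syn_comp[ampa] <- head_idx0
  syn_g[ampa] <- exc$w * syn$gmax_ampa
  syn_tr[ampa] <- syn$tau_ampa[1]; syn_td[ampa] <- syn$tau_ampa[2]

  syn_comp[nmda] <- head_idx0
  syn_g[nmda] <- exc$w * syn$gmax_nmda
  syn_tr[nmda] <- syn$tau_nmda[1]; syn_td[nmda] <- syn$tau_nmda[2]
  syn_mg[nmda] <- 1L
  syn_pool[nmda] <- seq_len(n_exc) - 1L
  syn_unit[nmda] <- ifelse(is.na(unit_of_exc), -1L, unit_of_exc - 1L)
  syn_wsp[nmda] <- exc$w

  if (n_unit > 0) {
    syn_comp[urow] <- match(unit_comp, comp$id) - 1L
    syn_g[urow] <- syn$gmax_extrasyn
    syn_tr[urow] <- syn$tau_extrasyn[1]; syn_td[urow] <- syn$tau_extrasyn[2]
    syn_mg[urow] <- 1L
  }
  if (n_inh > 0) {
    syn_comp[grow] <- match(inh$comp, comp$id) - 1L
    syn_g[grow] <- inh$w
    syn_e[grow] <- syn$e_gaba
    syn_tr[grow] <- syn$tau_gaba[1]; syn_td[grow] <- syn$tau_gaba[2]
  }
  if (n_noise > 0) {
    nci <- match(noise_comps, comp$id) - 1L
    syn_comp[nexr] <- nci
    syn_g[nexr] <- syn$noise_g_exc
    syn_tr[nexr] <- syn$tau_ampa[1]; syn_td[nexr] <- syn$tau_ampa[2]
    syn_comp[ninr] <- nci
    syn_g[ninr] <- syn$noise_g_inh
    syn_e[ninr] <- syn$e_gaba
    syn_tr[ninr] <- syn$tau_gaba[1]; syn_td[ninr] <- syn$tau_gaba[2]
  }
  syn_ton <- 2 * syn_tr

  list(
    parent = parent,
    cap = all_area * mb$cm * 1e3,
    g_leak = all_area * mb$g_pas * 1e3,
    g_kir = all_area * mb$g_kir_dens * 1e3,
    g_ax = g_ax,
    dist = dist_all,
    e_leak = mb$e_pas, e_k = mb$e_k,
    kir_vh = mb$kir_vh, kir_k = mb$kir_k,
    syn_comp = syn_comp, syn_g = syn_g, syn_e = syn_e,
    syn_tr = syn_tr, syn_td = syn_td, syn_ton = syn_ton,
    syn_mg = syn_mg, syn_pool = syn_pool, syn_unit = syn_unit,
    syn_wsp = syn_wsp,
    un_row = urow - 1L, un_thresh = rep(syn$spill_threshold, n_unit),
    g_lva = all_area * ca$g_lva_dens * 1e3 * vg_fac,
    g_hva = all_area * ca$g_hva_dens * 1e3 * vg_fac,
    lpool = lpool,
    lva_vh = ca$lva_vh, lva_k = ca$lva_k, lva_tau = ca$lva_tau,
    hva_vh = ca$hva_vh, hva_k = ca$hva_k, hva_tau = ca$hva_tau,
    e_ca = ca$e_ca, frac_l = ca$frac_l,
    n_exc = n_exc,
    phi_n = ca$phi_nmda, vmax_n = ca$pump_vmax_nmda, km_n = ca$pump_km,
    tau_n = ca$tau_nmda, base_n = 0,
    phi_l = ca$phi_ltype, vmax_l = ca$pump_vmax_ltype, km_l = ca$pump_km,
    tau_l = ca$tau_ltype, base_l = 0,
    phi_v = ca$phi_v, vmax_v = ca$pump_vmax_v, km_v = ca$pump_km,
    tau_v = ca$tau_v, base_v = ca$base_v,
    spike_thresh = mb$spike_threshold, v_reset = mb$v_reset,
    refrac = mb$refractory, bap_amp = mb$bap_amp,
    bap_lambda = mb$bap_lambda, ahp_inc = mb$ahp_inc, ahp_tau = mb$ahp_tau,
    # R-side maps (ignored by the C++ core)
    map = list(ampa = ampa, nmda = nmda, unit = urow, gaba = grow,
               noise_exc = nexr, noise_inh = ninr,
               unit_cluster = cl_ids, unit_comp = unit_comp,
               n_mc = n_mc, n_all = n_mc + n_exc, n_noise = n_noise,
               noise_comps = noise_comps, head = n_mc + seq_len(n_exc))
  )
}

# Push current weights into the compiled arrays (cheap per-stimulus update).
sync_weights <- function(model) {
  m <- model$pack$map
  model$pack$syn_g[m$ampa] <- model$exc$w * model$syn$gmax_ampa
  model$pack$syn_g[m$nmda] <- model$exc$w * model$syn$gmax_nmda
  model$pack$syn_wsp[m$nmda] <- model$exc$w
  if (length(m$gaba) > 0) model$pack$syn_g[m$gaba] <- model$inh$w
  model
}

#' Simulate the model over one time window
#'
#' Advances the full model (cable voltages, synaptic gating, spillover
#' triggering, somatic spiking, calcium pools) from the resting state for
#' `duration` ms, delivering the given presynaptic events, and returns
#' per-stimulus summary measures: somatic spike times, spillover trigger
#' times per unit, peak NMDA/L-type calcium per excitatory synapse, peak
#' all-VGCC calcium per compartment and peak voltage per compartment.
#'
#' @param model an `spn_model`.
#' @param events two-column matrix (`time` ms, `row`) of presynaptic events
#'   on compiled synapse rows, e.g. from [stimulus_events()]; may be NULL.
#' @param duration window length (ms).
#' @param dt integration step (ms), in [0.01, 0.5].
#' @param record record voltage/calcium traces.
#' @param rec_comps compartment indices (1-based, spine heads allowed via
#'   `model$pack$map$head`) to trace.
#' @param rec_pools excitatory synapse ids whose calcium pools to trace.
#' @param stride record every `stride`-th step.
#' @param inj optional current injection matrix with columns compartment id
#'   (1-based), amplitude (nA), start (ms), end (ms).
#' @param v_init optional initial voltage vector (defaults to rest).
#' @return a list with elements `spikes`, `trigger_time`, `ca_nmda_peak`,
#'   `ca_ltype_peak`, `ca_v_peak`, `v_peak`, `v_final`, `gate_peak`,
#'   `unit_wsum` and, if recording, `t`, `v_trace`, `ca_nmda_trace`,
#'   `ca_ltype_trace`.
#' @export
simulate_window <- function(model, events = NULL, duration = 350, dt = 0.1,
                            record = FALSE, rec_comps = 1L,
                            rec_pools = integer(0), stride = 5L,
                            inj = NULL, v_init = NULL) {
  if (dt < 0.01 || dt > 0.5) stop("dt must be in [0.01, 0.5] ms")
  pack <- model$pack
  if (is.null(events) || NROW(events) == 0) {
    events <- matrix(numeric(0), ncol = 2)
  } else {
    events <- events[order(events[, 1]), , drop = FALSE]
    events[, 2] <- events[, 2] - 1  # 0-based rows for C++
  }
  if (is.null(inj)) {
    inj <- matrix(numeric(0), ncol = 4)
  } else {
    inj <- matrix(as.numeric(inj), ncol = 4)
    inj[, 1] <- inj[, 1] - 1
  }
  if (is.null(v_init)) v_init <- rep(model$v_rest, pack$map$n_all)
  rec <- list(record = record, comps = as.integer(rec_comps) - 1L,
              pools = as.integer(rec_pools) - 1L, stride = as.integer(stride))
  sim_core(pack, v_init, events, inj, duration, dt, rec)
}

#' Advance the membrane by one integration step
#'
#' Exposes a single implicit step of the cable system for the given
#' membrane state and per-compartment injected currents.  Mostly useful for
#' verifying fixed points and steady-state responses; simulations use
#' [simulate_window()].
#'
#' @param model an `spn_model`.
#' @param state list with element `v` (voltage vector over compartments
#'   incl. spine heads) and `time` (ms); see [membrane_state()].
#' @param currents per-compartment injected current (nA), recycled to the
#'   number of compartments; default zero.
#' @param dt step (ms) in [0.01, 0.5].
#' @return the advanced state.
#' @export
step_membrane <- function(model, state, currents = 0, dt = 0.1) {
  n <- model$pack$map$n_all
  cur <- rep_len(currents, n)
  nz <- which(cur != 0)
  inj <- if (length(nz)) cbind(nz, cur[nz], -1, dt + 1) else NULL
  sim <- simulate_window(model, NULL, duration = dt, dt = dt, inj = inj,
                         v_init = state$v)
  list(v = sim$v_final, time = state$time + dt)
}

#' @rdname step_membrane
#' @export
membrane_state <- function(model) {
  list(v = rep(model$v_rest, model$pack$map$n_all), time = 0)
}
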