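#' Build a reduced compartmental surrogate morphology
#'
#' Constructs the electrical tree used throughout the package: a somatic
#' cylinder plus `n_dendrites` unbranched dendrites, each divided into
#' equal-length segments whose diameter tapers linearly from `diam_base` at
#' the soma to `taper * diam_base` at the tip.  Somatic path distance is
#' computed for every compartment midpoint.  Distal segments have higher
#' local input impedance than proximal ones, which is the substrate for the
#' location dependence of plateau efficacy.
#'
#' @param n_dendrites number of dendrites (>= 2).
#' @param dendrite_length dendrite length in um (>= 200).
#' @param segments_per_dendrite segments per dendrite (>= 4); segment length
#'   must not exceed 40 um (spatial resolution guard).
#' @param taper tip-to-base diameter ratio in (0, 1].
#' @param diam_base dendritic diameter at the soma (um).
#' @param membrane [membrane_params()] giving passive constants.
#' @return an object of class `spn_morphology`: a list with the compartment
#'   table (`comp`: id, parent, length, diameter, somatic distance of the
#'   midpoint, dendrite index, segment index) and the membrane parameters.
#' @examples
#' m <- build_surrogate_morphology(2, 200, 10)
#' nrow(m$comp)  # 21 compartments
#' @export
build_surrogate_morphology <- function(n_dendrites = 2,
                                       dendrite_length = 200,
                                       segments_per_dendrite = 10,
                                       taper = 0.25,
                                       diam_base = 1.0,
                                       membrane = membrane_params()) {
  if (n_dendrites < 2) stop("n_dendrites must be >= 2")
  if (dendrite_length < 200) stop("dendrite_length must be >= 200 um")
  if (segments_per_dendrite < 4) stop("segments_per_dendrite must be >= 4")
  if (taper <= 0 || taper > 1) stop("taper must be in (0, 1]")
  if (diam_base <= 0) stop("diam_base must be positive")
  seg_len <- dendrite_length / segments_per_dendrite
  if (seg_len > 40) stop("segment length exceeds 40 um; use more segments")

  n_comp <- 1L + n_dendrites * segments_per_dendrite
  id <- seq_len(n_comp)
  parent <- integer(n_comp)
  parent[1] <- NA_integer_
  len <- numeric(n_comp)
  diam <- numeric(n_comp)
  dist <- numeric(n_comp)
  dendrite <- integer(n_comp)
  seg <- integer(n_comp)

  len[1] <- membrane$soma_l
  diam[1] <- membrane$soma_diam
  dist[1] <- 0
  k <- 1L
  for (d in seq_len(n_dendrites)) {
    for (j in seq_len(segments_per_dendrite)) {
      k <- k + 1L
      parent[k] <- if (j == 1L) 1L else k - 1L
      len[k] <- seg_len
      # linear taper evaluated at the segment midpoint
      frac <- (j - 0.5) / segments_per_dendrite
      diam[k] <- diam_base * (1 - (1 - taper) * frac)
      dist[k] <- (j - 0.5) * seg_len
      dendrite[k] <- d
      seg[k] <- j
    }
  }
  comp <- data.frame(id = id, parent = parent, length = len, diameter = diam,
                     somatic_distance = dist, dendrite = dendrite, seg = seg)
  structure(list(comp = comp, membrane = membrane,
                 n_dendrites = n_dendrites,
                 dendrite_length = dendrite_length,
                 segments_per_dendrite = segments_per_dendrite),
            class = "spn_morphology")
}

#' @export
print.spn_morphology <- function(x, ...) {
  cat("spn_morphology:", nrow(x$comp), "compartments,",
      x$n_dendrites, "dendrites of", x$dendrite_length, "um (",
      x$segments_per_dendrite, "segments each )\n")
  cat("  resting potential:", round(resting_potential(x), 2), "mV\n")
  invisible(x)
}

# membrane area (cm^2), capacitance (nF) and conductances (uS) per
# compartment; cylinder side area, spine heads use their stated area.
comp_area_cm2 <- function(len_um, diam_um) {
  pi * diam_um * len_um * 1e-8
}

# axial resistance of one half-compartment in Mohm
half_axial_mohm <- function(len_um, diam_um, ra) {
  # Ra [ohm cm] * (L/2 [cm]) / (pi r^2 [cm^2]) -> ohm -> Mohm
  ra * (len_um * 1e-4 / 2) / (pi * (diam_um * 1e-4 / 2)^2) * 1e-6
}

#' Uniform resting potential of the surrogate membrane
#'
#' With spatially uniform leak and KIR densities the zero-input steady state
#' is the same in every compartment, so the resting potential solves the
#' scalar current balance `g_pas (V - e_pas) + g_kir m(V) (V - e_k) = 0`.
#'
#' @param morphology an `spn_morphology`.
#' @return resting potential in mV.
#' @export
resting_potential <- function(morphology) {
  mb <- morphology$membrane
  if (mb$g_pas + mb$g_kir_dens == 0) return(mb$e_pas)
  f <- function(v) {
    m <- 1 / (1 + exp((v - mb$kir_vh) / mb$kir_k))
    mb$g_pas * (v - mb$e_pas) + mb$g_kir_dens * m * (v - mb$e_k)
  }
  stats::uniroot(f, c(-95, -40), tol = 1e-10)$root
}

# Conductance matrix (uS) of the linearized membrane at voltage v0 with the
# KIR chord conductance frozen, plus axial coupling.  Rows/cols follow the
# compartment table; optionally appended spine heads.
conductance_matrix <- function(morphology, kir_on = TRUE) {
  comp <- morphology$comp
  mb <- morphology$membrane
  n <- nrow(comp)
  v0 <- resting_potential(morphology)
  m0 <- if (kir_on) 1 / (1 + exp((v0 - mb$kir_vh) / mb$kir_k)) else 0
  area <- comp_area_cm2(comp$length, comp$diameter)
  g_mem <- (mb$g_pas + mb$g_kir_dens * m0 * kir_on) * area * 1e3  # uS
  G <- diag(g_mem, n, n)
  for (i in 2:n) {
    p <- comp$parent[i]
    r <- half_axial_mohm(comp$length[i], comp$diameter[i], mb$ra) +
      half_axial_mohm(comp$length[p], comp$diameter[p], mb$ra)
    g <- 1 / r  # uS
    G[i, i] <- G[i, i] + g
    G[p, p] <- G[p, p] + g
    G[i, p] <- G[i, p] - g
    G[p, i] <- G[p, i] - g
  }
  G
}

#' Steady-state input impedance at a compartment
#'
#' Solves the linearized cable system (leak plus KIR chord conductance at
#' rest) for a unit test current injected at `site` and returns the local
#' voltage deflection per nA, i.e. the input impedance in Mohm.  Distal
#' dendritic sites are electrically more isolated and have higher input
#' impedance than proximal ones.
#'
#' @param morphology an `spn_morphology`.
#' @param site compartment id.
#' @param kir_on include the KIR chord conductance (default) or the passive
#'   limit.
#' @return input impedance in Mohm.
#' @export
input_impedance <- function(morphology, site, kir_on = TRUE) {
  comp <- morphology$comp
  if (!site %in% comp$id) stop("unknown site id: ", site)
  G <- conductance_matrix(morphology, kir_on = kir_on)
  i <- numeric(nrow(comp))
  i[match(site, comp$id)] <- 1  # 1 nA
  v <- solve(G, i)
  v[match(site, comp$id)]  # mV / nA = Mohm
}

#' Detect somatic spikes in a voltage trace
#'
#' Returns the times of upward threshold crossings separated by at least the
#' refractory period.  This is the offline counterpart of the online
#' detection used during simulation (which additionally resets the soma and
#' injects the attenuating back-propagating depolarization).
#'
#' @param voltage_trace numeric vector of somatic voltages (mV).
#' @param times sample times (ms); defaults to 0-based unit steps.
#' @param threshold detection threshold (mV).
#' @param refractory minimum separation between detected spikes (ms).
#' @return numeric vector of spike times (ms); empty if none.
#' @export
detect_somatic_spikes <- function(voltage_trace, times = NULL,
                                  threshold = -40, refractory = 5) {
  n <- length(voltage_trace)
  if (n == 0) return(numeric(0))
  if (is.null(times)) times <- seq_len(n) - 1
  up <- which(voltage_trace[-1] >= threshold & voltage_trace[-n] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  out <- times[up[1]]
  for (k in up[-1]) {
    if (times[k] - out[length(out)] >= refractory) out <- c(out, times[k])
  }
  out
}

#' Serialize a morphology to JSON
#'
#' Writes the compartment table and membrane parameters as structured text
#' with explicit units; [morphology_from_json()] restores it.
#'
#' @param morphology an `spn_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
morphology_to_json <- function(morphology, path) {
  obj <- list(units = list(length = "um", diameter = "um",
                           somatic_distance = "um", capacitance = "uF/cm2",
                           conductance = "mS/cm2", voltage = "mV"),
              n_dendrites = morphology$n_dendrites,
              dendrite_length = morphology$dendrite_length,
              segments_per_dendrite = morphology$segments_per_dendrite,
              membrane = unclass(morphology$membrane),
              comp = morphology$comp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname morphology_to_json
#' @param path file written by [morphology_to_json()].
#' @export
morphology_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mb <- do.call(membrane_params, obj$membrane[names(obj$membrane) %in%
                                                names(formals(membrane_params))])
  comp <- as.data.frame(obj$comp)
  comp$parent[1] <- NA_integer_
  comp <- comp[, c("id", "parent", "length", "diameter", "somatic_distance",
                   "dendrite", "seg")]
  structure(list(comp = comp, membrane = mb,
                 n_dendrites = obj$n_dendrites,
                 dendrite_length = obj$dendrite_length,
                 segments_per_dendrite = obj$segments_per_dendrite),
            class = "spn_morphology")
}
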