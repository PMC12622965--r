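#' Write a synapse placement table as CSV
#'
#' One row per synapse: id, compartment, somatic distance (um), feature,
#' cluster membership and current weight; inhibitory synapses follow the
#' excitatory ones with `type = "inh"` and conductance weights in uS.
#'
#' @param model an `spn_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(model, path) {
  exc <- data.frame(type = "exc", id = model$exc$id, comp = model$exc$comp,
                    distance_um = model$exc$dist,
                    feature = model$exc$feature,
                    cluster = model$exc$cluster, w = model$exc$w)
  tab <- exc
  if (nrow(model$inh) > 0) {
    inh <- data.frame(type = "inh", id = model$inh$id, comp = model$inh$comp,
                      distance_um = model$inh$dist,
                      feature = model$inh$feature,
                      cluster = NA_integer_, w = model$inh$w)
    tab <- rbind(exc, inh)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write training results and a reproducibility manifest
#'
#' Emits the per-stimulus response table (`performance.csv`), the logged
#' weight trajectories (`weights.csv`, long format), the synapse placement
#' table (`synapses.csv`) and a JSON manifest (`metadata.json`) carrying
#' every plasticity, protocol, synapse, calcium and membrane parameter of
#' the run plus the seed, so the run can be reproduced bit-identically.
#'
#' @param training an `spn_training` from [run_training()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(training, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  utils::write.csv(training$records, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  wl <- training$weight_log
  if (length(wl$at) > 0) {
    long <- data.frame(
      stimulus = rep(wl$at, times = ncol(wl$w)),
      synapse = rep(seq_len(ncol(wl$w)), each = length(wl$at)),
      w = as.vector(wl$w), theta_ltp = as.vector(wl$theta_ltp))
    utils::write.csv(long, file.path(out_dir, "weights.csv"),
                     row.names = FALSE)
  }
  write_synapse_table(training$model, file.path(out_dir, "synapses.csv"))
  meta <- list(config = training$config,
               membrane = unclass(training$model$morph$membrane),
               synapse = unclass(training$model$syn),
               calcium = unclass(training$model$ca),
               spill_mode = training$model$spill_mode,
               final_performance = training$final_performance,
               solved = training$solved)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read back a results directory
#'
#' @param out_dir directory written by [write_results()].
#' @return list with `records`, `weights`, `synapses` and `metadata`.
#' @export
read_results <- function(out_dir) {
  list(records = utils::read.csv(file.path(out_dir, "performance.csv")),
       weights = if (file.exists(file.path(out_dir, "weights.csv")))
         utils::read.csv(file.path(out_dir, "weights.csv")) else NULL,
       synapses = utils::read.csv(file.path(out_dir, "synapses.csv")),
       metadata = jsonlite::read_json(file.path(out_dir, "metadata.json"),
                                      simplifyVector = TRUE))
}
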