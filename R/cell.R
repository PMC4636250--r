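#' Build an integrable granule cell
#'
#' Combines a morphology with a membrane mechanism set into a `gc_cell`
#' ready for the cable-equation integrator.  With no input the cell settles
#' to a stable resting potential and stays subthreshold indefinitely.
#'
#' @param morphology a [gc_morphology()].
#' @param mechanisms a [mechanism_source()] mechanism set (or a source name).
#' @return An object of class `gc_cell` holding the compartment table, the
#'   per-compartment channel densities and the channel block state.
#' @examples
#' cell <- build_cell(gc_morphology("reduced"), mechanism_source("fallback-hh"))
#' @export
build_cell <- function(morphology = gc_morphology("full"),
                       mechanisms = mechanism_source("fallback-hh")) {
  stopifnot(inherits(morphology, "gc_morphology"))
  if (is.character(mechanisms)) mechanisms <- mechanism_source(mechanisms)
  stopifnot(inherits(mechanisms, "mechanism_set"))
  validate_morphology(morphology$sections)
  block <- matrix(1, nrow = length(CHANNELS), ncol = length(LAYERS),
                  dimnames = list(CHANNELS, LAYERS))
  structure(list(
    morphology = morphology,
    mechanisms = mechanisms,
    block = block,
    synapses = NULL
  ), class = "gc_cell")
}

#' @export
print.gc_cell <- function(x, ...) {
  cat("<gc_cell> ", nrow(x$morphology$compartments), " compartments, mechanisms: ",
      x$mechanisms$name, "\n", sep = "")
  if (!is.null(x$synapses)) {
    cat("  synapses:", nrow(x$synapses), "(",
        sum(x$synapses$pathway == "medial"), "medial /",
        sum(x$synapses$pathway == "lateral"), "lateral )\n")
  }
  invisible(x)
}

#' Place perforant path synapses on the dendrites
#'
#' Places `n_medial` medial perforant path synapses uniformly at random
#' across the middle molecular layer (MML) segments of both dendritic
#' branches, and `n_lateral` lateral path synapses across the outer
#' molecular layer (OML) segments.  Each synapse is a double-exponential
#' conductance (rise 0.2 ms, decay 2.5 ms, reversal 0 mV) whose waveform is
#' peak-normalized so that a single presynaptic spike produces a conductance
#' transient with maximum equal to the synaptic weight.
#'
#' @param cell a `gc_cell`.
#' @param n_medial,n_lateral synapse counts per pathway (default 150 each).
#' @param weight initial peak conductance in uS, either a scalar applied to
#'   all synapses or a length-2 vector `(medial, lateral)`.  See
#'   [calibrate_baseline_weight()] for the calibration routine.
#' @param tau_rise,tau_decay,e_rev synaptic kinetics (ms, ms, mV).
#' @param seed integer seed for the placement draw.
#' @return the `gc_cell` with a `synapses` tibble attached (id, pathway,
#'   section, position, compartment, path distance from soma, weight).
#' @export
attach_synapses <- function(cell, n_medial = 150L, n_lateral = 150L,
                            weight = 1e-3, tau_rise = 0.2, tau_decay = 2.5,
                            e_rev = 0, seed = 1L) {
  stopifnot(inherits(cell, "gc_cell"))
  if (n_medial < 1L || n_lateral < 1L) {
    rlang::abort("each pathway needs at least one synapse")
  }
  if (any(weight <= 0)) rlang::abort("synaptic weights must be strictly positive")
  w <- if (length(weight) == 2L) weight else c(weight, weight)
  comp <- cell$morphology$compartments
  place <- function(n, layer, pathway, w0) {
    host <- comp[comp$layer == layer, ]
    pick <- host[sample.int(nrow(host), n, replace = TRUE), ]
    tibble::tibble(
      pathway = pathway,
      section = pick$section,
      pos = pick$pos,
      comp = pick$comp,
      path_dist = pick$path_dist,
      weight = w0
    )
  }
  syn <- withr::with_seed(seed, {
    dplyr::bind_rows(place(n_medial, "MML", "medial", w[1]),
                     place(n_lateral, "OML", "lateral", w[2]))
  })
  syn$id <- seq_len(nrow(syn))
  syn <- syn[, c("id", "pathway", "section", "pos", "comp", "path_dist", "weight")]
  # both branches should carry synapses of each pathway
  for (pw in c("medial", "lateral")) {
    if (length(unique(syn$section[syn$pathway == pw])) < 2L &&
        sum(syn$pathway == pw) >= 10L) {
      rlang::warn(paste0("all ", pw, " synapses landed on one branch"))
    }
  }
  cell$synapses <- syn
  cell$syn_kinetics <- list(tau_rise = tau_rise, tau_decay = tau_decay,
                            e_rev = e_rev)
  cell
}

#' Double-exponential synaptic conductance kernel
#'
#' The conductance response of one synapse to presynaptic spikes under
#' linear summation: a difference of exponentials scaled so that a single
#' event peaks exactly at `weight`.
#'
#' @param t times (ms) at which to evaluate the conductance.
#' @param spike_times presynaptic spike times (ms).
#' @param weight peak conductance (uS).
#' @param tau_rise,tau_decay rise and decay time constants (ms).
#' @return conductance (uS) at `t`.
#' @export
syn_conductance_kernel <- function(t, spike_times, weight = 1,
                                   tau_rise = 0.2, tau_decay = 2.5) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  g <- numeric(length(t))
  for (ts in spike_times) {
    dt <- t - ts
    on <- dt > 0
    g[on] <- g[on] + weight * norm * (exp(-dt[on] / tau_decay) - exp(-dt[on] / tau_rise))
  }
  g
}
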