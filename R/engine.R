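# Internal glue between the R-side cell description and the C++ engine.

layer_index <- function(layer) match(layer, LAYERS) - 1L

# Per-compartment membrane area (cm^2); all sections are cylinders (the
# soma's length equals its diameter).
comp_areas <- function(compartments) {
  pi * (compartments$diam * 1e-4) * (compartments$seg_length * 1e-4)
}

prepare_engine_comp <- function(cell) {
  comp <- cell$morphology$compartments
  mech <- cell$mechanisms
  area <- comp_areas(comp)
  # axial conductance between each compartment's centre and its parent's
  half_res <- function(i) {
    mech$Ra * (comp$seg_length[i] / 2 * 1e-4) /
      (pi * (comp$diam[i] / 2 * 1e-4)^2)
  }
  n <- nrow(comp)
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- comp$parent[i]
    g_ax[i] <- 1 / (half_res(i) + half_res(p)) * 1e6  # uS
  }
  list(
    parent = as.integer(ifelse(is.na(comp$parent), -1L, comp$parent - 1L)),
    C_nF = mech$cm * area * 1e3,
    g_axial_uS = g_ax,
    layer = layer_index(comp$layer)
  )
}

prepare_engine_mech <- function(cell, block_schedule = NULL) {
  comp <- cell$morphology$compartments
  mech <- cell$mechanisms
  area <- comp_areas(comp)
  n <- nrow(comp)
  gchan <- matrix(0, nrow = length(CHANNELS), ncol = n)
  for (ci in seq_along(CHANNELS)) {
    gchan[ci, ] <- mech$densities[CHANNELS[ci], comp$layer] * area * 1e6
  }
  erev <- setNames(numeric(length(CHANNELS)), CHANNELS)
  erev[c("na")] <- mech$reversals[["na"]]
  erev[c("kdrf", "kdrs", "ka", "sk", "bk")] <- mech$reversals[["k"]]
  erev[c("cat", "can", "cal")] <- mech$reversals[["ca"]]
  sched <- if (is.null(block_schedule)) {
    matrix(numeric(0), ncol = 4)
  } else {
    block_schedule
  }
  list(
    g_leak_uS = mech$g_leak[comp$layer] * area * 1e6,
    e_leak = mech$e_leak,
    g_chan_uS = gchan,
    e_rev = unname(erev),
    vshift = unname(mech$vshift[CHANNELS]),
    ca_B = 2.59e-7 / area,      # nA -> mM/ms for a 0.2 um shell
    ca_tau = mech$ca_pool$tau_ms,
    ca0 = mech$ca_pool$ca0_mM,
    na_h_scale = mech$na_h_scale,
    na_h_shift = mech$na_h_shift,
    block = cell$block,
    block_schedule = sched
  )
}

prepare_engine_syn <- function(cell, weights = NULL) {
  syn <- cell$synapses
  kin <- cell$syn_kinetics
  if (is.null(syn)) {
    syn <- tibble::tibble(comp = integer(0), weight = numeric(0))
    kin <- list(tau_rise = 0.2, tau_decay = 2.5, e_rev = 0)
  }
  list(
    comp = as.integer(syn$comp - 1L),
    weight = if (is.null(weights)) syn$weight else weights,
    tau_rise = kin$tau_rise,
    tau_decay = kin$tau_decay,
    e_rev = kin$e_rev
  )
}

prepare_engine_drive <- function(streams, synapses) {
  if (is.null(streams) || nrow(streams) == 0L) {
    return(list(time = numeric(0), syn = integer(0)))
  }
  idx <- match(streams$synapse_id, synapses$id)
  ord <- order(streams$time_ms)
  list(time = streams$time_ms[ord], syn = as.integer(idx[ord] - 1L))
}

prepare_engine_plas <- function(params, dt, enabled, warmup_ms) {
  list(
    enabled = enabled,
    a_p0 = params$a_p0, a_d0 = params$a_d0,
    tau_p = params$tau_p, tau_d = params$tau_d,
    tau_c_ms = params$tau_c * 1000,
    alpha = effective_alpha(params, dt),
    v_syn_thresh = params$v_syn_thresh,
    v_soma_thresh = params$v_soma_thresh,
    max_change = params$max_change,
    c_floor = params$c_floor,
    debounce = params$debounce,
    c0 = params$c0,
    warmup_ms = warmup_ms,
    freeze_ap = params$freeze_ap,
    freeze_ad = params$freeze_ad
  )
}

resolve_probes <- function(cell, probes) {
  if (is.null(probes)) return(integer(0))
  if (is.character(probes)) {
    probes <- data.frame(section = probes, pos = 0.5)
  }
  vapply(seq_len(nrow(probes)), function(i) {
    locate_compartment(cell$morphology, probes$section[i], probes$pos[i])
  }, integer(1))
}

run_engine <- function(cell, streams = NULL, t_stop, dt = 0.2,
                       params = plasticity_params(), plasticity = FALSE,
                       warmup_ms = 0, probes = NULL, probe_stride = 1L,
                       snapshot_ms = 0, record_gsyn = FALSE,
                       record_events = FALSE, i_clamp = NULL,
                       block_schedule = NULL) {
  comp <- prepare_engine_comp(cell)
  mech <- prepare_engine_mech(cell, block_schedule)
  syn <- prepare_engine_syn(cell)
  drv <- prepare_engine_drive(streams, cell$synapses)
  plas <- prepare_engine_plas(params, dt, plasticity, warmup_ms)
  probe_idx <- resolve_probes(cell, probes)
  icl <- if (is.null(i_clamp)) matrix(numeric(0), ncol = 4) else i_clamp
  ctl <- list(dt = dt, t_stop = t_stop,
              probes = as.integer(probe_idx - 1L),
              probe_stride = as.integer(probe_stride),
              snapshot_ms = snapshot_ms,
              record_gsyn = record_gsyn, record_events = record_events,
              iclamp = icl)
  out <- engine_run(comp, mech, syn, drv, plas, ctl)
  out$probe_comp <- probe_idx
  out
}

#' Write voltage traces as CSV with an embedded manifest
#'
#' Writes a trace tibble (from [integrate_cell()]) as plain CSV, preceded
#' by `#`-prefixed header lines carrying the run manifest, so the file is
#' self-describing.
#'
#' @param traces tibble with at least `time`, `section`, `pos`, `mV`.
#' @param path output file.
#' @param manifest named list written into the header.
#' @return `path`, invisibly.
#' @export
write_voltage_traces <- function(traces, path, manifest = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(manifest)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(manifest[[nm]]), collapse = " ")), con)
  }
  utils::write.csv(as.data.frame(traces), con, row.names = FALSE)
  invisible(path)
}

#' Integrate the cell and record voltage traces
#'
#' Runs the implicit cable-equation integrator over `duration` ms with the
#' given afferent drive (plasticity off), returning membrane potential
#' traces at the probe locations.  The solution does not depend on the
#' probe set.
#'
#' @param cell a `gc_cell` (synapses attached if `drive` is given).
#' @param drive an [assemble_drive()] event stream, or `NULL`.
#' @param duration run length (ms).
#' @param dt integration step (ms; 0.1 and 0.2 are the supported defaults).
#' @param probes probe locations: character vector of section names (probed
#'   at mid-section) or a data frame with `section` and `pos` columns.
#' @param i_clamp optional current injection: data frame with columns
#'   `section`, `pos`, `t0`, `t1` (ms) and `amp` (nA).
#' @param record_gsyn also record the total synaptic conductance (uS) at
#'   each probe compartment.
#' @param soma_threshold somatic spike detection threshold (mV).
#' @return a tibble `(time, section, pos, mV[, g_syn])`, one row per sample
#'   and probe, with the somatic spike times in attribute `soma_spikes`.
#' @export
integrate_cell <- function(cell, drive = NULL, duration = 1000, dt = 0.2,
                           probes = "soma", i_clamp = NULL,
                           record_gsyn = FALSE, soma_threshold = 0) {
  stopifnot(inherits(cell, "gc_cell"))
  icl <- NULL
  if (!is.null(i_clamp)) {
    icl <- cbind(
      vapply(seq_len(nrow(i_clamp)), function(i) {
        locate_compartment(cell$morphology, i_clamp$section[i],
                           i_clamp$pos[i])
      }, integer(1)) - 1L,
      i_clamp$t0, i_clamp$t1, i_clamp$amp
    )
  }
  params <- plasticity_params(v_soma_thresh = soma_threshold)
  out <- run_engine(cell, drive, t_stop = duration, dt = dt, params = params,
                    plasticity = FALSE, probes = probes,
                    record_gsyn = record_gsyn, i_clamp = icl)
  nrec <- out$n_rec
  if (is.character(probes)) probes <- data.frame(section = probes, pos = 0.5)
  traces <- purrr::map_dfr(seq_len(nrow(probes)), function(p) {
    tb <- tibble::tibble(
      time = out$probe_times[seq_len(nrec)],
      section = probes$section[p],
      pos = probes$pos[p],
      mV = out$V[seq_len(nrec), p]
    )
    if (record_gsyn) tb$g_syn <- out$g_syn[seq_len(nrec), p]
    tb
  })
  attr(traces, "soma_spikes") <- out$soma_spikes
  attr(traces, "V_final") <- out$V_final
  traces
}
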