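#' Calibrate the baseline synaptic weight
#'
#' Finds, by seeded bisection, the uniform peak conductance at which 8 Hz
#' spontaneous drive at all synapses makes the cell fire at the target
#' somatic rate (default 2 Hz).  At that rate the steady-state spike
#' average `<c>` is ~1, so the plasticity amplitudes sit at their initial
#' values at baseline.
#'
#' @param cell a `gc_cell` with synapses attached.
#' @param target_rate target mean somatic rate (Hz).
#' @param spont_spec spontaneous train spec used for the probe runs.
#' @param duration probe run length (ms); the first `settle` ms are
#'   discarded.
#' @param settle discarded initial transient (ms).
#' @param dt integration step (ms).
#' @param seed seed for the probe drives.
#' @param w_range search interval for the weight (uS).
#' @param tol stop when the achieved rate is within `tol` Hz of target.
#' @param max_iter bisection iteration cap.
#' @return list with `weight` (uS), `rate` (Hz achieved) and the search
#'   trace.
#' @export
calibrate_baseline_weight <- function(cell, target_rate = 2,
                                      spont_spec = NULL,
                                      duration = 30000, settle = 5000,
                                      dt = 0.2, seed = 1L,
                                      w_range = c(5e-5, 5e-2),
                                      tol = 0.1, max_iter = 14L) {
  stopifnot(inherits(cell, "gc_cell"), !is.null(cell$synapses))
  if (is.null(spont_spec)) {
    spont_spec <- spike_train_spec(isi0 = 125, noise = 0.05,
                                   t_start = 0, t_end = duration)
  }
  streams <- assemble_drive(cell, spont_spec, protocol = NULL,
                            seed = seed, dt = dt)
  rate_at <- function(w) {
    cell$synapses$weight <- rep(w, nrow(cell$synapses))
    out <- run_engine(cell, streams, t_stop = duration, dt = dt,
                      plasticity = FALSE)
    sp <- out$soma_spikes
    sum(sp >= settle) / ((duration - settle) / 1000)
  }
  lo <- w_range[1]; hi <- w_range[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  trace <- tibble::tibble(weight = c(lo, hi), rate = c(r_lo, r_hi))
  if (r_lo > target_rate || r_hi < target_rate) {
    rlang::warn("calibration target rate outside the bracket; returning closest end")
    best <- if (abs(r_lo - target_rate) < abs(r_hi - target_rate)) {
      list(weight = lo, rate = r_lo)
    } else {
      list(weight = hi, rate = r_hi)
    }
    return(c(best, list(trace = trace)))
  }
  w <- NA_real_; r <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- sqrt(lo * hi)  # bisection in log space
    r <- rate_at(w)
    trace <- dplyr::bind_rows(trace, tibble::tibble(weight = w, rate = r))
    if (abs(r - target_rate) <= tol) break
    if (r < target_rate) lo <- w else hi <- w
  }
  list(weight = w, rate = r, trace = trace)
}

#' Specify a closed-loop plasticity experiment
#'
#' Bundles every knob of a simulated induction experiment: the protocol,
#' the fraction of medial synapses tetanized, the spontaneous-activity
#' noise, durations, replication, morphology/mechanism choices, optional
#' channel-block and lateral-silencing schedules, and homeostasis switches.
#'
#' The timeline of each run is: plasticity warm-up (weight updates off,
#' `warmup_ms`, default one integration period `tau_c`), baseline
#' (`baseline_ms`), the stimulation protocol (if any), and a post period
#' (`post_ms`).  Pathway changes are measured against each synapse's weight
#' at protocol onset, averaged over the final `final_window_ms`.
#'
#' @param protocol a preset name (`"400-DBS"`, `"100-TBS"`, `"400-TBS"`), a
#'   [protocol_spec()], or `NULL` for baseline-only runs.
#' @param tetanized_fraction fraction of medial synapses tetanized.
#' @param noise spontaneous-train jitter fraction.
#' @param isi0 spontaneous mean inter-spike interval (ms).
#' @param dt integration step (ms).
#' @param warmup_ms,baseline_ms,post_ms,final_window_ms timeline (ms);
#'   `warmup_ms = NULL` uses `tau_c`.
#' @param n_runs number of replicate runs.
#' @param seeds integer seeds, one per run (default `1:n_runs`).
#' @param morphology `"reduced"` (9 compartments) or `"full"` (125).
#' @param mechanisms mechanism source name.
#' @param n_medial,n_lateral synapse counts.
#' @param baseline_weight uniform starting weight (uS); `NULL` runs the
#'   calibration routine once and reuses the result for all runs.
#' @param params a [plasticity_params()].
#' @param channel_block `NULL`, or `list(channels=, layers=, at=)` where
#'   `at` is a time (ms) or `"hfs_onset"`.
#' @param lateral_off_at `NULL`, a time (ms), or `"hfs_onset"`: drop all
#'   lateral spikes from that time on.
#' @param snapshot_ms interval between weight/amplitude snapshots (ms).
#' @param probes optional probe locations recorded during the run
#'   (see [integrate_cell()]); sampled every `probe_stride` steps.
#' @param probe_stride probe sampling stride (steps).
#' @param record_events keep the per-compartment postsynaptic event log.
#' @return an `experiment_spec` list.
#' @export
experiment_spec <- function(protocol = "400-DBS", tetanized_fraction = 0.6,
                            noise = 0.05, isi0 = 125, dt = 0.2,
                            warmup_ms = NULL, baseline_ms = 120000,
                            post_ms = 600000, final_window_ms = 120000,
                            n_runs = 3L, seeds = NULL,
                            morphology = "reduced",
                            mechanisms = "fallback-hh",
                            n_medial = 150L, n_lateral = 150L,
                            baseline_weight = NULL,
                            params = plasticity_params(),
                            channel_block = NULL, lateral_off_at = NULL,
                            snapshot_ms = 1000, probes = NULL,
                            probe_stride = 5L, record_events = FALSE) {
  stopifnot(n_runs >= 1L, baseline_ms > 0, post_ms > 0)
  if (is.character(protocol)) {
    protocol <- protocol_preset(protocol, tetanized_fraction)
  } else if (inherits(protocol, "protocol_spec")) {
    protocol$tetanized_fraction <- tetanized_fraction
  }
  if (is.null(warmup_ms)) warmup_ms <- params$tau_c * 1000
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  structure(list(
    protocol = protocol, tetanized_fraction = tetanized_fraction,
    noise = noise, isi0 = isi0, dt = dt,
    warmup_ms = warmup_ms, baseline_ms = baseline_ms, post_ms = post_ms,
    final_window_ms = final_window_ms,
    n_runs = as.integer(n_runs), seeds = as.integer(seeds),
    morphology = morphology, mechanisms = mechanisms,
    n_medial = as.integer(n_medial), n_lateral = as.integer(n_lateral),
    baseline_weight = baseline_weight, params = params,
    channel_block = channel_block, lateral_off_at = lateral_off_at,
    snapshot_ms = snapshot_ms, probes = probes,
    probe_stride = as.integer(probe_stride),
    record_events = record_events
  ), class = "experiment_spec")
}

# Build the channel-block schedule matrix consumed by the engine.
block_schedule_matrix <- function(channel_block, t_hfs) {
  if (is.null(channel_block)) return(NULL)
  at <- channel_block$at
  t <- if (identical(at, "hfs_onset")) t_hfs else as.numeric(at)
  chans <- resolve_channels(channel_block$channels)
  rows <- expand.grid(chan = match(chans, CHANNELS) - 1L,
                      layer = layer_index(channel_block$layers))
  cbind(t, rows$chan, rows$layer, 0)
}

#' Run a closed-loop plasticity experiment
#'
#' Executes every replicate of an [experiment_spec()]: builds the cell,
#' calibrates (or applies) the baseline weight, assembles the afferent
#' drive, runs the engine with plasticity active after warm-up, and wraps
#' each run in a `simulation_result`.
#'
#' @param spec an [experiment_spec()].
#' @param quiet suppress progress messages.
#' @return a `simulation_batch`: list of `simulation_result` objects (one
#'   per run) with the shared manifest as an attribute.
#' @export
run_experiment <- function(spec, quiet = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  morph <- gc_morphology(ifelse(spec$morphology == "full", "full", "reduced"))
  mech <- mechanism_source(spec$mechanisms)
  cell0 <- build_cell(morph, mech)

  t_hfs <- spec$warmup_ms + spec$baseline_ms
  span <- if (is.null(spec$protocol)) 0 else protocol_span(spec$protocol)
  t_stop <- t_hfs + span + spec$post_ms

  # one calibration per experiment, reused across runs, recorded in the
  # manifest
  cal <- NULL
  w0 <- spec$baseline_weight
  if (is.null(w0)) {
    cell_cal <- attach_synapses(cell0, spec$n_medial, spec$n_lateral,
                                weight = 1e-3, seed = spec$seeds[1])
    cal <- calibrate_baseline_weight(cell_cal, dt = spec$dt,
                                     seed = spec$seeds[1] + 9000L)
    w0 <- cal$weight
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dentatestdp")),
    protocol = if (is.null(spec$protocol)) "none" else spec$protocol$name,
    tetanized_fraction = spec$tetanized_fraction,
    noise = spec$noise, isi0 = spec$isi0, dt = spec$dt,
    warmup_ms = spec$warmup_ms, baseline_ms = spec$baseline_ms,
    post_ms = spec$post_ms, final_window_ms = spec$final_window_ms,
    t_hfs = t_hfs, t_stop = t_stop,
    morphology = morph$mode, mechanism_source = mech$name,
    n_medial = spec$n_medial, n_lateral = spec$n_lateral,
    baseline_weight = w0,
    calibrated = is.null(spec$baseline_weight),
    calibration_rate = if (!is.null(cal)) cal$rate else NA_real_,
    params = unclass(spec$params),
    channel_block = spec$channel_block,
    lateral_off_at = spec$lateral_off_at,
    seeds = spec$seeds
  )

  runs <- lapply(spec$seeds, function(seed) {
    if (!quiet) message("run seed ", seed)
    cell <- attach_synapses(cell0, spec$n_medial, spec$n_lateral,
                            weight = w0, seed = seed)
    spont <- spike_train_spec(isi0 = spec$isi0, noise = spec$noise,
                              t_start = 0, t_end = t_stop)
    lat_off <- spec$lateral_off_at
    if (identical(lat_off, "hfs_onset")) lat_off <- t_hfs
    streams <- assemble_drive(cell, spont, protocol = spec$protocol,
                              t0 = t_hfs, lateral_off_at = lat_off,
                              seed = seed, dt = spec$dt)
    sched <- block_schedule_matrix(spec$channel_block, t_hfs)
    out <- run_engine(cell, streams, t_stop = t_stop, dt = spec$dt,
                      params = spec$params, plasticity = TRUE,
                      warmup_ms = spec$warmup_ms,
                      probes = spec$probes,
                      probe_stride = spec$probe_stride,
                      snapshot_ms = spec$snapshot_ms,
                      record_events = spec$record_events,
                      block_schedule = sched)
    new_simulation_result(out, cell, streams, manifest, seed)
  })
  structure(runs, class = "simulation_batch", manifest = manifest)
}

new_simulation_result <- function(out, cell, streams, manifest, seed) {
  ns <- out$n_snap
  snap_t <- out$snap_times[seq_len(ns)]
  W <- out$W[seq_len(ns), , drop = FALSE]
  # baseline = weight at protocol onset
  base_idx <- max(which(snap_t <= manifest$t_hfs))
  res <- list(
    seed = seed,
    synapses = cell$synapses,
    tetanized = tetanized_ids(streams),
    snap_times = snap_t,
    W = W,
    w_baseline = W[base_idx, ],
    w_final = out$w_final,
    homeostasis = tibble::tibble(
      time_ms = snap_t,
      c_avg = out$snap_c[seq_len(ns)],
      a_p = out$snap_ap[seq_len(ns)],
      a_d = out$snap_ad[seq_len(ns)]
    ),
    soma_spikes = out$soma_spikes,
    post_events = if (length(out$post_event_time)) {
      tibble::tibble(comp = out$post_event_comp, time_ms = out$post_event_time)
    } else NULL,
    probes = if (out$n_rec > 0) {
      list(times = out$probe_times[seq_len(out$n_rec)],
           V = out$V[seq_len(out$n_rec), , drop = FALSE],
           comp = out$probe_comp)
    } else NULL,
    manifest = manifest
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$manifest
  cat("<simulation_result> seed ", x$seed, ", protocol ", m$protocol,
      " (", round(m$tetanized_fraction * 100), "% tetanized), ",
      length(x$soma_spikes), " somatic spikes, mechanisms ",
      m$mechanism_source, "\n", sep = "")
  invisible(x)
}

#' @export
print.simulation_batch <- function(x, ...) {
  m <- attr(x, "manifest")
  cat("<simulation_batch> ", length(x), " runs, protocol ", m$protocol,
      ", mechanisms ", m$mechanism_source, "\n", sep = "")
  invisible(x)
}

# Per-synapse percent change of one run: final-window mean vs baseline.
synapse_changes <- function(result, final_window_ms = NULL) {
  m <- result$manifest
  if (is.null(final_window_ms)) final_window_ms <- m$final_window_ms
  t_end <- max(result$snap_times)
  sel <- result$snap_times >= t_end - final_window_ms
  w_fin <- colMeans(result$W[sel, , drop = FALSE])
  tibble::tibble(
    synapse_id = result$synapses$id,
    pathway = result$synapses$pathway,
    path_dist = result$synapses$path_dist,
    tetanized = result$synapses$id %in% result$tetanized,
    w_baseline = result$w_baseline,
    pct_change = (w_fin - result$w_baseline) / result$w_baseline * 100
  )
}

#' Pathway-level weight change
#'
#' For each run and pathway: the mean over that pathway's synapses of the
#' percent weight change relative to the pre-stimulation baseline (the
#' weight at protocol onset), with the final weight averaged over the last
#' `final_window_ms` of the run.  Across runs the per-run means are
#' summarised as mean +/- SD.
#'
#' @param results a `simulation_batch` or a single `simulation_result`.
#' @param pathways pathways to report.
#' @param final_window_ms measurement window (ms); `NULL` uses the spec's.
#' @return tibble: pathway, mean_pct, sd_pct, n_runs.
#' @export
measure_pathway_change <- function(results,
                                   pathways = c("medial", "lateral"),
                                   final_window_ms = NULL) {
  if (inherits(results, "simulation_result")) results <- list(results)
  per_run <- purrr::map_dfr(seq_along(results), function(i) {
    ch <- synapse_changes(results[[i]], final_window_ms)
    ch %>%
      dplyr::filter(.data$pathway %in% pathways) %>%
      dplyr::group_by(.data$pathway) %>%
      dplyr::summarise(run_mean = mean(.data$pct_change), .groups = "drop") %>%
      dplyr::mutate(run = i)
  })
  if (nrow(per_run) == 0L) rlang::abort("empty pathway selection")
  per_run %>%
    dplyr::group_by(.data$pathway) %>%
    dplyr::summarise(
      mean_pct = mean(.data$run_mean),
      sd_pct = if (dplyr::n() > 1) stats::sd(.data$run_mean) else 0,
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' Weight change versus distance from the soma
#'
#' Per-synapse percent weight change against path distance from the soma,
#' with Pearson correlations computed separately within the tetanized and
#' non-tetanized groups.  Degenerate groups (no variance in either
#' variable) are reported as r = 0 with `degenerate = TRUE`.
#'
#' @param result a `simulation_result`.
#' @param final_window_ms measurement window (ms).
#' @return list with `points` (tibble: synapse_id, pathway, tetanized,
#'   path_dist, pct_change) and `correlations` (tibble: group, r, n,
#'   degenerate).
#' @export
weight_vs_distance <- function(result, final_window_ms = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  pts <- synapse_changes(result, final_window_ms)
  cors <- pts %>%
    dplyr::mutate(group = ifelse(.data$tetanized, "tetanized", "non-tetanized")) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      degenerate = stats::sd(.data$pct_change) == 0 || stats::sd(.data$path_dist) == 0,
      r = ifelse(.data$degenerate[1], 0,
                 stats::cor(.data$path_dist, .data$pct_change)),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(list(points = pts, correlations = cors),
            class = "weight_distance")
}
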