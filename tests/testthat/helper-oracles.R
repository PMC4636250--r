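# Independent oracles and shared fixtures for the suite.

# Brute-force nearest-neighbour pairing: for one presynaptic spike, scan
# all postsynaptic events.
brute_pair <- function(pre, posts) {
  before <- posts[posts <= pre]
  after <- posts[posts > pre]
  c(dt_before = if (length(before)) max(before) - pre else NA_real_,
    dt_after = if (length(after)) min(after) - pre else NA_real_)
}

# Brute-force evaluation of the spike-average integral: direct summation of
# the exponentially weighted per-step indicator.
brute_spike_average <- function(spike_steps, n_steps, dt, tau_c_s, alpha, c0 = 0) {
  tau_ms <- tau_c_s * 1000
  spike <- logical(n_steps)
  spike[spike_steps] <- TRUE
  c_out <- numeric(n_steps)
  cc <- c0
  dec <- exp(-dt / tau_ms)
  inc <- (alpha / tau_ms) * dt
  for (k in seq_len(n_steps)) {
    cc <- cc * dec + if (spike[k]) inc else 0
    c_out[k] <- cc
  }
  c_out
}

# Direct summation of the integral at a single query step (no recursion).
brute_c_at <- function(spike_steps, k, dt, tau_c_s, alpha) {
  tau_ms <- tau_c_s * 1000
  s <- spike_steps[spike_steps <= k]
  (alpha / tau_ms) * dt * sum(exp(-((k - s) * dt) / tau_ms))
}

# Brute-force weight evaluation with *frozen* amplitudes: enumerate every
# presynaptic spike's nearest neighbours, then apply all contributions.
brute_weights_frozen <- function(pre, posts, w0, a_p, a_d, tau_p, tau_d,
                                 lapse = 5 * tau_p) {
  w <- w0
  for (tp in pre) {
    nn <- brute_pair(tp, posts)
    if (!is.na(nn["dt_after"]) && nn["dt_after"] > 0 &&
        nn["dt_after"] <= lapse) {
      w <- w * (1 + a_p * exp(-nn["dt_after"] / tau_p))
    }
    if (!is.na(nn["dt_before"]) && nn["dt_before"] < 0) {
      w <- w * (1 - a_d * exp(nn["dt_before"] / tau_d))
    }
  }
  unname(w)
}

# Shared cells (cheap to build)
reduced_cell <- function() {
  build_cell(gc_morphology("reduced"), mechanism_source("fallback-hh"))
}

# One calibration shared across the suite.
.fixtures <- new.env(parent = emptyenv())
calibrated_weight <- function() {
  if (is.null(.fixtures$w_cal)) {
    cell <- attach_synapses(reduced_cell(), 150, 150, weight = 1e-3, seed = 1)
    cal <- calibrate_baseline_weight(cell, seed = 9001)
    .fixtures$w_cal <- cal
  }
  .fixtures$w_cal
}

# Heavy closed-loop batches shared by several acceptance checks: the three
# protocols at 60% tetanization, 3 seeds each, at the study conditions.
ordering_batches <- function() {
  if (is.null(.fixtures$ordering)) {
    .fixtures$ordering <- lapply(
      c("400-DBS" = "400-DBS", "400-TBS" = "400-TBS", "100-TBS" = "100-TBS"),
      function(p) {
        run_experiment(experiment_spec(p, tetanized_fraction = 0.6,
                                       n_runs = 3))
      })
  }
  .fixtures$ordering
}

# Matched pair for the lateral-silencing control (100% tetanization).
lateral_pair <- function() {
  if (is.null(.fixtures$lateral)) {
    .fixtures$lateral <- list(
      off = run_experiment(experiment_spec("400-DBS", tetanized_fraction = 1,
                                           lateral_off_at = "hfs_onset",
                                           n_runs = 1)),
      on = run_experiment(experiment_spec("400-DBS", tetanized_fraction = 1,
                                          n_runs = 1))
    )
  }
  .fixtures$lateral
}

onset_times <- function(batch, threshold_pct = 5) {
  tc <- pathway_timecourse(batch)
  agg <- stats::aggregate(mean_pct ~ time_ms + pathway, data = tc, FUN = mean)
  med <- agg$time_ms[agg$pathway == "medial" & agg$mean_pct > 100 + threshold_pct]
  lat <- agg$time_ms[agg$pathway == "lateral" & agg$mean_pct < 100 - threshold_pct]
  c(medial = if (length(med)) min(med) else NA_real_,
    lateral = if (length(lat)) min(lat) else NA_real_)
}
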