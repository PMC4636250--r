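#' Parameters of the STDP rule with fast BCM-like metaplasticity
#'
#' The weight of a synapse evolves under a presynaptically centered
#' nearest-neighbour pair rule,
#' `w <- w * (1 + dw_p - dw_d)`, with
#' `dw_p = A_p * exp(-dt/tau_p)` for the earliest postsynaptic event after
#' the presynaptic spike (`dt = t_post - t_pre > 0`) and
#' `dw_d = A_d * exp(dt/tau_d)` for the latest postsynaptic event before it
#' (`dt < 0`).  A simultaneous pair (`dt = 0`) contributes to neither
#' window.  The amplitudes are not fixed: they slide homeostatically with
#' the exponentially weighted average somatic spike count `<c>`,
#' `A_p(t) = A_p0 / <c>` and `A_d(t) = A_d0 * <c>`, so their product is
#' conserved.  `<c>` integrates somatic spikes with period `tau_c` and
#' scale `alpha`.
#'
#' @param a_p0,a_d0 initial potentiation / depression amplitudes
#'   (dimensionless weight fractions; defaults 0.003 and 0.001, a 3:1 ratio).
#' @param tau_p,tau_d STDP window time constants (ms; defaults 20 and 70).
#' @param tau_c integration period of the spike average (seconds, default 60).
#' @param alpha scale of the spike average.  `NULL` (default) keeps
#'   `alpha * dt` fixed at 500 ms, i.e. `alpha` = 2500 at dt = 0.2 ms and
#'   5000 at dt = 0.1 ms, making `<c>` invariant to the step size.
#' @param v_syn_thresh dendritic voltage threshold (mV) defining the local
#'   postsynaptic event for pairing (default -37).
#' @param v_soma_thresh somatic spike threshold (mV) feeding `<c>`
#'   (default 0).
#' @param max_change hard bound on relative weight change (default 1 =
#'   100 %), applied symmetrically about the baseline weight.
#' @param c_floor lower floor on `<c>` keeping `A_p` finite at start-up.
#' @param debounce minimum separation (ms) between successive postsynaptic
#'   events at one site (one action potential width).
#' @param c0 initial value of `<c>` (default 1, the baseline steady state
#'   for a 2 Hz somatic rate at the default `alpha * dt`).
#' @param freeze_ap,freeze_ad if `TRUE`, hold the corresponding amplitude at
#'   its initial value (homeostasis-off controls).
#' @return a `plasticity_params` list.
#' @export
plasticity_params <- function(a_p0 = 0.003, a_d0 = 0.001,
                              tau_p = 20, tau_d = 70,
                              tau_c = 60, alpha = NULL,
                              v_syn_thresh = -37, v_soma_thresh = 0,
                              max_change = 1, c_floor = 1e-3,
                              debounce = 5, c0 = 1,
                              freeze_ap = FALSE, freeze_ad = FALSE) {
  stopifnot(a_p0 > 0, a_d0 > 0, tau_p > 0, tau_d > 0, tau_c > 0,
            max_change > 0, c_floor > 0, debounce >= 0, c0 >= 0)
  structure(list(a_p0 = a_p0, a_d0 = a_d0, tau_p = tau_p, tau_d = tau_d,
                 tau_c = tau_c, alpha = alpha,
                 v_syn_thresh = v_syn_thresh, v_soma_thresh = v_soma_thresh,
                 max_change = max_change, c_floor = c_floor,
                 debounce = debounce, c0 = c0,
                 freeze_ap = freeze_ap, freeze_ad = freeze_ad),
            class = "plasticity_params")
}

# Effective alpha for a given integration step: alpha * dt is held constant
# (500 ms at the defaults) so the spike average is invariant to dt.
effective_alpha <- function(params, dt) {
  if (is.null(params$alpha)) 500 / dt else params$alpha
}

#' Detect threshold-crossing events in a voltage trace
#'
#' Returns the times at which a uniformly sampled membrane potential crosses
#' `threshold` from below (rising edges), linearly interpolated between
#' samples.  Successive events closer than `debounce` ms are collapsed onto
#' the first, so one depolarization is not counted repeatedly.
#'
#' @param time sample times (ms), uniformly spaced.
#' @param v membrane potential (mV); must be finite.
#' @param threshold crossing threshold (mV).
#' @param debounce minimum event separation (ms).
#' @return numeric vector of event times (ms), strictly increasing.
#' @export
detect_events <- function(time, v, threshold, debounce = 5) {
  if (any(!is.finite(v))) rlang::abort("non-finite samples in voltage trace")
  n <- length(v)
  if (n < 2L) return(numeric(0))
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1L] - v[up])
  t_ev <- time[up] + frac * (time[up + 1L] - time[up])
  if (debounce > 0 && length(t_ev) > 1L) {
    keep <- rep(TRUE, length(t_ev))
    last <- t_ev[1L]
    for (i in seq_along(t_ev)[-1L]) {
      if (t_ev[i] - last < debounce) keep[i] <- FALSE else last <- t_ev[i]
    }
    t_ev <- t_ev[keep]
  }
  t_ev
}

#' One-step update of the average postsynaptic spike count
#'
#' Exponential-decay recursion exactly equivalent to the defining integral
#' of `<c>` with a per-step spike indicator:
#' `<c> <- <c> * exp(-dt/tau_c) + (alpha/tau_c) * dt * spike`.
#' For constant-rate spiking at `r` Hz the steady state is
#' `alpha * dt * r / 1000`, i.e. 1.0 at the defaults (alpha = 2500,
#' dt = 0.2 ms, 2 Hz).
#'
#' @param c_prev current `<c>` (>= 0).
#' @param spike logical/0-1 indicator: somatic spike in this step.
#' @param dt integration step (ms).
#' @param tau_c integration period (seconds).
#' @param alpha scaling constant.
#' @return updated `<c>`.
#' @export
update_spike_average <- function(c_prev, spike, dt, tau_c = 60, alpha = 2500) {
  stopifnot(c_prev >= 0)
  tau_ms <- tau_c * 1000
  c_prev * exp(-dt / tau_ms) + (alpha / tau_ms) * dt * as.numeric(spike)
}

#' Homeostatic amplitudes from the spike average
#'
#' `A_p = A_p0 / max(<c>, c_floor)` and `A_d = A_d0 * max(<c>, c_floor)`:
#' high average firing shrinks the potentiation amplitude and grows the
#' depression amplitude, and vice versa.  The product `A_p * A_d` is
#' conserved at `A_p0 * A_d0`.
#'
#' @param c_avg current `<c>` (>= 0).
#' @param params a [plasticity_params()].
#' @return named numeric vector `c(a_p = , a_d = )`.
#' @export
update_amplitudes <- function(c_avg, params = plasticity_params()) {
  stopifnot(c_avg >= 0)
  cc <- max(c_avg, params$c_floor)
  a_p <- if (params$freeze_ap) params$a_p0 else params$a_p0 / cc
  a_d <- if (params$freeze_ad) params$a_d0 else params$a_d0 * cc
  c(a_p = a_p, a_d = a_d)
}

#' Presynaptically centered nearest-neighbour pairing
#'
#' For each presynaptic spike, only two postsynaptic events are considered:
#' the latest one at or before the spike and the earliest one strictly
#' after it.  Postsynaptic events are not consumed — one event may be the
#' nearest neighbour of several presynaptic spikes.
#'
#' @param pre_times presynaptic spike times (ms).
#' @param post_times sorted postsynaptic event times (ms).
#' @return tibble with one row per presynaptic spike: `pre`, `dt_before`
#'   (`t_post - t_pre <= 0`, `NA` if no earlier event) and `dt_after`
#'   (`> 0`, `NA` if no later event).
#' @examples
#' pair_nearest_neighbor(100, c(90, 130)) # dt_before -10, dt_after +30
#' @export
pair_nearest_neighbor <- function(pre_times, post_times) {
  post_times <- sort(post_times)
  idx <- findInterval(pre_times, post_times)
  dt_before <- ifelse(idx >= 1L, post_times[pmax(idx, 1L)] - pre_times, NA_real_)
  after_idx <- idx + 1L
  dt_after <- ifelse(after_idx <= length(post_times),
                     post_times[pmin(after_idx, length(post_times))] - pre_times,
                     NA_real_)
  tibble::tibble(pre = pre_times, dt_before = dt_before, dt_after = dt_after)
}

#' Apply one nearest-neighbour STDP update to a weight
#'
#' @param w current weight (> 0).
#' @param dt_before `t_post - t_pre` of the preceding event (<= 0 or `NA`).
#' @param dt_after `t_post - t_pre` of the following event (> 0 or `NA`).
#' @param a_p,a_d current amplitudes.
#' @param tau_p,tau_d window time constants (ms).
#' @param w0 baseline weight defining the hard bounds.
#' @param max_change relative bound (1 = 100 %).
#' @return updated weight, clamped to
#'   `[w0 * (1 - max_change), w0 * (1 + max_change)]` and kept positive.
#' @export
apply_weight_update <- function(w, dt_before = NA, dt_after = NA,
                                a_p = 0.003, a_d = 0.001,
                                tau_p = 20, tau_d = 70,
                                w0 = w, max_change = 1) {
  stopifnot(w > 0)
  dw_p <- if (!is.na(dt_after) && dt_after > 0) a_p * exp(-dt_after / tau_p) else 0
  dw_d <- if (!is.na(dt_before) && dt_before < 0) a_d * exp(dt_before / tau_d) else 0
  clamp_weight(w * (1 + dw_p - dw_d), w0, max_change)
}

clamp_weight <- function(w, w0, max_change) {
  lo <- max(w0 * (1 - max_change), w0 * 1e-9)
  hi <- w0 * (1 + max_change)
  pmin(hi, pmax(lo, w))
}

#' Standalone event-driven evaluation of the plasticity rule
#'
#' Runs the full STDP + metaplasticity rule over externally supplied event
#' streams, without the biophysical cell: presynaptic spikes per synapse,
#' local postsynaptic threshold-crossing events per synapse, and global
#' somatic spike times.  Semantics match the closed-loop engine exactly:
#' `<c>` and the amplitudes advance on the dt grid (an event inside a step
#' takes the amplitudes current at that step's end), pair intervals use the
#' exact event times, the depression term of a presynaptic spike applies
#' immediately, the potentiation term applies when the next postsynaptic
#' event arrives (or lapses after `5 * tau_p` without one), and no update is
#' applied during the warm-up period.
#'
#' @param pre_streams data frame `(synapse_id, time_ms)` of presynaptic
#'   spikes (e.g. an [assemble_drive()] result or [read_event_streams()]).
#' @param post_streams data frame `(synapse_id, time_ms)` of local
#'   postsynaptic events per synapse.
#' @param somatic_spikes numeric vector of somatic spike times (ms).
#' @param params a [plasticity_params()].
#' @param dt integration step (ms).
#' @param t_end end of the evaluation window (ms).
#' @param w0 named or plain numeric vector of baseline weights, one per
#'   synapse id appearing in the streams (recycled if scalar).
#' @param warmup_ms no weight updates before this time (default
#'   `tau_c * 1000`).
#' @param record_every if not `NULL`, also return per-step-free time series
#'   of `<c>`, `A_p`, `A_d` sampled every `record_every` ms.
#' @return list with `weights` (tibble: synapse_id, w0, w_final),
#'   `n_updates`, and optionally `series` (tibble: time_ms, c_avg, a_p, a_d).
#' @export
run_plasticity_offline <- function(pre_streams, post_streams, somatic_spikes,
                                   params = plasticity_params(), dt = 0.2,
                                   t_end = NULL, w0 = 1,
                                   warmup_ms = params$tau_c * 1000,
                                   record_every = NULL) {
  ids <- sort(unique(c(pre_streams$synapse_id, post_streams$synapse_id)))
  nid <- length(ids)
  idmap <- setNames(seq_len(nid), ids)
  if (length(w0) == 1L) w0 <- rep(w0, nid)
  stopifnot(length(w0) == nid)
  w <- w0
  alpha <- effective_alpha(params, dt)
  tau_ms <- params$tau_c * 1000
  inc <- alpha * dt / tau_ms
  lapse <- 5 * params$tau_p

  if (is.null(t_end)) {
    t_end <- max(c(pre_streams$time_ms, post_streams$time_ms, somatic_spikes, 0))
  }

  # quantize event times up to the step grid (a spike inside a step enters
  # <c> at the step's end; an update inside a step uses that step's
  # amplitudes); the integer step index is the authoritative clock
  step_of <- function(t) ceiling(t / dt - 1e-9)
  warmup_steps <- round(warmup_ms / dt)
  sp_grid <- sort(step_of(somatic_spikes) * dt)
  c_state <- params$c0
  c_time <- 0
  sp_ptr <- 1L
  c_at <- function(tg) {
    while (sp_ptr <= length(sp_grid) && sp_grid[sp_ptr] <= tg) {
      c_state <<- c_state * exp(-(sp_grid[sp_ptr] - c_time) / tau_ms) + inc
      c_time <<- sp_grid[sp_ptr]
      sp_ptr <<- sp_ptr + 1L
    }
    c_state * exp(-(tg - c_time) / tau_ms)
  }

  # merged event walk: posts type 0 before pres type 1 at equal times
  mk_ev <- function(df, type) {
    data.frame(id = unname(idmap[as.character(df$synapse_id)]),
               t = df$time_ms, type = rep(type, nrow(df)))
  }
  ev <- rbind(mk_ev(post_streams, 0L), mk_ev(pre_streams, 1L))
  ev <- ev[ev$t <= t_end, ]
  ev <- ev[order(ev$t, ev$type), ]

  last_post <- rep(NA_real_, nid)
  pending <- vector("list", nid)
  n_upd <- 0L

  rec_t <- if (!is.null(record_every)) seq(0, t_end, by = record_every) else numeric(0)
  rec <- if (length(rec_t)) {
    tibble::tibble(time_ms = rec_t, c_avg = NA_real_, a_p = NA_real_, a_d = NA_real_)
  } else NULL
  rec_ptr <- 1L

  amp_at <- function(tg) update_amplitudes(c_at(tg), params)

  flush_records <- function(upto) {
    while (rec_ptr <= length(rec_t) && rec_t[rec_ptr] <= upto) {
      cc <- c_at(rec_t[rec_ptr])
      a <- update_amplitudes(cc, params)
      rec$c_avg[rec_ptr] <<- cc
      rec$a_p[rec_ptr] <<- a[["a_p"]]
      rec$a_d[rec_ptr] <<- a[["a_d"]]
      rec_ptr <<- rec_ptr + 1L
    }
  }

  for (k in seq_len(nrow(ev))) {
    i <- ev$id[k]; tk <- ev$t[k]
    if (length(rec_t)) flush_records(tk)
    ks <- step_of(tk)
    tg <- ks * dt
    if (ev$type[k] == 0L) {  # postsynaptic event
      q <- pending[[i]]
      if (length(q) && ks > warmup_steps) {
        a <- amp_at(tg)
        for (qt in q) {
          dta <- tk - qt
          if (dta > 0 && dta <= lapse) {
            w[i] <- clamp_weight(w[i] * (1 + a[["a_p"]] * exp(-dta / params$tau_p)),
                                 w0[i], params$max_change)
            n_upd <- n_upd + 1L
          }
        }
      }
      if (length(q)) pending[[i]] <- q[tk - q <= 0]  # dt = 0 pairs stay pending
      last_post[i] <- tk
    } else {               # presynaptic spike
      lp <- last_post[i]
      if (!is.na(lp) && tk - lp > 0 && ks > warmup_steps) {
        a <- amp_at(tg)
        w[i] <- clamp_weight(w[i] * (1 - a[["a_d"]] * exp(-(tk - lp) / params$tau_d)),
                             w0[i], params$max_change)
        n_upd <- n_upd + 1L
      }
      pending[[i]] <- c(pending[[i]][tk - pending[[i]] <= lapse], tk)
    }
  }
  if (length(rec_t)) flush_records(t_end)

  list(
    weights = tibble::tibble(synapse_id = ids, w0 = w0, w_final = w),
    n_updates = n_upd,
    series = rec
  )
}
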