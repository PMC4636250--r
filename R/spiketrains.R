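#' Specification of a quasi-periodic spontaneous spike train
#'
#' Spontaneous afferent activity follows the NetStim-style quasi-periodic
#' generator: successive inter-spike intervals are drawn i.i.d. as
#' `ISI = (1 - noise) * ISI0 + Exponential(mean = noise * ISI0)`,
#' so the mean ISI is `ISI0` for every noise level.  `noise = 0` gives a
#' perfectly periodic train, `noise = 1` a homogeneous Poisson train, and
#' intermediate values quasi-periodic firing.  Defaults (`ISI0` = 125 ms,
#' `noise` = 0.05) give a lightly jittered 8 Hz train, matching in vivo
#' perforant path activity.
#'
#' @param isi0 mean inter-spike interval (ms), > 0.
#' @param noise jitter fraction in `[0, 1]`.
#' @param t_start,t_end window (ms) over which spikes are generated.
#' @return a `spike_train_spec` list.
#' @export
spike_train_spec <- function(isi0 = 125, noise = 0.05, t_start = 0, t_end = 1000) {
  if (isi0 <= 0) rlang::abort("isi0 must be positive")
  if (noise < 0 || noise > 1) rlang::abort("noise must lie in [0, 1]")
  if (t_end <= t_start) rlang::abort("t_end must exceed t_start")
  structure(list(isi0 = isi0, noise = noise, t_start = t_start, t_end = t_end),
            class = "spike_train_spec")
}

#' Generate a spontaneous presynaptic spike train
#'
#' Draws spike times in `[t_start, t_end)` under a [spike_train_spec()].
#' The first spike falls one ISI draw after `t_start` (no explicit phase
#' variable: trains with a shared `isi0` are phase-locked on average, with
#' independent jitter per train).
#'
#' @param spec a [spike_train_spec()].
#' @param seed optional integer seed; when given, generation is reproducible
#'   and leaves the global RNG state untouched.
#' @return numeric vector of strictly increasing spike times (ms).
#' @examples
#' s <- generate_spontaneous(spike_train_spec(noise = 0), seed = 1)
#' diff(s) # all exactly 125 ms
#' @export
generate_spontaneous <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "spike_train_spec"))
  gen <- function() {
    dur <- spec$t_end - spec$t_start
    # expected count + slack; top up in the rare case the draw falls short
    n_guess <- max(16L, ceiling(dur / spec$isi0 * 1.25) + 10L)
    draw_isi <- function(n) {
      fixed <- (1 - spec$noise) * spec$isi0
      if (spec$noise == 0) rep(fixed, n)
      else fixed + stats::rexp(n, rate = 1 / (spec$noise * spec$isi0))
    }
    isi <- draw_isi(n_guess)
    t <- spec$t_start + cumsum(isi)
    while (t[length(t)] < spec$t_end) {
      isi <- draw_isi(n_guess)
      t <- c(t, t[length(t)] + cumsum(isi))
    }
    t[t < spec$t_end]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Specification of a high-frequency stimulation protocol
#'
#' A protocol is a nested timing structure: `pulses_per_burst` pulses at
#' `intra_burst_freq` within a burst; `bursts_per_train` bursts at
#' `inter_burst_freq` within one train (repeat); `n_repeats` trains
#' separated by `inter_repeat_interval` seconds.
#'
#' @param pulses_per_burst,bursts_per_train,n_repeats counts (>= 1).
#' @param intra_burst_freq,inter_burst_freq frequencies in Hz (> 0).
#' @param inter_repeat_interval interval between train onsets, in seconds.
#' @param tetanized_fraction fraction of the target pathway's synapses that
#'   receive the protocol, in `(0, 1]`.
#' @param pathway target pathway, `"medial"` or `"lateral"`.
#' @param name optional label.
#' @return a `protocol_spec` list.
#' @seealso [protocol_preset()] for the named presets.
#' @export
protocol_spec <- function(pulses_per_burst, intra_burst_freq,
                          bursts_per_train, inter_burst_freq,
                          n_repeats, inter_repeat_interval,
                          tetanized_fraction = 1, pathway = "medial",
                          name = "custom") {
  if (any(c(pulses_per_burst, bursts_per_train, n_repeats) < 1)) {
    rlang::abort("all protocol counts must be >= 1")
  }
  if (any(c(intra_burst_freq, inter_burst_freq) <= 0) ||
      inter_repeat_interval <= 0) {
    rlang::abort("protocol frequencies and intervals must be positive")
  }
  if (tetanized_fraction <= 0 || tetanized_fraction > 1) {
    rlang::abort("tetanized_fraction must lie in (0, 1]")
  }
  burst_dur <- (pulses_per_burst - 1) / intra_burst_freq * 1000
  if (bursts_per_train > 1 && burst_dur >= 1000 / inter_burst_freq) {
    rlang::abort("overlapping bursts: burst duration >= inter-burst interval")
  }
  train_dur <- (bursts_per_train - 1) / inter_burst_freq * 1000 + burst_dur
  if (n_repeats > 1 && train_dur >= inter_repeat_interval * 1000) {
    rlang::abort("overlapping trains: train duration >= inter-repeat interval")
  }
  structure(list(
    name = name,
    pulses_per_burst = as.integer(pulses_per_burst),
    intra_burst_freq = intra_burst_freq,
    bursts_per_train = as.integer(bursts_per_train),
    inter_burst_freq = inter_burst_freq,
    n_repeats = as.integer(n_repeats),
    inter_repeat_interval = inter_repeat_interval,
    tetanized_fraction = tetanized_fraction,
    pathway = pathway
  ), class = "protocol_spec")
}

#' Named high-frequency stimulation presets
#'
#' * `"400-DBS"`: 5 bursts of 10 pulses at 400 Hz, delta (1 Hz) inter-burst
#'   frequency, repeated 10 times at 1 min intervals (500 pulses).
#' * `"100-TBS"`: 10 bursts of 4 pulses at 100 Hz, theta (5 Hz) inter-burst
#'   frequency, repeated 8 times at 10 s intervals (320 pulses).
#' * `"400-TBS"`: as 100-TBS but with a 400 Hz intra-burst frequency
#'   (320 pulses).
#'
#' @param name preset name.
#' @param tetanized_fraction fraction of medial synapses tetanized.
#' @return a [protocol_spec()].
#' @export
protocol_preset <- function(name = c("400-DBS", "100-TBS", "400-TBS"),
                            tetanized_fraction = 1) {
  name <- match.arg(name)
  switch(name,
    "400-DBS" = protocol_spec(10, 400, 5, 1, 10, 60,
                              tetanized_fraction, "medial", name),
    "100-TBS" = protocol_spec(4, 100, 10, 5, 8, 10,
                              tetanized_fraction, "medial", name),
    "400-TBS" = protocol_spec(4, 400, 10, 5, 8, 10,
                              tetanized_fraction, "medial", name)
  )
}

#' Deterministic pulse times of a protocol
#'
#' @param spec a [protocol_spec()].
#' @param t0 onset of the first pulse (ms).
#' @return numeric vector of pulse times (ms), strictly increasing.
#' @examples
#' length(build_protocol(protocol_preset("400-DBS"))) # 500
#' @export
build_protocol <- function(spec, t0 = 0) {
  stopifnot(inherits(spec, "protocol_spec"))
  pulse <- (seq_len(spec$pulses_per_burst) - 1) / spec$intra_burst_freq * 1000
  burst <- (seq_len(spec$bursts_per_train) - 1) / spec$inter_burst_freq * 1000
  rep_on <- (seq_len(spec$n_repeats) - 1) * spec$inter_repeat_interval * 1000
  t0 + as.vector(outer(pulse, outer(burst, rep_on, "+"), "+")) |> sort()
}

# Total span of a protocol from first to last pulse (ms).
protocol_span <- function(spec) {
  p <- build_protocol(spec, 0)
  p[length(p)] - p[1]
}

#' Assemble per-synapse afferent event streams
#'
#' Every synapse receives its own independent spontaneous train.  If a
#' protocol is given, a seeded random subset of the target pathway's
#' synapses (of size `tetanized_fraction * n`) additionally receives all
#' protocol pulses, merged into its stream.  Spontaneous activity is
#' maintained throughout; spikes landing within one integration step at the
#' same synapse are merged into a single spike.  If `lateral_off_at` is set,
#' all lateral path spikes after that time are removed (the
#' "no lateral activity" control).
#'
#' @param synapses synapse table from [attach_synapses()] (or a `gc_cell`).
#' @param spont_spec a [spike_train_spec()] covering the run window.
#' @param protocol a [protocol_spec()] or `NULL`.
#' @param t0 protocol onset time (ms).
#' @param lateral_off_at time (ms) after which lateral spikes are dropped,
#'   or `NULL`.
#' @param seed integer seed governing the spontaneous trains and the
#'   tetanized-subset draw.
#' @param dt integration step (ms), used as the merge window.
#' @return an `event_streams` object: a tibble `(synapse_id, time_ms)` of
#'   all presynaptic spikes plus a `tetanized` attribute flagging tetanized
#'   synapse ids.
#' @export
assemble_drive <- function(synapses, spont_spec, protocol = NULL, t0 = 0,
                           lateral_off_at = NULL, seed = 1L, dt = 0.2) {
  if (inherits(synapses, "gc_cell")) synapses <- synapses$synapses
  stopifnot(is.data.frame(synapses), inherits(spont_spec, "spike_train_spec"))
  n_syn <- nrow(synapses)
  trains <- withr::with_seed(seed, {
    lapply(seq_len(n_syn), function(i) generate_spontaneous(spont_spec))
  })

  tet_ids <- integer(0)
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "protocol_spec"))
    target <- synapses$id[synapses$pathway == protocol$pathway]
    if (protocol$pathway == "lateral") {
      rlang::warn("protocol targets the lateral pathway; flagged but allowed")
    }
    n_tet <- round(protocol$tetanized_fraction * length(target))
    if (n_tet < 1L) rlang::abort("tetanized fraction resolves to zero synapses")
    tet_ids <- withr::with_seed(seed + 1L, sort(sample(target, n_tet)))
    pulses <- build_protocol(protocol, t0)
    idx <- match(tet_ids, synapses$id)
    for (i in idx) trains[[i]] <- sort(c(trains[[i]], pulses))
  }

  if (!is.null(lateral_off_at)) {
    lat <- which(synapses$pathway == "lateral")
    for (i in lat) trains[[i]] <- trains[[i]][trains[[i]] < lateral_off_at]
  }

  # merge events closer than one integration step at the same synapse
  trains <- lapply(trains, function(t) {
    if (length(t) < 2L) return(t)
    t[c(TRUE, diff(t) >= dt)]
  })

  streams <- tibble::tibble(
    synapse_id = rep(synapses$id, lengths(trains)),
    time_ms = unlist(trains)
  )
  structure(streams, class = c("event_streams", class(streams)),
            tetanized = tet_ids, dt = dt)
}

#' Tetanized synapse ids of an event stream
#' @param streams an `event_streams` object.
#' @return integer vector of synapse ids that received the protocol.
#' @export
tetanized_ids <- function(streams) attr(streams, "tetanized")

#' Write / read event streams as two-column text
#'
#' Plain-text round trip `(synapse_id, time_ms)` so the plasticity core can
#' be exercised standalone on externally supplied spike trains.
#'
#' @param streams an `event_streams` tibble (or any data frame with columns
#'   `synapse_id`, `time_ms`).
#' @param path file path.
#' @return `read_event_streams()` returns the tibble.
#' @export
write_event_streams <- function(streams, path) {
  utils::write.table(streams[, c("synapse_id", "time_ms")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_streams
#' @export
read_event_streams <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  tibble::as_tibble(df[order(df$synapse_id, df$time_ms), ])
}
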