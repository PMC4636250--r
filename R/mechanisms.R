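#' Load a membrane mechanism parameter set
#'
#' Membrane mechanisms (channel conductance densities, reversal potentials,
#' passive properties, calcium pool parameters) are parameter data, kept in
#' a registry of flat JSON files shipped with the package, one file per
#' named source.  Two sources are registered:
#'
#' * `"fallback-hh"` (default): a simplified Hodgkin-Huxley-style set
#'   authored for this package — sodium and delayed-rectifier potassium in
#'   soma and dendrites, plus a generic high-threshold calcium channel and
#'   an SK-type calcium-activated potassium channel in the dendrites.  It is
#'   calibrated for qualitative work: stable rest near -75 mV, somatic
#'   spiking with refractoriness, and active back-propagation that crosses
#'   the dendritic plasticity threshold in the outer molecular layer.
#' * `"modeldb-51781"`: a best-effort transcription of the granule-cell
#'   channel densities of the Santhakumar et al. (2005) dentate gyrus model
#'   (ModelDB accession 51781, the cell model of Aradi & Holmes 1998).
#'   Channel kinetics are represented by this package's channel forms with
#'   matched activation ranges, so this source is quantitative only to the
#'   fidelity of that transcription.
#'
#' The active source name is recorded in every run manifest.
#'
#' @param source a registered source name, or a path to a JSON file with the
#'   same schema (see the packaged files under `extdata/mechanisms/`).
#' @return An object of class `mechanism_set`.
#' @examples
#' mech <- mechanism_source("fallback-hh")
#' mech$densities["na", "soma"]
#' @export
mechanism_source <- function(source = "fallback-hh") {
  path <- if (file.exists(source)) {
    source
  } else {
    system.file("extdata", "mechanisms", paste0(source, ".json"),
                package = "dentatestdp")
  }
  if (!nzchar(path) || !file.exists(path)) {
    rlang::abort(paste0("unresolvable mechanism source: ", source))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dens <- matrix(0, nrow = length(CHANNELS), ncol = length(LAYERS),
                 dimnames = list(CHANNELS, LAYERS))
  for (ch in names(raw$densities_S_cm2)) {
    if (!ch %in% CHANNELS) {
      rlang::abort(paste0("unknown channel in mechanism file: ", ch))
    }
    v <- raw$densities_S_cm2[[ch]]
    dens[ch, names(v)] <- unlist(v)
  }
  gl <- raw$passive$g_leak_S_cm2
  gl_vec <- if (length(gl) == 1L && is.null(names(gl))) {
    setNames(rep(unlist(gl), length(LAYERS)), LAYERS)
  } else {
    out <- setNames(rep(NA_real_, length(LAYERS)), LAYERS)
    out[names(gl)] <- unlist(gl)
    out
  }
  vshift <- setNames(rep(0, length(CHANNELS)), CHANNELS)
  if (!is.null(raw$vshift_mV)) vshift[names(raw$vshift_mV)] <- unlist(raw$vshift_mV)
  structure(list(
    name = raw$name,
    description = raw$description,
    cm = raw$passive$cm_uF_cm2,
    Ra = raw$passive$Ra_ohm_cm,
    g_leak = gl_vec,
    e_leak = raw$passive$e_leak_mV,
    reversals = unlist(raw$reversals_mV),
    ca_pool = raw$ca_pool,
    na_h_scale = if (!is.null(raw$kinetics$na_h_scale)) raw$kinetics$na_h_scale else 1,
    na_h_shift = if (!is.null(raw$kinetics$na_h_shift)) raw$kinetics$na_h_shift else 0,
    vshift = vshift,
    densities = dens
  ), class = "mechanism_set")
}

#' @export
print.mechanism_set <- function(x, ...) {
  cat("<mechanism_set> ", x$name, "\n", sep = "")
  cat(" ", x$description, "\n", sep = "")
  invisible(x)
}

# Resolve user-facing channel names (case-insensitive, with the "ca" group
# meaning all three calcium channel types) to roster names.
resolve_channels <- function(channels) {
  out <- character(0)
  for (ch in channels) {
    key <- tolower(ch)
    if (key == "ca") {
      out <- c(out, "cat", "can", "cal")
    } else if (key %in% CHANNELS) {
      out <- c(out, key)
    } else {
      rlang::abort(paste0("unknown channel name: ", ch,
                          " (known: ", paste(CHANNELS, collapse = ", "), ", ca)"))
    }
  }
  unique(out)
}

#' Block or restore channels in chosen layers
#'
#' Sets the conductance densities of the named channels to zero in the named
#' layers (`active = FALSE`), or restores them to their mechanism-set values
#' (`active = TRUE`).  The change applies from the next integration step; to
#' switch channels mid-run (e.g. at stimulation onset) give a block schedule
#' in [experiment_spec()] instead.
#'
#' @param cell a `gc_cell` from [build_cell()].
#' @param channels channel names; `"ca"` expands to the T-, N- and L-type
#'   calcium channels.
#' @param layers layer tags among `r paste(LAYERS, collapse = ", ")`.
#' @param active logical; `FALSE` blocks, `TRUE` restores.
#' @return the modified `gc_cell`.
#' @export
set_channel_block <- function(cell, channels, layers, active = FALSE) {
  stopifnot(inherits(cell, "gc_cell"))
  channels <- resolve_channels(channels)
  bad <- setdiff(layers, LAYERS)
  if (length(bad)) rlang::abort(paste0("unknown layer tag: ", paste(bad, collapse = ", ")))
  cell$block[channels, layers] <- if (active) 1 else 0
  cell
}
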