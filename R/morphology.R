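#' Reduced granule cell morphology
#'
#' Builds the nine-section reduced morphology of a dentate gyrus granule
#' cell: a soma and two symmetric dendritic branches, each branch consisting
#' of one section per dendritic zone (granule cell layer, inner, middle and
#' outer molecular layer).  Medial perforant path synapses terminate on the
#' middle molecular layer (MML) sections, lateral perforant path synapses on
#' the outer molecular layer (OML) sections.
#'
#' Two discretisations are provided.  The `"full"` mode uses 125
#' compartments (1 somatic segment, 5 per GCL section, 19 per IML/MML/OML
#' section); the `"reduced"` mode uses one segment per section (9 total) and
#' is intended for parameter scans and batch runs where speed matters more
#' than spatial resolution.
#'
#' @param mode `"full"` (125 compartments) or `"reduced"` (9 compartments).
#' @return An object of class `gc_morphology` with elements
#'   \describe{
#'     \item{sections}{tibble of sections: name, length (um), diameter (um),
#'       segment count, parent section and layer tag.}
#'     \item{compartments}{tibble with one row per compartment: section,
#'       layer, segment index, segment length/diameter, normalized position
#'       along the section (segment centre, soma end = 0), path distance of
#'       the segment centre from the soma centre (um) and parent compartment
#'       index.}
#'     \item{mode}{the discretisation mode.}
#'   }
#' @examples
#' m <- gc_morphology("reduced")
#' nrow(m$compartments) # 9
#' @export
gc_morphology <- function(mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  nseg_gcl <- if (mode == "full") 5L else 1L
  nseg_ml  <- if (mode == "full") 19L else 1L

  sections <- tibble::tibble(
    name   = c("soma",
               "gcl_a", "iml_a", "mml_a", "oml_a",
               "gcl_b", "iml_b", "mml_b", "oml_b"),
    length = c(16.8, rep(c(50, 150, 150, 150), 2)),
    diam   = c(16.8, rep(3, 8)),
    nseg   = c(1L, rep(c(nseg_gcl, nseg_ml, nseg_ml, nseg_ml), 2)),
    parent = c(NA, "soma", "gcl_a", "iml_a", "mml_a",
               "soma", "gcl_b", "iml_b", "mml_b"),
    layer  = c("soma", rep(c("GCL", "IML", "MML", "OML"), 2))
  )
  validate_morphology(sections)

  comp <- build_compartments(sections)
  structure(list(sections = sections, compartments = comp, mode = mode),
            class = "gc_morphology")
}

validate_morphology <- function(sections) {
  if (!all(sections$layer %in% LAYERS)) {
    rlang::abort(paste0("unknown layer tag: ",
                        paste(setdiff(sections$layer, LAYERS), collapse = ", ")))
  }
  if (any(sections$length <= 0) || any(sections$diam <= 0) ||
      any(sections$nseg < 1L)) {
    rlang::abort("non-positive geometry: lengths, diameters and segment counts must be positive")
  }
  if (nrow(sections) != 9L || sum(sections$layer == "soma") != 1L ||
      !all(table(sections$layer[sections$layer != "soma"]) == 2L)) {
    rlang::abort("morphology must have exactly 9 sections: 1 soma + 2 per dendritic layer")
  }
  invisible(sections)
}

# Expand sections into per-segment compartments with parent links and path
# distances (measured along the dendrite from the soma centre to each
# segment centre).
build_compartments <- function(sections) {
  rows <- list()
  # bookkeeping: index of the last compartment of each section, and path
  # distance at each section's distal end
  last_comp <- c()
  end_dist <- c()
  idx <- 0L
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    seg_len <- s$length / s$nseg
    if (is.na(s$parent)) {
      base_dist <- 0
      parent_idx <- NA_integer_
    } else {
      base_dist <- end_dist[[s$parent]]
      parent_idx <- last_comp[[s$parent]]
    }
    for (k in seq_len(s$nseg)) {
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        comp = idx,
        section = s$name,
        layer = s$layer,
        seg = k,
        seg_length = seg_len,
        diam = s$diam,
        pos = (k - 0.5) / s$nseg,
        path_dist = if (s$name == "soma") 0 else base_dist + (k - 0.5) * seg_len,
        parent = if (k == 1L) parent_idx else idx - 1L
      )
    }
    last_comp[[s$name]] <- idx
    end_dist[[s$name]] <- if (s$name == "soma") 0 else base_dist + s$length
  }
  dplyr::bind_rows(rows)
}

#' @export
print.gc_morphology <- function(x, ...) {
  cat("<gc_morphology> ", x$mode, " mode: ",
      nrow(x$sections), " sections, ",
      nrow(x$compartments), " compartments\n", sep = "")
  invisible(x)
}

# Map a (section, normalized position) location to a compartment index.
locate_compartment <- function(morphology, section, x) {
  sec <- morphology$sections[morphology$sections$name == section, ]
  if (nrow(sec) == 0L) rlang::abort(paste0("unknown section: ", section))
  if (x < 0 || x > 1) rlang::abort("position must lie in [0, 1]")
  seg <- min(sec$nseg, max(1L, ceiling(x * sec$nseg)))
  comp <- morphology$compartments
  comp$comp[comp$section == section & comp$seg == seg]
}
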