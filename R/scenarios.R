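# Scenario registry: every simulated experiment of the study, one named
# entry each, resolvable to complete experiment specifications.

scenario_entries <- function() {
  list(
    fig1b_top = list(
      description = "400-DBS to 100% of medial synapses",
      variants = function(n_runs) list(
        "400-DBS-100" = list(protocol = "400-DBS", tetanized_fraction = 1,
                             n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig1b_mid = list(
      description = "400-DBS to 60% of medial synapses",
      variants = function(n_runs) list(
        "400-DBS-60" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                            n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig1b_bottom = list(
      description = "400-DBS with lateral spontaneous activity silenced at stimulation onset",
      variants = function(n_runs) list(
        "400-DBS-lateral-off" = list(protocol = "400-DBS",
                                     tetanized_fraction = 1,
                                     lateral_off_at = "hfs_onset",
                                     n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig2a = list(
      description = "100-TBS to 60% of medial synapses",
      variants = function(n_runs) list(
        "100-TBS-60" = list(protocol = "100-TBS", tetanized_fraction = 0.6,
                            n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig2b = list(
      description = "400-TBS to 60% of medial synapses",
      variants = function(n_runs) list(
        "400-TBS-60" = list(protocol = "400-TBS", tetanized_fraction = 0.6,
                            n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig3 = list(
      description = "summary triplet: all three protocols at 60% tetanization",
      variants = function(n_runs) list(
        "400-DBS" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                         n_runs = n_runs),
        "100-TBS" = list(protocol = "100-TBS", tetanized_fraction = 0.6,
                         n_runs = n_runs),
        "400-TBS" = list(protocol = "400-TBS", tetanized_fraction = 0.6,
                         n_runs = n_runs)
      ), n_runs = 3L
    ),
    fig4 = list(
      description = "spike-average and amplitude dynamics for each protocol",
      variants = function(n_runs) list(
        "400-DBS" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                         n_runs = n_runs, snapshot_ms = 500),
        "100-TBS" = list(protocol = "100-TBS", tetanized_fraction = 0.6,
                         n_runs = n_runs, snapshot_ms = 500),
        "400-TBS" = list(protocol = "400-TBS", tetanized_fraction = 0.6,
                         n_runs = n_runs, snapshot_ms = 500)
      ), n_runs = 1L
    ),
    fig5 = list(
      description = "somatic and dendritic voltage during one stimulation train",
      variants = function(n_runs) {
        one_train <- function(preset) {
          p <- protocol_preset(preset)
          p$n_repeats <- 1L
          p
        }
        list(
          "400-DBS-train" = list(protocol = one_train("400-DBS"),
                                 tetanized_fraction = 0.6, n_runs = n_runs,
                                 baseline_ms = 5000, post_ms = 5000,
                                 final_window_ms = 2000,
                                 probes = c("soma", "mml_a"), probe_stride = 1L),
          "100-TBS-train" = list(protocol = one_train("100-TBS"),
                                 tetanized_fraction = 0.6, n_runs = n_runs,
                                 baseline_ms = 5000, post_ms = 5000,
                                 final_window_ms = 2000,
                                 probes = c("soma", "mml_a"), probe_stride = 1L),
          "400-TBS-train" = list(protocol = one_train("400-TBS"),
                                 tetanized_fraction = 0.6, n_runs = n_runs,
                                 baseline_ms = 5000, post_ms = 5000,
                                 final_window_ms = 2000,
                                 probes = c("soma", "mml_a"), probe_stride = 1L)
        )
      }, n_runs = 1L
    ),
    fig6 = list(
      description = "early weight evolution: LTP onset precedes LTD onset",
      variants = function(n_runs) list(
        "400-DBS" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                         n_runs = n_runs, snapshot_ms = 250),
        "400-TBS" = list(protocol = "400-TBS", tetanized_fraction = 0.6,
                         n_runs = n_runs, snapshot_ms = 250)
      ), n_runs = 3L
    ),
    fig7 = list(
      description = "dendritic Na/Ca channels blocked at stimulation onset, all protocols",
      variants = function(n_runs) {
        blk <- list(channels = c("na", "ca"),
                    layers = c("GCL", "IML", "MML", "OML"), at = "hfs_onset")
        list(
          "400-DBS-block" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                                 channel_block = blk, n_runs = n_runs),
          "100-TBS-block" = list(protocol = "100-TBS", tetanized_fraction = 0.6,
                                 channel_block = blk, n_runs = n_runs),
          "400-TBS-block" = list(protocol = "400-TBS", tetanized_fraction = 0.6,
                                 channel_block = blk, n_runs = n_runs)
        )
      }, n_runs = 3L
    ),
    fig8 = list(
      description = "integration period tau_c at 0.1, 1, 10 and 20 min (100-TBS)",
      variants = function(n_runs) {
        mk <- function(tc) list(protocol = "100-TBS", tetanized_fraction = 0.6,
                                params = plasticity_params(tau_c = tc * 60),
                                n_runs = n_runs)
        list("tau-0.1min" = mk(0.1), "tau-1min" = mk(1),
             "tau-10min" = mk(10), "tau-20min" = mk(20))
      }, n_runs = 3L
    ),
    s1 = list(
      description = "tetanized fraction scan: 20, 60, 100% (400-DBS)",
      variants = function(n_runs) {
        mk <- function(f) list(protocol = "400-DBS", tetanized_fraction = f,
                               n_runs = n_runs)
        list("frac-20" = mk(0.2), "frac-60" = mk(0.6), "frac-100" = mk(1))
      }, n_runs = 10L
    ),
    s2 = list(
      description = "spontaneous-activity noise scan: 0, 0.01, 0.05, 1 (400-DBS)",
      variants = function(n_runs) {
        mk <- function(nz) list(protocol = "400-DBS", tetanized_fraction = 0.6,
                                noise = nz, n_runs = n_runs)
        list("noise-0" = mk(0), "noise-0.01" = mk(0.01),
             "noise-0.05" = mk(0.05), "noise-1" = mk(1))
      }, n_runs = 10L
    ),
    s3 = list(
      description = "STDP window scan: tau_d in {30,70,100} ms, tau_p in {10,20,40} ms",
      variants = function(n_runs) {
        mk <- function(tp, td) list(
          protocol = "400-DBS", tetanized_fraction = 0.6,
          params = plasticity_params(tau_p = tp, tau_d = td), n_runs = n_runs)
        list("td-30" = mk(20, 30), "td-70" = mk(20, 70), "td-100" = mk(20, 100),
             "tp-10" = mk(10, 70), "tp-40" = mk(40, 70))
      }, n_runs = 10L
    ),
    s4 = list(
      description = "initial amplitude ratio A_p0:A_d0 at 1:1 and 3:1",
      variants = function(n_runs) list(
        "ratio-1to1" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                            params = plasticity_params(a_p0 = 0.003, a_d0 = 0.003),
                            n_runs = n_runs),
        "ratio-3to1" = list(protocol = "400-DBS", tetanized_fraction = 0.6,
                            params = plasticity_params(a_p0 = 0.003, a_d0 = 0.001),
                            n_runs = n_runs)
      ), n_runs = 10L
    ),
    s5 = list(
      description = "dendritic event threshold scan: -30, -33, -37, -40 mV",
      variants = function(n_runs) {
        mk <- function(th) list(protocol = "400-DBS", tetanized_fraction = 0.6,
                                params = plasticity_params(v_syn_thresh = th),
                                n_runs = n_runs)
        list("thr-30" = mk(-30), "thr-33" = mk(-33),
             "thr-37" = mk(-37), "thr-40" = mk(-40))
      }, n_runs = 10L
    )
  )
}

#' The scenario catalog
#'
#' Named scenarios covering every simulated experiment: the weight-evolution
#' panels (`fig1b_*`, `fig2a`, `fig2b`), the protocol summary (`fig3`),
#' amplitude/trace captures (`fig4`, `fig5`), the early-window comparison
#' (`fig6`), the channel-block experiment (`fig7`), the integration-period
#' comparison (`fig8`) and the robustness scans (`s1`-`s5`).
#'
#' @return tibble with scenario names, descriptions, variant counts and
#'   default run counts.
#' @export
scenario_catalog <- function() {
  entries <- scenario_entries()
  tibble::tibble(
    name = names(entries),
    description = purrr::map_chr(entries, "description"),
    n_variants = purrr::map_int(entries, function(e) length(e$variants(1L))),
    default_runs = purrr::map_int(entries, function(e) as.integer(e$n_runs))
  )
}

#' Run a named scenario
#'
#' Resolves a catalog entry to its experiment specifications, runs every
#' variant, and returns (optionally writes) a result bundle with a summary
#' table of pathway changes.
#'
#' @param name scenario name (see [scenario_catalog()]).
#' @param overrides named list of [experiment_spec()] arguments applied on
#'   top of each variant (e.g. `list(n_runs = 1, post_ms = 120000)`).
#' @param out_dir if not `NULL`, write `summary.csv`, `timecourse.csv` and
#'   `manifest.json` there.
#' @param quiet suppress progress messages.
#' @return a `scenario_bundle`: list with `name`, `variants` (named list of
#'   `simulation_batch`es), `summary` (tibble: variant, pathway, mean_pct,
#'   sd_pct, n_runs) and `manifest`.
#' @export
run_scenario <- function(name, overrides = list(), out_dir = NULL,
                         quiet = TRUE) {
  entries <- scenario_entries()
  if (!name %in% names(entries)) {
    rlang::abort(paste0(
      "unknown scenario '", name, "'. Catalog: ",
      paste(names(entries), collapse = ", ")))
  }
  entry <- entries[[name]]
  n_runs <- if (!is.null(overrides$n_runs)) overrides$n_runs else entry$n_runs
  variants <- entry$variants(n_runs)
  if (identical(name, "s2") && !is.null(overrides$noise) &&
      overrides$noise == 0) {
    rlang::warn("noise = 0 gives fully synchronous input; both pathways may co-potentiate or co-depress")
  }
  batches <- purrr::imap(variants, function(args, vname) {
    if (!quiet) message("scenario ", name, " variant ", vname)
    if (identical(name, "s2") && !is.null(args$noise) && args$noise == 0) {
      rlang::warn("noise = 0 gives fully synchronous input; both pathways may co-potentiate or co-depress")
    }
    args[names(overrides)] <- overrides
    spec <- do.call(experiment_spec, args)
    run_experiment(spec, quiet = quiet)
  })
  summary <- purrr::imap_dfr(batches, function(b, vname) {
    measure_pathway_change(b) %>% dplyr::mutate(variant = vname, .before = 1)
  })
  bundle <- structure(list(
    name = name,
    variants = batches,
    summary = summary,
    manifest = list(
      scenario = name, description = entry$description,
      overrides = overrides,
      variant_manifests = purrr::map(batches, attr, "manifest")
    )
  ), class = "scenario_bundle")
  if (!is.null(out_dir)) write_scenario_bundle(bundle, out_dir)
  bundle
}

write_scenario_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  tc <- purrr::imap_dfr(bundle$variants, function(b, vname) {
    pathway_timecourse(b) %>% dplyr::mutate(variant = vname, .before = 1)
  })
  utils::write.csv(tc, file.path(out_dir, "timecourse.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle> ", x$name, ": ", length(x$variants), " variant(s)\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare scenario results with recorded reference values
#'
#' Joins the pathway changes of one or more scenario bundles against the
#' packaged table of reference weight-change values for the canonical model
#' configuration (`extdata/reference_changes.csv`) and flags each row as
#' passing when `|simulated - reference| <= tolerance`.  The default
#' tolerance is `max(3, 3 * reference SD)` percentage points.  Rows are
#' marked `conditional` unless the runs used the `"modeldb-51781"`
#' mechanism source, since the reference values presume that biophysics.
#'
#' @param bundles a `scenario_bundle` or list of them (empty list allowed).
#' @param tolerance percentage-point tolerance; `NULL` for the default rule.
#' @return tibble: scenario, variant, pathway, simulated mean/SD, reference
#'   mean/SD, tolerance, pass, conditional.
#' @export
summarize_scenarios <- function(bundles, tolerance = NULL) {
  if (inherits(bundles, "scenario_bundle")) bundles <- list(bundles)
  ref <- utils::read.csv(system.file("extdata", "reference_changes.csv",
                                     package = "dentatestdp"))
  if (length(bundles) == 0L) {
    return(tibble::tibble(scenario = character(0), variant = character(0),
                          pathway = character(0), sim_mean = numeric(0),
                          sim_sd = numeric(0), ref_mean = numeric(0),
                          ref_sd = numeric(0), tol = numeric(0),
                          pass = logical(0), conditional = logical(0)))
  }
  purrr::map_dfr(bundles, function(b) {
    mech <- b$manifest$variant_manifests[[1]]$mechanism_source
    b$summary %>%
      dplyr::mutate(scenario = b$name, .before = 1) %>%
      dplyr::left_join(ref, by = c("scenario", "variant", "pathway")) %>%
      dplyr::mutate(
        sim_mean = .data$mean_pct, sim_sd = .data$sd_pct,
        tol = if (is.null(tolerance)) pmax(3, 3 * .data$ref_sd) else tolerance,
        pass = !is.na(.data$ref_mean) &
          abs(.data$sim_mean - .data$ref_mean) <= .data$tol,
        conditional = !identical(mech, "modeldb-51781")
      ) %>%
      dplyr::select("scenario", "variant", "pathway", "sim_mean", "sim_sd",
                    "ref_mean", "ref_sd", "tol", "pass", "conditional")
  })
}
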