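#' Pathway-mean weight time course
#'
#' Mean synaptic weight per pathway, expressed as percent of each synapse's
#' pre-stimulation baseline, at every snapshot time.
#'
#' @param results a `simulation_batch` or single `simulation_result`.
#' @return tibble: run, time_ms, pathway, mean_pct (100 = baseline).
#' @export
pathway_timecourse <- function(results) {
  if (inherits(results, "simulation_result")) results <- list(results)
  purrr::map_dfr(seq_along(results), function(i) {
    r <- results[[i]]
    rel <- sweep(r$W, 2, r$w_baseline, "/") * 100
    purrr::map_dfr(c("medial", "lateral"), function(pw) {
      sel <- r$synapses$pathway == pw
      tibble::tibble(
        run = i,
        time_ms = r$snap_times,
        pathway = pw,
        mean_pct = rowMeans(rel[, sel, drop = FALSE])
      )
    })
  })
}

#' @rdname tidy.simulation_result
#' @export
tidy.simulation_batch <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(i) {
    tidy.simulation_result(x[[i]], ...) %>% dplyr::mutate(run = i, .before = 1)
  })
}

#' Tidy per-synapse outcomes of a simulation
#'
#' One row per synapse: pathway, tetanization flag, path distance from the
#' soma and the percent weight change over the measurement window.
#'
#' @param x a `simulation_result` or `simulation_batch`.
#' @param final_window_ms measurement window (ms); `NULL` uses the spec's.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.simulation_result <- function(x, final_window_ms = NULL, ...) {
  synapse_changes(x, final_window_ms)
}

#' One-row summary of a simulation run
#'
#' @param x a `simulation_result` or `simulation_batch`.
#' @param ... unused.
#' @return tibble with protocol, mechanism source, somatic spike count and
#'   pathway mean changes.
#' @export
glance.simulation_result <- function(x, ...) {
  ch <- measure_pathway_change(x)
  tibble::tibble(
    protocol = x$manifest$protocol,
    mechanism_source = x$manifest$mechanism_source,
    morphology = x$manifest$morphology,
    n_soma_spikes = length(x$soma_spikes),
    medial_pct = ch$mean_pct[ch$pathway == "medial"],
    lateral_pct = ch$mean_pct[ch$pathway == "lateral"]
  )
}

#' @rdname glance.simulation_result
#' @export
glance.simulation_batch <- function(x, ...) {
  m <- attr(x, "manifest")
  ch <- measure_pathway_change(x)
  tibble::tibble(
    protocol = m$protocol,
    mechanism_source = m$mechanism_source,
    morphology = m$morphology,
    n_runs = length(x),
    medial_pct = ch$mean_pct[ch$pathway == "medial"],
    medial_sd = ch$sd_pct[ch$pathway == "medial"],
    lateral_pct = ch$mean_pct[ch$pathway == "lateral"],
    lateral_sd = ch$sd_pct[ch$pathway == "lateral"]
  )
}

#' Plot the weight evolution of a simulation
#'
#' `type = "weights"` draws the pathway-mean weight (percent of baseline)
#' against time, averaged over runs; `type = "homeostasis"` draws the spike
#' average and the sliding amplitudes.
#'
#' @param object a `simulation_batch` or `simulation_result`.
#' @param type `"weights"` or `"homeostasis"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.simulation_batch <- function(object, type = c("weights", "homeostasis"),
                                      ...) {
  type <- match.arg(type)
  m <- if (inherits(object, "simulation_batch")) attr(object, "manifest") else object$manifest
  if (type == "weights") {
    tc <- pathway_timecourse(object) %>%
      dplyr::group_by(.data$time_ms, .data$pathway) %>%
      dplyr::summarise(mean_pct = mean(.data$mean_pct), .groups = "drop")
    ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_ms / 60000,
                                     y = .data$mean_pct,
                                     colour = .data$pathway)) +
      ggplot2::geom_hline(yintercept = 100, linetype = 3) +
      ggplot2::geom_vline(xintercept = m$t_hfs / 60000, linetype = 2,
                          colour = "grey40") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (min)", y = "mean weight (% of baseline)",
                    colour = NULL,
                    title = paste0(m$protocol, " (",
                                   round(m$tetanized_fraction * 100),
                                   "% tetanized)")) +
      ggplot2::theme_minimal()
  } else {
    r <- if (inherits(object, "simulation_batch")) object[[1]] else object
    hs <- r$homeostasis %>%
      tidyr::pivot_longer(c("c_avg", "a_p", "a_d"),
                          names_to = "quantity", values_to = "value")
    ggplot2::ggplot(hs, ggplot2::aes(x = .data$time_ms / 60000,
                                     y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "time (min)", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.simulation_batch
#' @export
autoplot.simulation_result <- autoplot.simulation_batch

#' @rdname autoplot.simulation_batch
#' @export
autoplot.weight_distance <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$path_dist, y = .data$pct_change,
                               colour = .data$pathway,
                               shape = .data$tetanized)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "path distance from soma (um)",
                  y = "weight change (%)", colour = NULL,
                  shape = "tetanized") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.simulation_batch
#' @export
autoplot.scenario_bundle <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$variant, y = .data$mean_pct,
                               fill = .data$pathway)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                   ymax = .data$mean_pct + .data$sd_pct),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "weight change (%)", fill = NULL,
                  title = object$name) +
    ggplot2::theme_minimal()
}
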