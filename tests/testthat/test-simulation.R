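test_that("pathway change arithmetic matches hand-built series", {
  # two synapses: one to 150 %, one to 50 % -> (+50, -50), pooled 0
  mk_result <- function(w_final) {
    res <- list(
      seed = 1,
      synapses = tibble::tibble(id = 1:2, pathway = c("medial", "medial"),
                                path_dist = c(100, 200)),
      tetanized = 1L,
      snap_times = c(0, 1000, 2000),
      W = rbind(c(1, 1), c(1, 1), w_final),
      w_baseline = c(1, 1),
      w_final = w_final,
      manifest = list(final_window_ms = 500, t_hfs = 0)
    )
    class(res) <- "simulation_result"
    res
  }
  ch <- measure_pathway_change(mk_result(c(1.5, 0.5)), pathways = "medial")
  expect_equal(ch$mean_pct, 0)
  per_syn <- synapse_changes(mk_result(c(1.5, 0.5)))
  expect_equal(per_syn$pct_change, c(50, -50))
  # constant weights -> 0 %; doubled weights -> +100 %
  expect_equal(measure_pathway_change(mk_result(c(1, 1)))$mean_pct, 0)
  expect_equal(measure_pathway_change(mk_result(c(2, 2)))$mean_pct, 100)
  expect_error(measure_pathway_change(mk_result(c(1, 1)), pathways = "lateral"),
               "empty")
})

test_that("weight_vs_distance recovers a synthetic linear gradient", {
  n <- 40
  dist <- seq(50, 450, length.out = n)
  w_fin <- 1 + dist / 1000  # perfect linear gradient
  res <- list(
    seed = 1,
    synapses = tibble::tibble(id = 1:n,
                              pathway = rep(c("medial", "lateral"), n / 2),
                              path_dist = dist),
    tetanized = integer(0),
    snap_times = c(0, 1000),
    W = rbind(rep(1, n), w_fin),
    w_baseline = rep(1, n),
    w_final = w_fin,
    manifest = list(final_window_ms = 500, t_hfs = 0)
  )
  class(res) <- "simulation_result"
  wd <- weight_vs_distance(res)
  expect_equal(wd$correlations$r[wd$correlations$group == "non-tetanized"], 1,
               tolerance = 1e-10)
  expect_false(any(wd$correlations$degenerate))

  # all changes equal -> degenerate, r reported as 0 with flag
  res$W[2, ] <- 1.5
  wd2 <- weight_vs_distance(res)
  expect_equal(wd2$correlations$r, 0)
  expect_true(all(wd2$correlations$degenerate))
})

test_that("identical spec and seeds reproduce the simulation exactly", {
  spec <- experiment_spec("100-TBS", tetanized_fraction = 0.6, n_runs = 1,
                          baseline_ms = 5000, post_ms = 5000,
                          final_window_ms = 2000,
                          baseline_weight = 1.2e-4,
                          params = plasticity_params(tau_c = 5))
  a <- run_experiment(spec)
  b <- run_experiment(spec)
  expect_identical(a[[1]]$w_final, b[[1]]$w_final)
  expect_identical(a[[1]]$soma_spikes, b[[1]]$soma_spikes)
  expect_identical(a[[1]]$homeostasis$c_avg, b[[1]]$homeostasis$c_avg)
})

test_that("the closed-loop weight update matches the standalone evaluator", {
  # run a short closed loop with the event log on, then replay the logged
  # events through the event-driven offline core
  spec <- experiment_spec(NULL, n_runs = 1,
                          warmup_ms = 2000, baseline_ms = 28000,
                          post_ms = 10, final_window_ms = 5000,
                          baseline_weight = calibrated_weight()$weight,
                          n_medial = 150, n_lateral = 150,
                          record_events = TRUE,
                          params = plasticity_params(tau_c = 10))
  b <- run_experiment(spec)
  r <- b[[1]]
  expect_false(is.null(r$post_events))

  # rebuild the drive exactly as the run did
  cell <- attach_synapses(
    build_cell(gc_morphology("reduced"), mechanism_source("fallback-hh")),
    150, 150, weight = r$manifest$baseline_weight, seed = r$seed)
  streams <- assemble_drive(cell, spike_train_spec(t_end = r$manifest$t_stop),
                            protocol = NULL, seed = r$seed, dt = 0.2)
  # map compartment-level events onto the synapses they host
  post_streams <- dplyr::inner_join(
    cell$synapses[, c("id", "comp")],
    r$post_events, by = "comp", relationship = "many-to-many")
  off <- run_plasticity_offline(
    pre_streams = data.frame(synapse_id = streams$synapse_id,
                             time_ms = streams$time_ms),
    post_streams = data.frame(synapse_id = post_streams$id,
                              time_ms = post_streams$time_ms),
    somatic_spikes = r$soma_spikes,
    params = spec$params, dt = 0.2, t_end = r$manifest$t_stop,
    w0 = cell$synapses$weight, warmup_ms = spec$warmup_ms
  )
  expect_equal(off$weights$w_final, r$w_final, tolerance = 1e-10)
})

test_that("tidy, glance and autoplot methods work on results", {
  spec <- experiment_spec("100-TBS", tetanized_fraction = 0.6, n_runs = 2,
                          baseline_ms = 3000, post_ms = 3000,
                          final_window_ms = 1000,
                          baseline_weight = 1.2e-4,
                          params = plasticity_params(tau_c = 5))
  b <- run_experiment(spec)
  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 600L)
  expect_true(all(c("run", "synapse_id", "pathway", "pct_change") %in% names(td)))
  gl <- glance(b)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_runs, 2L)
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(autoplot(b[[1]], type = "homeostasis"), "ggplot")
  expect_s3_class(autoplot(weight_vs_distance(b[[1]])), "ggplot")
  tc <- pathway_timecourse(b)
  expect_true(all(tc$pathway %in% c("medial", "lateral")))
})

test_that("freezing A_p (homeostasis off) enlarges 100-TBS medial LTP", {
  w0 <- calibrated_weight()$weight
  mk <- function(freeze) {
    run_experiment(experiment_spec(
      "100-TBS", tetanized_fraction = 0.6, n_runs = 1, baseline_weight = w0,
      params = plasticity_params(freeze_ap = freeze)))
  }
  normal <- measure_pathway_change(mk(FALSE))
  frozen <- measure_pathway_change(mk(TRUE))
  expect_gt(frozen$mean_pct[frozen$pathway == "medial"],
            normal$mean_pct[normal$pathway == "medial"] + 2)
})

test_that("the solution does not depend on the probe set", {
  cell <- attach_synapses(reduced_cell(), 20, 20, weight = 1.3e-4, seed = 1)
  drv <- assemble_drive(cell, spike_train_spec(t_end = 2000), seed = 2)
  a <- integrate_cell(cell, drv, duration = 2000, probes = "soma")
  b <- integrate_cell(cell, drv, duration = 2000,
                      probes = c("soma", "mml_a", "oml_b"))
  expect_identical(a$mV, b$mV[b$section == "soma"])
  expect_identical(attr(a, "soma_spikes"), attr(b, "soma_spikes"))
})

test_that("voltage traces round-trip through self-describing CSV", {
  cell <- reduced_cell()
  tr <- integrate_cell(cell, duration = 100, probes = "soma")
  path <- tempfile(fileext = ".csv")
  write_voltage_traces(tr, path, manifest = list(mechanisms = "fallback-hh",
                                                 dt = 0.2))
  lines <- readLines(path, n = 3)
  expect_match(lines[1], "^# mechanisms: fallback-hh")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$mV, tr$mV)
})

test_that("the run manifest records provenance", {
  spec <- experiment_spec(NULL, n_runs = 1, warmup_ms = 500,
                          baseline_ms = 1000, post_ms = 10,
                          final_window_ms = 500, baseline_weight = 1e-4)
  b <- run_experiment(spec)
  m <- attr(b, "manifest")
  expect_equal(m$mechanism_source, "fallback-hh")
  expect_equal(m$morphology, "reduced")
  expect_false(m$calibrated)
  expect_equal(m$baseline_weight, 1e-4)
  expect_true(!is.null(m$package_version))
})
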