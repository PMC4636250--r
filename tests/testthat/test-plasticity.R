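test_that("threshold crossings are detected with linear interpolation", {
  t <- seq(0, 100, by = 0.5)
  expect_length(detect_events(t, rep(-70, length(t)), -37), 0L)

  # triangle wave: rises from -70 to -20 over 0..50 ms, falls back
  v <- ifelse(t <= 50, -70 + t, -20 - (t - 50))
  ev <- detect_events(t, v, -37)
  expect_length(ev, 1L)
  expect_equal(ev, 33, tolerance = 1e-10)  # -70 + t = -37 at t = 33

  expect_error(detect_events(t, c(NaN, v[-1]), -37), "non-finite")
})

test_that("the event debounce collapses rapid re-crossings", {
  t <- seq(0, 20, by = 0.1)
  v <- -50 + 20 * sin(2 * pi * t / 2)  # crosses -37 every 2 ms
  expect_length(detect_events(t, v, -37, debounce = 5), 4L)
  expect_length(detect_events(t, v, -37, debounce = 0), 10L)
})

test_that("the spike-average recursion matches brute-force summation and closed forms", {
  dt <- 0.2; tau_c <- 60; alpha <- 2500
  # single spike: <c>(t) = (alpha/tau)*dt*exp(-(t - t0)/tau)
  n <- 5000
  cc <- brute_spike_average(100, n, dt, tau_c, alpha)
  k <- seq_len(n)
  expected <- ifelse(k >= 100, (alpha / 60000) * dt * exp(-((k - 100) * dt) / 60000), 0)
  expect_equal(cc, expected, tolerance = 1e-12)

  # recursion agrees with the one-step operation
  c1 <- update_spike_average(0.5, TRUE, dt, tau_c, alpha)
  expect_equal(c1, 0.5 * exp(-dt / 60000) + alpha / 60000 * dt)
  expect_equal(update_spike_average(0, FALSE, dt, tau_c, alpha), 0)
})

test_that("steady-state <c> equals alpha * dt * rate for regular spiking", {
  # 2 Hz regular spiking: steady state 1.0 at alpha*dt = 500 ms
  for (dt in c(0.2, 0.1)) {
    alpha <- 500 / dt
    steps_per_spike <- 500 / dt
    n <- 3e6 * 0.2 / dt  # 10 min simulated
    spikes <- seq(steps_per_spike, n, by = steps_per_spike)
    query <- round(seq(n * 0.9, n, length.out = 50))
    tail_mean <- mean(vapply(query, function(k) {
      brute_c_at(spikes, k, dt, 60, alpha)
    }, numeric(1)))
    expect_equal(tail_mean, 1.0, tolerance = 0.02)
    # and the one-step recursion reproduces the direct summation
    cc <- 0
    for (k in seq_len(20000)) {
      cc <- update_spike_average(cc, k %% steps_per_spike == 0, dt, 60, alpha)
    }
    expect_equal(cc, brute_c_at(seq(steps_per_spike, 20000, by = steps_per_spike),
                                20000, dt, 60, alpha), tolerance = 1e-10)
  }
})

test_that("amplitudes slide with <c> and conserve their product", {
  p <- plasticity_params()
  expect_equal(update_amplitudes(1, p), c(a_p = 0.003, a_d = 0.001))
  expect_equal(update_amplitudes(3, p), c(a_p = 0.001, a_d = 0.003))
  for (cc in c(0.002, 0.5, 1, 7, 40)) {
    a <- update_amplitudes(cc, p)
    expect_equal(unname(a["a_p"] * a["a_d"]), 3e-6, tolerance = 1e-12)
  }
  # floor keeps A_p finite at start-up
  a0 <- update_amplitudes(0, p)
  expect_equal(unname(a0["a_p"]), 0.003 / p$c_floor)
  # freeze switches
  pf <- plasticity_params(freeze_ap = TRUE)
  expect_equal(unname(update_amplitudes(5, pf)["a_p"]), 0.003)
})

test_that("nearest-neighbour pairing matches the stated examples", {
  p <- pair_nearest_neighbor(100, c(90, 130))
  expect_equal(p$dt_before, -10)
  expect_equal(p$dt_after, 30)

  p2 <- pair_nearest_neighbor(100, numeric(0))
  expect_true(is.na(p2$dt_before) && is.na(p2$dt_after))

  p3 <- pair_nearest_neighbor(c(100, 200), 150)
  expect_true(is.na(p3$dt_before[1])); expect_equal(p3$dt_after[1], 50)
  expect_equal(p3$dt_before[2], -50); expect_true(is.na(p3$dt_after[2]))
})

test_that("streaming pairing equals brute force on random streams", {
  set.seed(42)
  for (i in 1:200) {
    pre <- sort(runif(sample(1:8, 1), 0, 100))
    posts <- sort(runif(sample(0:8, 1), 0, 100))
    got <- pair_nearest_neighbor(pre, posts)
    for (j in seq_along(pre)) {
      want <- brute_pair(pre[j], posts)
      expect_identical(unname(got$dt_before[j]), unname(want[["dt_before"]]))
      expect_identical(unname(got$dt_after[j]), unname(want[["dt_after"]]))
    }
  }
})

test_that("single-pair weight updates match the exponential windows", {
  # potentiation one window constant away: w' = 1 + 0.003 * exp(-1)
  expect_equal(apply_weight_update(1, dt_after = 20, w0 = 1),
               1.0011036383, tolerance = 1e-9)
  # depression: w' = 1 - 0.001 * exp(-1)
  expect_equal(apply_weight_update(1, dt_before = -70, w0 = 1),
               0.9996321206, tolerance = 1e-9)
  # dt = 0 contributes to neither window
  expect_equal(apply_weight_update(1, dt_before = 0, dt_after = NA, w0 = 1), 1)
})

test_that("|dw| decreases strictly with the pair interval", {
  dts <- seq(1, 100, by = 1)
  pot <- vapply(dts, function(d) apply_weight_update(1, dt_after = d, w0 = 1),
                numeric(1))
  dep <- vapply(dts, function(d) apply_weight_update(1, dt_before = -d, w0 = 1),
                numeric(1))
  expect_true(all(diff(pot) < 0))  # smaller potentiation further out
  expect_true(all(diff(dep) > 0))  # weaker depression further out
})

test_that("cumulative potentiation saturates at the hard bound", {
  w <- 1
  for (i in 1:3000) w <- apply_weight_update(w, dt_after = 1, a_p = 0.01, w0 = 1)
  expect_equal(w, 2)  # +100 % cap
  w <- 1
  for (i in 1:5000) w <- apply_weight_update(w, dt_before = -1, a_d = 0.01, w0 = 1)
  expect_gt(w, 0)
  expect_equal(w, 1e-9, tolerance = 1e-6)  # symmetric lower clamp, kept positive
})

test_that("offline evaluator matches brute force with frozen amplitudes", {
  params <- plasticity_params(freeze_ap = TRUE, freeze_ad = TRUE, c0 = 1)
  # hand-built 5-pre / 3-post stream
  pre <- c(100, 180, 260, 300, 420)
  posts <- c(150, 290, 400)
  res <- run_plasticity_offline(
    data.frame(synapse_id = 1, time_ms = pre),
    data.frame(synapse_id = 1, time_ms = posts),
    somatic_spikes = numeric(0), params = params, dt = 0.2,
    t_end = 500, w0 = 1, warmup_ms = 0
  )
  want <- brute_weights_frozen(pre, posts, 1, 0.003, 0.001, 20, 70)
  expect_equal(res$weights$w_final, want, tolerance = 1e-12)

  # random small streams, several synapses
  set.seed(99)
  for (i in 1:25) {
    pre <- sort(runif(sample(2:10, 1), 0, 1000))
    posts <- sort(runif(sample(1:10, 1), 0, 1000))
    res <- run_plasticity_offline(
      data.frame(synapse_id = 1, time_ms = pre),
      data.frame(synapse_id = 1, time_ms = posts),
      numeric(0), params, dt = 0.2, t_end = 1100, w0 = 1, warmup_ms = 0
    )
    want <- brute_weights_frozen(pre, posts, 1, 0.003, 0.001, 20, 70)
    expect_equal(res$weights$w_final, want, tolerance = 1e-10)
  }
})

test_that("weight bounds are never violated under random streams (fuzz)", {
  set.seed(7)
  params <- plasticity_params(a_p0 = 0.2, a_d0 = 0.2, c0 = 1)
  for (i in 1:20) {
    pre <- sort(runif(300, 0, 5000))
    posts <- sort(runif(300, 0, 5000))
    res <- run_plasticity_offline(
      data.frame(synapse_id = 1, time_ms = pre),
      data.frame(synapse_id = 1, time_ms = posts),
      somatic_spikes = sort(runif(20, 0, 5000)),
      params, dt = 0.2, t_end = 5100, w0 = 2, warmup_ms = 0
    )
    expect_gt(res$weights$w_final, 0)
    expect_lte(res$weights$w_final, 2 * (1 + params$max_change) + 1e-12)
    expect_gte(res$weights$w_final, 2e-9 - 1e-15)
  }
})

test_that("raising the sustained somatic rate lowers A_p and raises A_d", {
  params <- plasticity_params()
  dt <- 0.2
  series_at <- function(rate_hz) {
    spikes <- seq(1000 / rate_hz, 180000, by = 1000 / rate_hz)
    res <- run_plasticity_offline(
      data.frame(synapse_id = 1, time_ms = 1),
      data.frame(synapse_id = numeric(0), time_ms = numeric(0)),
      somatic_spikes = spikes, params = params, dt = dt, t_end = 180000,
      w0 = 1, warmup_ms = 0, record_every = 1000
    )
    utils::tail(res$series, 1)
  }
  lo <- series_at(1); mid <- series_at(2); hi <- series_at(8)
  expect_true(lo$a_p > mid$a_p && mid$a_p > hi$a_p)
  expect_true(lo$a_d < mid$a_d && mid$a_d < hi$a_d)
  expect_equal(mid$c_avg, 1, tolerance = 0.05)
})

test_that("offline weight outcome is invariant to the integration step", {
  set.seed(5)
  pre <- sort(runif(200, 0, 60000))
  posts <- sort(runif(150, 0, 60000))
  spikes <- sort(runif(120, 0, 60000))
  res <- lapply(c(0.2, 0.1), function(dt) {
    run_plasticity_offline(
      data.frame(synapse_id = 1, time_ms = pre),
      data.frame(synapse_id = 1, time_ms = posts),
      spikes, plasticity_params(), dt = dt, t_end = 60000, w0 = 1,
      warmup_ms = 0
    )$weights$w_final
  })
  expect_equal(res[[1]], res[[2]], tolerance = 1e-4)
})
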