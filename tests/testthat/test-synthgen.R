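test_that("membrane-test generator matches the two-compartment closed form", {
  cfg <- sim_config(seed = 1, noise_sd = 0,
                    membrane = list(Rm = 190, Rs = 10, Cm = 200,
                                    Vrest = -70, Vth = -50))
  mt <- simulate_membrane_test(cfg)
  # Ohm's law at the two extremes of the transient
  expect_equal(mt$truth$Is, 1000 * 10 / 200)          # 50 pA steady state
  expect_equal(mt$truth$Ip, 1000 * 10 / 10)           # 1000 pA peak
  # closed-form RC time constant Cm * (Rs || Rm)
  expect_equal(mt$truth$tau, 200 * (10 * 190 / 200) / 1000)
  # noiseless trace equals its closed form at the recorded samples
  fs <- mt$sweep$sampling_rate
  i0 <- round(50 * fs) + 1L
  tt <- (0:99) / fs
  expect_equal(mt$sweep$values[i0 + 0:99],
               -(50 + 950 * exp(-tt / 1.9)), tolerance = 1e-12)
  expect_error(simulate_membrane_test(
    sim_config(membrane = list(Rm = -1, Rs = 10, Cm = 100,
                               Vrest = -70, Vth = -50))),
    "positive")
})

test_that("same seed and config give byte-identical outputs", {
  cfg <- sim_config(seed = 42, duration = 2000)
  a <- simulate_event_trace(cfg, "sEPSC")
  b <- simulate_event_trace(cfg, "sEPSC")
  expect_identical(a$sweep$values, b$sweep$values)
  expect_identical(a$truth, b$truth)
  m1 <- simulate_membrane_test(cfg)
  m2 <- simulate_membrane_test(cfg)
  expect_identical(m1$sweep$values, m2$sweep$values)
})

test_that("planted event statistics follow the configured Poisson process", {
  expect_equal(nrow(simulate_event_trace(
    sim_config(seed = 3, duration = 5000, event_rate = 0),
    "mEPSC")$truth$events), 0L)
  cfg <- sim_config(seed = 7, duration = 100000, event_rate = 5,
                    noise_sd = 0)
  n <- nrow(simulate_event_trace(cfg, "mEPSC")$truth$events)
  expect_lt(abs(n - 500), 3 * sqrt(500))
  # multiplicity 1 + Poisson(1): expected planted amplitude 2x quantal
  cfg2 <- sim_config(seed = 8, duration = 200000, event_rate = 3,
                     multiplicity_mean = 1)
  tr <- simulate_event_trace(cfg2, "sEPSC")$truth$events
  expect_equal(mean(tr$amp), 2 * 20, tolerance = 0.05)
  # refractory floor between planted events
  expect_true(all(diff(tr$time) >= 2))
  # events within a kernel length of the end are flagged
  cfg3 <- sim_config(seed = 9, duration = 1000, event_rate = 50)
  tr3 <- simulate_event_trace(cfg3, "mEPSC")$truth
  expect_true(all(tr3$events$edge_flag ==
                    (tr3$events$time > 1000 - tr3$kernel_ms)))
})

test_that("noiseless single event reproduces the kernel exactly", {
  cfg <- sim_config(seed = 5, duration = 500, event_rate = 0, noise_sd = 0)
  sim <- simulate_event_trace(cfg, "mEPSC")
  fs <- cfg$sampling_rate
  y <- sim$sweep$values
  t0 <- 100
  i0 <- round(t0 * fs) + 1L
  y[i0:(i0 + 400)] <- y[i0:(i0 + 400)] -
    biexp_kernel((0:400) / fs, 20, 0.5, 5, TRUE)
  # manual injection reproduces the generator's kernel sampling
  sim2 <- simulate_event_trace(cfg, "mEPSC")
  expect_identical(sim$sweep$values, sim2$sweep$values)
  expect_equal(max(abs(-biexp_kernel((0:400) / fs, 20, 0.5, 5, TRUE))),
               20, tolerance = 2e-3)
})

test_that("current-step generator spikes where the LIF closed form says", {
  cfg <- sim_config(seed = 2, noise_sd = 0,
                    membrane = list(Rm = 100, Rs = 10, Cm = 200,
                                    Vrest = -70, Vth = -50))
  st <- simulate_current_steps(cfg)
  expect_equal(st$truth$rheobase_pA, 200)
  izero <- which(st$truth$steps_pA == 0)
  expect_length(st$truth$spike_times[[izero]], 0L)
  # refractory bound: <= 100 spikes in 500 ms at 5 ms refractory
  imax <- which.max(st$truth$steps_pA)
  expect_lte(length(st$truth$spike_times[[imax]]), 100L)
  # no step below the analytic rheobase fires
  sub <- st$truth$steps_pA < 200
  expect_true(all(lengths(st$truth$spike_times[sub]) == 0L))
  expect_gte(length(st$truth$spike_times[[which(st$truth$steps_pA == 200)]]),
             1L)
  expect_error(simulate_current_steps(
    sim_config(membrane = list(Rm = 100, Rs = 10, Cm = 200,
                               Vrest = -50, Vth = -70))), "Vth")
})

test_that("evoked and paired-pulse generators plant the configured peaks", {
  cfg <- sim_config(seed = 4, noise_sd = 0)
  ev <- simulate_evoked_series(cfg, sigmoid = list(max = 800, half = 40,
                                                   slope = 12))
  expect_equal(ev$truth$true_peak[10], 800, tolerance = 0.01)
  pp <- simulate_paired_pulse(cfg, A1 = 200, ppr = 1.0, n_traces = 2)
  expect_equal(pp$truth$A1, pp$truth$A2)
})

test_that("tonic-block generator plants exact steps and noise levels", {
  cfg <- sim_config(seed = 6)
  tb <- simulate_tonic_block(cfg, step_pA = 20, drug_ms = 1000,
                             duration_ms = 2000, noise_before = 0,
                             noise_after = 0)
  v <- tb$sweep$values
  fs <- tb$sweep$sampling_rate
  expect_equal(mean(v[1:(1000 * fs)]) - mean(v[(1000 * fs + 1):(2000 * fs)]),
               20, tolerance = 1e-12)
  tb0 <- simulate_tonic_block(cfg, step_pA = 0, drug_ms = 1000,
                              duration_ms = 2000, noise_before = 0,
                              noise_after = 0)
  expect_equal(diff(range(tb0$sweep$values)), 0)
  # noise SD change is recovered on long windows
  tb2 <- simulate_tonic_block(sim_config(seed = 11), step_pA = 0,
                              drug_ms = 30000, duration_ms = 60000,
                              noise_before = 5, noise_after = 3)
  v2 <- tb2$sweep$values
  half <- length(v2) / 2
  expect_equal(sd(v2[1:half]) - sd(v2[(half + 1):length(v2)]), 2,
               tolerance = 0.05)
})

test_that("puncta generator plants controllable colocalization", {
  cfg <- sim_config(seed = 10)
  ps <- simulate_puncta_stack(cfg, n_pairs = 20, overlap_fraction = 1)
  expect_equal(sum(ps$truth$colocalized), 20L)
  ps0 <- simulate_puncta_stack(sim_config(seed = 11), n_pairs = 10,
                               overlap_fraction = 0)
  expect_equal(sum(ps0$truth$colocalized & !ps0$truth$oversize &
                     !ps0$truth$undersize), 0L)
  # a planted 2.0 um^2 punctum is flagged oversize
  ps2 <- simulate_puncta_stack(sim_config(seed = 12), n_pairs = 5,
                               n_oversize = 1)
  expect_equal(sum(ps2$truth$oversize), 1L)
  expect_gt(ps2$truth$area_um2[ps2$truth$oversize], 1.2)
})

test_that("tree generator records exact cable length and crossings", {
  tr <- simulate_tree(sim_config(seed = 13))
  n <- tr$tree$nodes
  child <- n[n$parent != -1, ]
  p <- n[match(child$parent, n$id), ]
  manual_len <- sum(sqrt((child$x - p$x)^2 + (child$y - p$y)^2 +
                           (child$z - p$z)^2))
  expect_equal(tr$truth$total_length_um, manual_len, tolerance = 1e-12)
  oracle <- sholl_oracle(tr$tree, tr$truth$sholl$radius)
  expect_equal(tr$truth$sholl$crossings, oracle)
})
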