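test_that("template detection is exact on noiseless traces", {
  cfg <- sim_config(seed = 4, duration = 20000, noise_sd = 0,
                    event_rate = 0.5)
  sim <- simulate_event_trace(cfg, "mEPSC")
  ev <- detect_events_template(sim$sweep)
  expect_equal(nrow(ev), nrow(sim$truth$events))
  fs <- sim$sweep$sampling_rate
  expect_lt(max(abs(sort(ev$time) - sort(sim$truth$events$time))), 2.5 / fs)
  # amplitudes recovered (1 ms peak-window convention: small finite-window
  # bias only)
  expect_equal(mean(ev$peak_amp), 20, tolerance = 0.03)
  # per-event decay fits recover the kernel decay exactly without noise
  expect_equal(mean(ev$decay_tau), 5, tolerance = 0.02)
  expect_error(
    detect_events_template(sweep_trace(rnorm(100), 20, "pA"),
                           template = list(tau_rise = 0.5, tau_decay = 5)),
    "longer than trace")
})

test_that("detection is translation-invariant", {
  cfg <- sim_config(seed = 6, duration = 5000, noise_sd = 2, event_rate = 1)
  sim <- simulate_event_trace(cfg, "mEPSC")
  fs <- sim$sweep$sampling_rate
  m <- 37L
  shifted <- sweep_trace(c(sim$sweep$values[(m + 1):length(sim$sweep$values)],
                           sim$sweep$values[1:m]), fs, "pA")
  # compare over the common interior (wrap-around ends excluded)
  ev <- detect_events_template(sim$sweep, fit_decay = FALSE)
  evs <- detect_events_template(shifted, fit_decay = FALSE)
  interior <- ev$time > m / fs + 50 & ev$time < 4950
  expect_equal(evs$time[evs$time > 50 & evs$time < 4950 - m / fs] + m / fs,
               ev$time[interior], tolerance = 1e-9)
})

test_that("inhibitory (positive-going) events reuse the same machinery", {
  cfg <- sim_config(seed = 7, duration = 10000, noise_sd = 2, event_rate = 1)
  sim <- simulate_event_trace(cfg, "mEPSC")
  flipped <- sweep_trace(-sim$sweep$values, sim$sweep$sampling_rate, "pA")
  ev_in <- detect_events_template(sim$sweep, sign = -1, fit_decay = FALSE)
  ev_out <- detect_events_template(flipped, sign = +1, fit_decay = FALSE,
                                   condition = "mIPSC")
  expect_equal(ev_in$time, ev_out$time)
  expect_equal(ev_in$peak_amp, ev_out$peak_amp, tolerance = 1e-9)
})

test_that("event summaries compute intervals, amplitudes and decays", {
  ev <- data.frame(time = c(0, 100, 200), peak_time = c(1, 101, 201),
                   peak_amp = c(40, 40, 40), rise_10_90 = 0.5,
                   decay_tau = 5, charge = 200, detection_score = 10)
  s <- summarize_events(ev)
  expect_equal(s$mean_iei_ms, 100)
  expect_equal(s$mean_amp_pA, 40)
  expect_true(s$intervals_defined)
  s1 <- summarize_events(ev[1, ])
  expect_false(s1$intervals_defined)
  expect_true(is.na(s1$mean_iei_ms))
  # planted 40 pA quantal events, noiseless, full pipeline
  cfg <- sim_config(seed = 8, duration = 30000, noise_sd = 0,
                    event_rate = 1,
                    ampa_kernel = list(amp = 40, tau_rise = 0.5,
                                       tau_decay = 5))
  sim <- simulate_event_trace(cfg, "mEPSC")
  s2 <- summarize_events(detect_events_template(sim$sweep))
  expect_equal(s2$mean_amp_pA, 40, tolerance = 0.03)
  expect_equal(s2$mean_decay_ms, 5, tolerance = 0.05)
})

test_that("multiplicity comparison distinguishes null from multivesicular", {
  amp_null_a <- 20 + rnorm(200, sd = 2)
  set.seed(1)
  amp_null_a <- 20 + rnorm(200, sd = 2)
  amp_null_b <- 20 + rnorm(200, sd = 2)
  r <- multiplicity_compare(amp_null_a, amp_null_b)
  expect_equal(r$ratio, 1, tolerance = 0.05)
  expect_false(r$multiplicity_present)
  k <- 1 + rpois(200, 1)
  r2 <- multiplicity_compare(20 * k + rnorm(200, sd = 2), amp_null_b)
  expect_equal(r2$ratio, 2, tolerance = 0.1)
  expect_true(r2$multiplicity_present)
  expect_error(multiplicity_compare(numeric(0), amp_null_b), "non-empty")
})

test_that("input-output curve recovers planted peaks with artifact blanking", {
  cfg <- sim_config(seed = 9, noise_sd = 0)
  ev <- simulate_evoked_series(cfg)
  io <- io_curve(ev$sweeps, ev$stimuli_uA)
  expect_equal(io$io_points$peak_pA, ev$truth$true_peak, tolerance = 0.01)
  expect_equal(max(io$io_points$peak_pA), 800, tolerance = 0.02)
  expect_error(io_curve(ev$sweeps[1:3], ev$stimuli_uA), "lengths differ")
  # with noise, averaging 6 repeats keeps the error within the CLT bound
  cfgn <- sim_config(seed = 10, noise_sd = 10)
  evn <- simulate_evoked_series(cfgn, n_repeats = 6)
  ion <- io_curve(evn$sweeps, evn$stimuli_uA)
  expect_true(all(abs(ion$io_points$peak_pA - evn$truth$true_peak) <=
                    3 * 10 / sqrt(6) + 1))
})

test_that("paired-pulse ratio uses averaged traces and local baselines", {
  cfg0 <- sim_config(seed = 11, noise_sd = 0)
  pp1 <- simulate_paired_pulse(cfg0, A1 = 200, ppr = 1.0, n_traces = 2)
  expect_equal(paired_pulse_ratio(pp1$sweeps)$ppr, 1.0, tolerance = 0.02)
  pp2 <- simulate_paired_pulse(cfg0, A1 = 200, ppr = 1.5, n_traces = 2)
  expect_equal(paired_pulse_ratio(pp2$sweeps)$ppr, 1.5, tolerance = 0.02)
  # planted facilitation with noise, six averaged traces: within 10%
  cfgn <- sim_config(seed = 12, noise_sd = 8)
  pp3 <- simulate_paired_pulse(cfgn, A1 = 200, ppr = 1.5, n_traces = 6)
  expect_equal(paired_pulse_ratio(pp3$sweeps)$ppr, 1.5, tolerance = 0.1)
  # averaging idempotence: a trace averaged with itself changes nothing
  one <- pp3$sweeps[[1]]
  expect_equal(paired_pulse_ratio(list(one))$ppr,
               paired_pulse_ratio(list(one, one))$ppr)
  # an A1 below the noise floor is an undefined ratio
  ppz <- simulate_paired_pulse(sim_config(seed = 13, noise_sd = 5),
                               A1 = 0.5, ppr = 1, n_traces = 2)
  expect_error(paired_pulse_ratio(ppz$sweeps), "noise floor")
})
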