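test_that("average events reproduce the kernel and enforce min_n", {
  cfg <- sim_config(seed = 20, duration = 120000, noise_sd = 0,
                    event_rate = 1,
                    ampa_kernel = list(amp = 60, tau_rise = 0.5,
                                       tau_decay = 5))
  sim <- simulate_event_trace(cfg, "mEPSC")
  ev <- detect_events_template(sim$sweep, fit_decay = FALSE)
  avg <- build_average_event(ev, sim$sweep, min_n = 50,
                             condition = "AMPA_only")
  expect_gte(avg$n_events, 50)
  fs <- avg$sampling_rate
  # identical noiseless events: the average equals the kernel up to the
  # one-sample onset-detection discretization
  kern <- -biexp_kernel((0:(40 * fs)) / fs, 60, 0.5, 5, TRUE)
  on <- which(abs(kern) > 0.1 * 60)[1]
  post <- which(avg$t_ms >= 0)[1]
  n <- 20 * fs
  expect_lt(best_shift_maxdiff(avg$waveform[post + 0:n], kern[on + 0:n]),
            0.01 * 60)
  expect_equal(max(abs(avg$waveform)), 60, tolerance = 0.02)
  expect_error(build_average_event(ev[1:10, ], sim$sweep, min_n = 50),
               "insufficient")
})

test_that("noisy averages converge at the CLT rate", {
  cfg <- sim_config(seed = 21, duration = 120000, noise_sd = 3,
                    event_rate = 1,
                    ampa_kernel = list(amp = 60, tau_rise = 0.5,
                                       tau_decay = 5))
  sim <- simulate_event_trace(cfg, "dual")
  ev <- detect_events_template(sim$sweep, fit_decay = FALSE)
  avg <- build_average_event(ev, sim$sweep, min_n = 50)
  # on the slow decay (where onset-alignment jitter is negligible) the
  # average deviates from the planted dual kernel at the CLT rate
  fs <- avg$sampling_rate
  kern <- -(biexp_kernel((0:(60 * fs)) / fs, 60, 0.5, 5, TRUE) +
              biexp_kernel((0:(60 * fs)) / fs, 5, 5, 80, TRUE))
  on <- which(abs(kern) > 0.1 * max(abs(kern)))[1]
  post <- which(avg$t_ms >= 0)[1]
  idx <- seq(3 * fs, 40 * fs)
  resid <- avg$waveform[post + idx] - kern[on + idx]
  expect_lt(mean(abs(resid)), 3 * 3 / sqrt(avg$n_events))
})

test_that("charge decomposition matches the analytic kernel integrals", {
  dual <- kernel_average_event(100, 0.5, 5)
  nmda <- kernel_average_event(20, 5, 80)
  both <- dual
  both$waveform <- dual$waveform + nmda$waveform
  d <- decompose_ampa_nmda(both, dual)
  expect_equal(d$Q_ampa, 100 * (5 - 0.5), tolerance = 0.02)   # 450 fC
  expect_equal(d$Q_nmda, 20 * (80 - 5), tolerance = 0.02)     # 1500 fC
  expect_equal(d$ratio, 450 / 1500, tolerance = 0.02)
  # identical inputs: zero NMDA waveform, ratio flagged undefined
  same <- decompose_ampa_nmda(dual, dual)
  expect_false(same$ratio_defined)
  expect_true(is.na(same$ratio))
  expect_lt(max(abs(same$nmda_waveform)), 1e-12)
})

test_that("decomposition is linear and converges with sampling rate", {
  mk <- function(fs) {
    dual <- kernel_average_event(100, 0.5, 5, fs = fs)
    nm <- kernel_average_event(20, 5, 80, fs = fs)
    dual2 <- dual; dual2$waveform <- dual$waveform + nm$waveform
    decompose_ampa_nmda(dual2, dual)
  }
  d1 <- mk(20)
  # scaling both inputs by c scales charges by c, ratio unchanged
  dual <- kernel_average_event(100, 0.5, 5)
  nm <- kernel_average_event(20, 5, 80)
  both <- dual; both$waveform <- dual$waveform + nm$waveform
  sc_b <- both; sc_b$waveform <- 3 * both$waveform
  sc_a <- dual; sc_a$waveform <- 3 * dual$waveform
  d3 <- decompose_ampa_nmda(sc_b, sc_a)
  expect_equal(d3$Q_ampa, 3 * d1$Q_ampa, tolerance = 1e-9)
  expect_equal(d3$Q_nmda, 3 * d1$Q_nmda, tolerance = 1e-9)
  expect_equal(d3$ratio, d1$ratio, tolerance = 1e-9)
  # trapezoid error shrinks toward the analytic 450 fC as the rate doubles
  err <- sapply(c(20, 40, 80), function(fs)
    abs(mk(fs)$Q_ampa - 450) / 450)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.005)
})

test_that("single-event components apply the windows and inclusion gates", {
  fs <- 20
  tpk <- biexp_peak_time(0.5, 5)
  # one clean raw-multiplier AMPA event of 100 pA
  cfg <- sim_config(seed = 22, duration = 2000, noise_sd = 0,
                    event_rate = 0, normalize_peak = FALSE,
                    ampa_kernel = list(amp = 100, tau_rise = 0.5,
                                       tau_decay = 5))
  sim <- simulate_event_trace(cfg, "mEPSC")
  y <- sim$sweep$values
  i0 <- round(500 * fs) + 1L
  y[i0:length(y)] <- y[i0:length(y)] -
    biexp_kernel((0:(length(y) - i0)) / fs, 100, 0.5, 5, FALSE)
  sw <- sweep_trace(y, fs, "pA")
  ev <- detect_events_template(sw, fit_decay = FALSE)
  rows <- single_event_components(ev, sw, rms_noise = 1)
  expect_equal(nrow(rows), 1L)
  # late AMPA residual matches the closed-form window mean after the peak
  pk_ms <- ev$peak_time[1] - 500
  want <- biexp_window_mean(100, 0.5, 5, pk_ms + 22, pk_ms + 27,
                            normalize_peak = FALSE)
  expect_equal(rows$nmda_meas, want, tolerance = 0.05)
  # a 20 pA event fails the >= 30 pA gate
  y2 <- numeric(2000 * fs)
  y2[i0:length(y2)] <- -biexp_kernel((0:(length(y2) - i0)) / fs, 20, 0.5, 5,
                                     TRUE)
  sw2 <- sweep_trace(y2, fs, "pA")
  ev2 <- detect_events_template(sw2, fit_decay = FALSE)
  expect_equal(nrow(single_event_components(ev2, sw2, rms_noise = 1)), 0L)
})

test_that("dual-event single components equal NMDA window mean plus residual", {
  cfg <- sim_config(seed = 23, duration = 60000, noise_sd = 0,
                    event_rate = 0.5,
                    ampa_kernel = list(amp = 60, tau_rise = 0.5,
                                       tau_decay = 5))
  sim <- simulate_event_trace(cfg, "dual")
  ev <- detect_events_template(sim$sweep, fit_decay = FALSE)
  rows <- single_event_components(ev, sim$sweep, rms_noise = 0.5)
  expect_gt(nrow(rows), 5)
  # closed form: NMDA kernel mean over [pk+22, pk+27] (onset-shifted) plus
  # the AMPA decay residual over the same window
  pk_ms <- biexp_peak_time(0.5, 5)
  want <- biexp_window_mean(5, 5, 80, pk_ms + 22, pk_ms + 27, TRUE) +
    biexp_window_mean(60, 0.5, 5, pk_ms + 22, pk_ms + 27, TRUE)
  expect_equal(median(rows$nmda_meas), want, tolerance = 0.1)
})

test_that("component correlation and ANCOVA recover planted offsets", {
  set.seed(5)
  n <- 60
  ampa <- runif(n, 30, 90)
  nmda_a <- 0.1 * ampa + rnorm(n, sd = 0.5)
  nmda_b0 <- 0.1 * ampa + rnorm(n, sd = 0.5)
  rows_null <- data.frame(ampa_peak = c(ampa, ampa),
                          nmda_meas = c(nmda_a, nmda_b0))
  g <- rep(c("wt", "ko"), each = n)
  r0 <- correlate_components(rows_null, g)
  expect_gt(r0$group_p, 0.05)
  expect_lt(abs(r0$offsets), 0.3)
  # group B shifted down by 5 pA
  rows_sh <- rows_null
  rows_sh$nmda_meas[g == "wt"] <- rows_sh$nmda_meas[g == "wt"] - 5
  r1 <- correlate_components(rows_sh, g)
  expect_equal(unname(r1$offsets), -5, tolerance = 0.1)
  expect_lt(r1$group_p, 1e-6)
  # perfectly collinear data has r = 1
  rows_col <- data.frame(ampa_peak = 1:10, nmda_meas = (1:10) * 0.2)
  rc <- correlate_components(rows_col, rep("a", 10))
  expect_equal(rc$per_group$r, 1)
  expect_error(correlate_components(rows_col[1:2, ], rep("a", 2)),
               "at least 3")
})

test_that("tonic current analysis measures steps and RMS noise", {
  cfg <- sim_config(seed = 24)
  tb <- simulate_tonic_block(cfg, step_pA = 20, drug_ms = 15000,
                             duration_ms = 30000, noise_before = 0,
                             noise_after = 0)
  tc <- tonic_current(tb$sweep, 15000, event_times = numeric(0))
  expect_equal(tc$I_drug_sensitive, 20, tolerance = 1e-9)
  expect_equal(tc$rms_change, 0, tolerance = 1e-9)
  # equal noise, no step: null result with rms near the planted SD
  tb2 <- simulate_tonic_block(sim_config(seed = 25), step_pA = 0,
                              drug_ms = 15000, duration_ms = 30000,
                              noise_before = 5, noise_after = 5)
  tc2 <- tonic_current(tb2$sweep, 15000, event_times = numeric(0))
  expect_equal(tc2$I_drug_sensitive, 0, tolerance = 0.5)
  expect_equal(tc2$rms_before, 5, tolerance = 0.25)
  expect_equal(tc2$rms_after, 5, tolerance = 0.25)
  # event-dense traces leave too few clean regions and raise an error
  dense <- seq(0, 30000, by = 40)
  expect_error(tonic_current(tb2$sweep, 15000, event_times = dense),
               "regions found")
})
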