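#' Simulate a whole-cell membrane-test sweep
#'
#' Analytic two-compartment RC response of a voltage-clamped cell to a
#' hyperpolarizing voltage step: an instantaneous capacitive transient of
#' magnitude `|V|/Rs` relaxing with time constant
#' `tau = Cm * (Rs*Rm)/(Rs+Rm)` to the steady-state `|V|/(Rs+Rm)`, plus
#' Gaussian noise. Currents follow the physiological sign convention (a
#' hyperpolarizing step drives a negative-going current).
#'
#' @param cfg a [sim_config()]; membrane parameters are taken from
#'   `cfg$membrane`.
#' @param step_mV applied voltage step in mV (default -10).
#' @param baseline_ms,step_ms,post_ms epoch durations in ms.
#' @return list with elements `sweep` (a [sweep_trace()], units pA, epochs
#'   `baseline`/`step`/`post`) and `truth` (list with Rt, Rs, Rm, Cm, tau,
#'   Is, Ip — resistances MOhm, capacitance pF, tau ms, currents pA
#'   magnitudes).
#' @export
simulate_membrane_test <- function(cfg, step_mV = -10, baseline_ms = 50,
                                   step_ms = 100, post_ms = 50) {
  m <- cfg$membrane
  if (any(c(m$Rm, m$Rs, m$Cm) <= 0)) stop("membrane R and C must be positive")
  .sim_seed(cfg)
  fs <- cfg$sampling_rate
  Rt <- m$Rs + m$Rm
  tau <- m$Cm * (m$Rs * m$Rm / Rt) / 1000        # pF * MOhm = us -> ms
  Ip <- 1000 * abs(step_mV) / m$Rs               # pA
  Is <- 1000 * abs(step_mV) / Rt
  n_base <- round(baseline_ms * fs); n_step <- round(step_ms * fs)
  n_post <- round(post_ms * fs)
  t_step <- (seq_len(n_step) - 1L) / fs
  i_step <- Is + (Ip - Is) * exp(-t_step / tau)
  sgn <- sign(step_mV)
  vals <- c(rep(0, n_base), sgn * i_step, rep(0, n_post))
  if (cfg$noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, cfg$noise_sd)
  sw <- sweep_trace(vals, fs, "pA",
                    epochs = list(baseline = c(0, baseline_ms),
                                  step = c(baseline_ms, baseline_ms + step_ms),
                                  post = c(baseline_ms + step_ms,
                                           baseline_ms + step_ms + post_ms)),
                    meta = list(step_mV = step_mV))
  list(sweep = sw,
       truth = list(Rt = Rt, Rs = m$Rs, Rm = m$Rm, Cm = m$Cm, tau = tau,
                    Is = Is, Ip = Ip))
}

#' Simulate a family of current-step sweeps from a leaky integrate-and-fire cell
#'
#' One current-clamp voltage sweep per injected step (default -25 to 250 pA
#' in 25 pA increments, 500 ms steps). Between spikes the membrane follows the
#' exact exponential solution of the leaky integrator; when the voltage comes
#' within `v_tol` of threshold a stereotyped action-potential waveform (fast
#' linear upstroke to `spike_peak`, linear repolarization, absolute
#' refractory hold at rest) is pasted in and its onset time recorded. The
#' small `v_tol` makes the asymptotic analytic rheobase
#' `(Vth - Vrest)/Rm` attainable within a finite step (see the methods
#' vignette).
#'
#' @param cfg a [sim_config()].
#' @param steps_pA injected currents in pA.
#' @param step_ms,pre_ms,post_ms step and flanking durations, ms.
#' @param refractory_ms absolute refractory period after a spike, ms.
#' @param v_tol threshold-approach tolerance in mV.
#' @param spike_peak peak of the pasted action potential, mV.
#' @return list with `sweeps` (list of mV [sweep_trace()]s with
#'   `baseline`/`step`/`post` epochs and `meta$injected_pA`), and `truth`
#'   (list: `spike_times` per step in ms from sweep start, `rheobase_pA`
#'   analytic minimal sustained current, `steps_pA`).
#' @export
simulate_current_steps <- function(cfg, steps_pA = seq(-25, 250, by = 25),
                                   step_ms = 500, pre_ms = 100, post_ms = 100,
                                   refractory_ms = 5, v_tol = 0.01,
                                   spike_peak = 30) {
  m <- cfg$membrane
  if (m$Vth <= m$Vrest) stop("Vth must exceed Vrest")
  .sim_seed(cfg)
  fs <- cfg$sampling_rate; dt <- 1 / fs
  tau_m <- m$Rm * m$Cm / 1000                    # ms
  n_pre <- round(pre_ms * fs); n_step <- round(step_ms * fs)
  n_post <- round(post_ms * fs)
  n_tot <- n_pre + n_step + n_post
  up_n <- max(2L, round(0.5 * fs))               # 0.5 ms upstroke
  down_n <- max(2L, round(1.0 * fs))             # 1 ms repolarization
  ref_n <- round(refractory_ms * fs)
  decay <- exp(-dt / tau_m)
  sweeps <- vector("list", length(steps_pA))
  spike_times <- vector("list", length(steps_pA))
  for (s in seq_along(steps_pA)) {
    I <- steps_pA[s]
    v <- numeric(n_tot)
    v[seq_len(n_pre)] <- m$Vrest
    vinf <- m$Vrest + I * m$Rm / 1000            # pA * MOhm / 1000 = mV
    st <- numeric(0)
    i <- n_pre + 1L
    vcur <- m$Vrest
    while (i <= n_pre + n_step) {
      vcur <- vinf + (vcur - vinf) * decay
      if (vcur >= m$Vth - v_tol) {
        st <- c(st, (i - 1L) * dt)
        up <- seq(m$Vth, spike_peak, length.out = up_n)
        down <- seq(spike_peak, m$Vrest, length.out = down_n + 1L)[-1L]
        wave <- c(up, down, rep(m$Vrest, ref_n))
        j <- seq.int(i, min(i + length(wave) - 1L, n_tot))
        v[j] <- wave[seq_along(j)]
        i <- i + length(wave)
        vcur <- m$Vrest
      } else {
        v[i] <- vcur
        i <- i + 1L
      }
    }
    if (i <= n_tot) {
      for (k in seq.int(i, n_tot)) {
        vcur <- m$Vrest + (vcur - m$Vrest) * decay
        v[k] <- vcur
      }
    }
    if (cfg$noise_sd > 0)
      v <- v + stats::rnorm(n_tot, 0, cfg$noise_sd / 100)  # tiny mV jitter
    sweeps[[s]] <- sweep_trace(v, fs, "mV",
      epochs = list(baseline = c(0, pre_ms),
                    step = c(pre_ms, pre_ms + step_ms),
                    post = c(pre_ms + step_ms, pre_ms + step_ms + post_ms)),
      meta = list(injected_pA = I))
    spike_times[[s]] <- st
  }
  list(sweeps = sweeps,
       truth = list(spike_times = spike_times,
                    rheobase_pA = 1000 * (m$Vth - m$Vrest) / m$Rm,
                    steps_pA = steps_pA))
}

# draw Poisson event times on (edge_ms, duration - ...) with a refractory floor
.draw_event_times <- function(rate_hz, duration_ms, refractory_ms) {
  n <- stats::rpois(1L, rate_hz * duration_ms / 1000)
  if (n == 0L) return(numeric(0))
  tt <- sort(stats::runif(n, 0, duration_ms))
  if (refractory_ms > 0 && length(tt) > 1L) {
    keep <- c(TRUE, diff(tt) >= refractory_ms)
    # iterate: thinning can create new close pairs only towards earlier kept
    while (!all(keep)) {
      tt <- tt[keep]
      if (length(tt) < 2L) break
      keep <- c(TRUE, diff(tt) >= refractory_ms)
    }
  }
  tt
}

#' Simulate a trace of spontaneous or miniature synaptic currents
#'
#' Poisson event times (with a refractory floor between planted events); each
#' event is the sum of k independent quantal AMPA kernels, where k is drawn
#' from 1 + Poisson(`multiplicity_mean`) in `"sEPSC"` mode and fixed at 1 in
#' `"mEPSC"` mode. `"dual"` mode adds the slow NMDA kernel to every event
#' (Mg-free recording conditions) with k = 1. Events are negative-going;
#' Gaussian noise is added on top.
#'
#' @param cfg a [sim_config()].
#' @param mode `"mEPSC"`, `"sEPSC"` or `"dual"`.
#' @return list with `sweep` (pA [sweep_trace()]) and `truth` (data.frame
#'   `events` with columns time (ms), k, amp (planted summed amplitude, pA,
#'   magnitude), edge_flag for events within one kernel length of the trace
#'   end; plus `kernel_ms`, the kernel support used).
#' @export
simulate_event_trace <- function(cfg, mode = c("mEPSC", "sEPSC", "dual")) {
  mode <- match.arg(mode)
  .sim_seed(cfg)
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  ak <- cfg$ampa_kernel; nk <- cfg$nmda_kernel
  kernel_ms <- if (mode == "dual")
    nk$tau_rise + 5 * nk$tau_decay else ak$tau_rise + 5 * ak$tau_decay
  tt <- .draw_event_times(cfg$event_rate, cfg$duration, cfg$refractory_ms)
  k <- if (mode == "sEPSC" && length(tt))
    1L + stats::rpois(length(tt), cfg$multiplicity_mean)
  else rep(1L, length(tt))
  vals <- numeric(n)
  kern_n <- min(n, round(kernel_ms * fs))
  tk <- (seq_len(kern_n) - 1L) / fs
  base_a <- biexp_kernel(tk, ak$amp, ak$tau_rise, ak$tau_decay,
                         cfg$normalize_peak)
  base_nm <- biexp_kernel(tk, nk$amp, nk$tau_rise, nk$tau_decay,
                          cfg$normalize_peak)
  for (e in seq_along(tt)) {
    i0 <- .t2i(tt[e], fs)
    idx <- seq.int(i0, min(n, i0 + kern_n - 1L))
    add <- k[e] * base_a[seq_along(idx)]
    if (mode == "dual") add <- add + base_nm[seq_along(idx)]
    vals[idx] <- vals[idx] - add
  }
  if (cfg$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, cfg$noise_sd)
  truth <- data.frame(time = tt, k = k,
                      amp = k * ak$amp + (mode == "dual") * nk$amp,
                      edge_flag = tt > cfg$duration - kernel_ms)
  list(sweep = sweep_trace(vals, fs, "pA", meta = list(mode = mode)),
       truth = list(events = truth, kernel_ms = kernel_ms))
}

#' Simulate an evoked EPSC input-output series
#'
#' One compound EPSC per stimulus strength whose true peak follows a
#' configured sigmoid `peak(s) = max / (1 + exp(-(s - half)/slope))`; each
#' stimulus can be repeated with fresh noise. A brief positive stimulus
#' artifact is planted at stimulus onset to exercise artifact blanking.
#'
#' @param cfg a [sim_config()].
#' @param stimuli_uA stimulus strengths in uA.
#' @param sigmoid list `list(max, half, slope)` (pA, uA, uA).
#' @param n_repeats sweeps per stimulus.
#' @param stim_ms stimulus onset within each sweep, ms.
#' @param sweep_ms sweep duration, ms.
#' @param artifact_pA amplitude of the planted 0.2 ms stimulus artifact.
#' @return list with `sweeps` (list of lists of [sweep_trace()]s, one inner
#'   list per stimulus), `stimuli_uA`, and `truth` (data.frame stimulus,
#'   true_peak pA magnitude).
#' @export
simulate_evoked_series <- function(cfg, stimuli_uA = seq(10, 100, by = 10),
                                   sigmoid = list(max = 800, half = 40,
                                                  slope = 12),
                                   n_repeats = 1L, stim_ms = 20,
                                   sweep_ms = 120, artifact_pA = 400) {
  .sim_seed(cfg)
  fs <- cfg$sampling_rate
  peaks <- sigmoid$max / (1 + exp(-(stimuli_uA - sigmoid$half) / sigmoid$slope))
  ak <- cfg$ampa_kernel
  sweeps <- lapply(seq_along(stimuli_uA), function(s) {
    lapply(seq_len(n_repeats), function(r) {
      .evoked_sweep(cfg, peaks[s], stim_ms, sweep_ms, artifact_pA, ak)
    })
  })
  list(sweeps = sweeps, stimuli_uA = stimuli_uA,
       truth = data.frame(stimulus = stimuli_uA, true_peak = peaks))
}

.evoked_sweep <- function(cfg, peak_pA, stim_ms, sweep_ms, artifact_pA, ak,
                          second = NULL, isi = 50) {
  fs <- cfg$sampling_rate
  n <- round(sweep_ms * fs)
  vals <- numeric(n)
  add_event <- function(t0, pk) {
    i0 <- .t2i(t0, fs)
    kern_n <- min(n - i0 + 1L, round((ak$tau_rise + 6 * ak$tau_decay) * fs))
    tk <- (seq_len(kern_n) - 1L) / fs
    idx <- seq.int(i0, i0 + kern_n - 1L)
    vals[idx] <<- vals[idx] - biexp_kernel(tk, pk, ak$tau_rise, ak$tau_decay,
                                           TRUE)
  }
  add_artifact <- function(t0) {
    idx <- seq.int(.t2i(t0, fs), .t2i(t0 + 0.2, fs))
    vals[idx] <<- vals[idx] + artifact_pA
  }
  add_artifact(stim_ms); add_event(stim_ms + 0.5, peak_pA)
  if (!is.null(second)) {
    add_artifact(stim_ms + isi); add_event(stim_ms + isi + 0.5, second)
  }
  if (cfg$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, cfg$noise_sd)
  ep <- list(stim1 = c(stim_ms, stim_ms + 0.2))
  if (!is.null(second)) ep$stim2 <- c(stim_ms + isi, stim_ms + isi + 0.2)
  sweep_trace(vals, fs, "pA", epochs = ep, meta = list(stim_ms = stim_ms))
}

#' Simulate paired-pulse EPSC traces
#'
#' Two EPSCs 50 ms apart with configured first amplitude and paired-pulse
#' ratio, repeated `n_traces` times with independent noise (the analysis
#' averages them, mirroring the six-trace averaging convention).
#'
#' @param cfg a [sim_config()].
#' @param A1 first EPSC peak in pA (magnitude).
#' @param ppr planted paired-pulse ratio A2/A1.
#' @param n_traces number of traces.
#' @param isi inter-stimulus interval, ms.
#' @param stim_ms first stimulus onset, ms.
#' @param sweep_ms sweep duration, ms.
#' @param artifact_pA planted stimulus artifact amplitude.
#' @return list with `sweeps` (list of [sweep_trace()]s) and `truth`
#'   (list A1, A2, ppr).
#' @export
simulate_paired_pulse <- function(cfg, A1 = 200, ppr = 1.0, n_traces = 6L,
                                  isi = 50, stim_ms = 20, sweep_ms = 150,
                                  artifact_pA = 400) {
  .sim_seed(cfg)
  ak <- cfg$ampa_kernel
  sweeps <- lapply(seq_len(n_traces), function(r)
    .evoked_sweep(cfg, A1, stim_ms, sweep_ms, artifact_pA, ak,
                  second = A1 * ppr, isi = isi))
  list(sweeps = sweeps, truth = list(A1 = A1, A2 = A1 * ppr, ppr = ppr))
}

#' Simulate a holding-current trace with a pharmacological block step
#'
#' Emulates wash-in of a blocker of a tonic (standing) current: the holding
#' current steps by `step_pA` at `drug_ms` (reported drug-sensitive current =
#' mean before minus mean after = `step_pA`), and the baseline noise SD
#' changes from `noise_before` to `noise_after`. Optionally superimposes
#' synaptic events on both sides so that event-free region selection can be
#' exercised.
#'
#' @param cfg a [sim_config()].
#' @param step_pA planted drug-sensitive current, pA.
#' @param drug_ms drug application time, ms.
#' @param duration_ms total duration, ms (>= drug_ms + 10 s recommended).
#' @param noise_before,noise_after baseline noise SD, pA.
#' @param holding_pA holding current before the drug, pA.
#' @param with_events logical; plant synaptic events at `cfg$event_rate`.
#' @return list with `sweep` and `truth` (list step_pA, drug_ms,
#'   noise_before, noise_after, event_times).
#' @export
simulate_tonic_block <- function(cfg, step_pA = 20, drug_ms = 15000,
                                 duration_ms = 30000, noise_before = 5,
                                 noise_after = 3, holding_pA = -100,
                                 with_events = FALSE) {
  .sim_seed(cfg)
  fs <- cfg$sampling_rate
  n <- round(duration_ms * fs)
  t_axis <- (seq_len(n) - 1L) / fs
  after <- t_axis >= drug_ms
  vals <- rep(holding_pA, n)
  vals[after] <- holding_pA - step_pA
  sd_vec <- ifelse(after, noise_after, noise_before)
  if (any(sd_vec > 0)) vals <- vals + stats::rnorm(n, 0, sd_vec)
  ev <- numeric(0)
  if (with_events) {
    ak <- cfg$ampa_kernel
    ev <- .draw_event_times(cfg$event_rate, duration_ms, cfg$refractory_ms)
    kern_n <- round((ak$tau_rise + 5 * ak$tau_decay) * fs)
    tk <- (seq_len(kern_n) - 1L) / fs
    base <- biexp_kernel(tk, ak$amp, ak$tau_rise, ak$tau_decay,
                         cfg$normalize_peak)
    for (t0 in ev) {
      i0 <- .t2i(t0, fs)
      idx <- seq.int(i0, min(n, i0 + kern_n - 1L))
      vals[idx] <- vals[idx] - base[seq_along(idx)]
    }
  }
  list(sweep = sweep_trace(vals, fs, "pA", meta = list(drug_ms = drug_ms)),
       truth = list(step_pA = step_pA, drug_ms = drug_ms,
                    noise_before = noise_before, noise_after = noise_after,
                    event_times = ev))
}
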