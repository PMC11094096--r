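#' Passive membrane properties from a voltage-step membrane test
#'
#' From a voltage-clamp current sweep containing `baseline` and `step`
#' epochs: steady-state current `Is` (mean of the last quarter of the step,
#' baseline-subtracted), peak transient `Ip` (extremal baseline-subtracted
#' current in the step), decay time constant `tau` from a mono-exponential
#' least-squares fit of the transient (0.1 ms after the peak to the end of
#' the step), and
#' \deqn{R_t = V/I_s, \quad R_s = V/I_p, \quad R_m = R_t - R_s.}
#' Cell capacitance defaults to the conventional printed form
#' `Cm = tau * (Is + Ip)^2 / (V * Is)`; `cm_method = "two_compartment"`
#' instead uses the two-compartment identity `Cm = tau * (1/Rs + 1/Rm)`
#' (the two conventions differ in how the transient peak is referenced; see
#' the methods vignette).
#'
#' @param sweep a pA [sweep_trace()] with `baseline` and `step` epochs;
#'   the applied step (mV) is read from `sweep$meta$step_mV` unless given.
#' @param step_mV applied voltage step in mV (sign irrelevant; magnitudes
#'   are used throughout).
#' @param cm_method `"as_printed"` or `"two_compartment"`.
#' @param baseline_ms length of the pre-step window used for the baseline.
#' @return An object of class `"membrane_test"`: list with Rt, Rs, Rm
#'   (MOhm), Cm (pF), tau (ms), Is, Ip (pA magnitudes), V (mV magnitude).
#' @export
measure_membrane_test <- function(sweep, step_mV = NULL,
                                  cm_method = c("as_printed",
                                                "two_compartment"),
                                  baseline_ms = 50) {
  cm_method <- match.arg(cm_method)
  if (sweep$units != "pA") stop("membrane test requires a pA sweep")
  ep <- sweep$epochs
  if (is.null(ep$step) || is.null(ep$baseline))
    stop("sweep must carry 'baseline' and 'step' epochs")
  if (is.null(step_mV)) step_mV <- sweep$meta$step_mV
  if (is.null(step_mV)) stop("applied step size (mV) not provided")
  V <- abs(step_mV)
  fs <- sweep$sampling_rate
  t0 <- ep$step[1]; t1 <- ep$step[2]
  base <- .epoch_mean(sweep, max(ep$baseline[1], t0 - baseline_ms), t0)
  # steady state: mean of the last quarter of the step
  Is <- abs(.epoch_mean(sweep, t0 + 0.75 * (t1 - t0), t1) - base)
  i0 <- .t2i(t0, fs); i1 <- .t2i(t1, fs) - 1L
  seg <- sweep$values[i0:i1] - base
  ipk <- which.max(abs(seg))
  Ip <- abs(seg[ipk])
  if (Ip <= Is * (1 + 1e-9) || Is <= 0)
    stop("degenerate sweep: no detectable capacitive transient (Ip <= Is)")
  # mono-exponential fit of the decay, from 0.1 ms after the peak
  jstart <- ipk + max(1L, round(0.1 * fs))
  tt <- (seq.int(jstart, length(seg)) - ipk) / fs
  yy <- abs(seg[seq.int(jstart, length(seg))])
  excess <- yy - Is
  # log-linear initialization on clearly supra-steady-state samples
  pos <- which(excess > max(0.05 * (Ip - Is), 1e-12))
  if (length(pos) < 3L) stop("fit error: transient decays too fast to fit")
  ilin <- pos[seq_len(min(length(pos), max(10L, round(0.8 * length(pos)))))]
  lfit <- stats::lm(log(excess[ilin]) ~ tt[ilin])
  tau0 <- unname(-1 / stats::coef(lfit)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ Is_f + A * exp(-tt / tau),
                      start = list(Is_f = Is, A = Ip - Is, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: mono-exponential fit failed (",
                             conditionMessage(e), ")"))
  tau <- stats::coef(fit)[["tau"]]
  Rt <- 1000 * V / Is
  Rs <- 1000 * V / Ip
  Rm <- Rt - Rs
  Cm <- switch(cm_method,
               as_printed = tau * (Is + Ip)^2 / (V * Is),
               two_compartment = tau * 1000 * (1 / Rs + 1 / Rm))
  structure(list(Rt = Rt, Rs = Rs, Rm = Rm, Cm = Cm, tau = tau,
                 Is = Is, Ip = Ip, V = V, cm_method = cm_method),
            class = "membrane_test")
}

#' @export
print.membrane_test <- function(x, ...) {
  cat(sprintf("<membrane_test> Rt %.1f MOhm, Rs %.1f MOhm, Cm %.0f pF, tau %.2f ms\n",
              x$Rt, x$Rs, x$Cm, x$tau))
  invisible(x)
}

#' Series-resistance stability flag
#'
#' Marks a recording for exclusion when the series resistance changes by
#' more than `threshold` (default 20%) relative to its initial value at any
#' point in the recording.
#'
#' @param rs_values series resistance measurements over the recording, MOhm.
#' @param threshold relative change triggering exclusion.
#' @return logical: `TRUE` if the cell should be excluded.
#' @export
flag_rs_change <- function(rs_values, threshold = 0.2) {
  stopifnot(length(rs_values) >= 1L, all(rs_values > 0))
  any(abs(rs_values - rs_values[1]) / rs_values[1] > threshold)
}

#' Detect action potentials as threshold crossings
#'
#' Times of upward crossings of `crossing_mV` (default 0 mV) in a voltage
#' sweep, with a minimum separation (default 1 ms) between detections.
#'
#' @param sweep a mV [sweep_trace()].
#' @param crossing_mV detection level in mV.
#' @param min_separation minimum spacing between spikes, ms.
#' @return numeric vector of spike times in ms.
#' @export
detect_spikes <- function(sweep, crossing_mV = 0, min_separation = 1) {
  if (sweep$units != "mV") stop("spike detection requires a mV sweep")
  v <- sweep$values
  up <- which(v[-1] >= crossing_mV & v[-length(v)] < crossing_mV)
  if (!length(up)) return(numeric(0))
  tt <- up / sweep$sampling_rate   # time of the crossing sample
  keep <- c(TRUE, diff(tt) >= min_separation)
  while (!all(keep)) {
    tt <- tt[keep]
    if (length(tt) < 2L) break
    keep <- c(TRUE, diff(tt) >= min_separation)
  }
  tt
}

#' Excitability analysis of a current-step family
#'
#' Resting potential (mean pre-step voltage of the 0 pA sweep), the F-I
#' curve (spikes per step and firing frequency), the rheobase (first step
#' current eliciting at least one spike; `NA` with `rheobase_defined =
#' FALSE` if no step does), and the action-potential threshold voltage: the
#' membrane voltage at the first sample of the first spike's ascending phase
#' where dV/dt exceeds `dvdt_threshold` (3-point central difference at
#' native sampling).
#'
#' @param sweeps list of mV [sweep_trace()]s ordered by injected current;
#'   each must carry `meta$injected_pA` and a `step` epoch.
#' @param dvdt_threshold slope criterion in mV/ms.
#' @param crossing_mV spike-detection level passed to [detect_spikes()].
#' @return An object of class `"excitability_result"`: list with
#'   `resting_potential` (mV), `fi_curve` (data.frame current_pA, n_spikes,
#'   freq_hz), `rheobase` (pA or NA), `rheobase_defined`,
#'   `threshold_voltage` (mV or NA), `spike_times` (list, ms).
#' @export
analyze_excitability <- function(sweeps, dvdt_threshold = 20,
                                 crossing_mV = 0) {
  currents <- vapply(sweeps, function(s) s$meta$injected_pA, numeric(1))
  if (is.unsorted(currents)) stop("sweeps must be ordered by injected current")
  step_ep <- sweeps[[1]]$epochs$step
  if (is.null(step_ep)) stop("sweeps must carry a 'step' epoch")
  step_dur_s <- diff(step_ep) / 1000
  spikes <- lapply(sweeps, detect_spikes, crossing_mV = crossing_mV)
  fi <- data.frame(current_pA = currents,
                   n_spikes = lengths(spikes),
                   freq_hz = lengths(spikes) / step_dur_s)
  izero <- which(currents == 0)
  resting <- if (length(izero))
    .epoch_mean(sweeps[[izero[1]]], sweeps[[izero[1]]]$epochs$baseline[1],
                sweeps[[izero[1]]]$epochs$baseline[2]) else NA_real_
  ifirst <- which(fi$n_spikes >= 1L)
  if (!length(ifirst)) {
    return(structure(list(resting_potential = resting, fi_curve = fi,
                          rheobase = NA_real_, rheobase_defined = FALSE,
                          threshold_voltage = NA_real_,
                          spike_times = spikes),
                     class = "excitability_result"))
  }
  rheo_idx <- ifirst[1]
  sw <- sweeps[[rheo_idx]]
  fs <- sw$sampling_rate
  v <- sw$values
  spike1 <- spikes[[rheo_idx]][1]
  icross <- .t2i(spike1, fs)
  # scan the ascending phase: from 5 ms before the crossing up to it
  j0 <- max(2L, icross - round(5 * fs))
  dv <- (v[(j0 + 1):(icross + 1)] - v[(j0 - 1):(icross - 1)]) * fs / 2
  hit <- which(dv > dvdt_threshold)
  thr <- if (length(hit)) v[j0 + hit[1] - 1L] else NA_real_
  structure(list(resting_potential = resting, fi_curve = fi,
                 rheobase = currents[rheo_idx], rheobase_defined = TRUE,
                 threshold_voltage = thr, spike_times = spikes),
            class = "excitability_result")
}

#' @export
print.excitability_result <- function(x, ...) {
  cat(sprintf("<excitability_result> Vrest %.1f mV, rheobase %s pA, threshold %s mV\n",
              x$resting_potential,
              if (x$rheobase_defined) format(x$rheobase) else "undefined",
              if (is.na(x$threshold_voltage)) "NA"
              else sprintf("%.1f", x$threshold_voltage)))
  invisible(x)
}

#' Per-cell passive/excitability CSV export
#'
#' @param rows data.frame of per-cell results (one row per cell).
#' @param path output CSV path.
#' @export
write_cellprops_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
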