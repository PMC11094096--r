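#' Summary statistics of a detected event table
#'
#' Mean and median inter-event interval, mean peak amplitude and mean
#' fitted decay constant. With fewer than two events the interval summaries
#' are `NA` and flagged.
#'
#' @param events an `event_table` from [detect_events_template()].
#' @return list with `n_events`, `mean_iei_ms`, `median_iei_ms`,
#'   `mean_amp_pA`, `mean_decay_ms`, `frequency_hz`, `intervals_defined`.
#' @export
summarize_events <- function(events) {
  n <- nrow(events)
  iei <- if (n >= 2L) diff(events$time) else numeric(0)
  list(n_events = n,
       mean_iei_ms = if (n >= 2L) mean(iei) else NA_real_,
       median_iei_ms = if (n >= 2L) stats::median(iei) else NA_real_,
       mean_amp_pA = if (n) mean(events$peak_amp) else NA_real_,
       mean_decay_ms = if (n) mean(events$decay_tau, na.rm = TRUE)
       else NA_real_,
       frequency_hz = if (n >= 2L) 1000 / mean(iei) else NA_real_,
       intervals_defined = n >= 2L)
}

#' Compare sEPSC and mEPSC amplitudes (synaptic multiplicity)
#'
#' Multivesicular release manifests as spontaneous (action-potential-driven)
#' event amplitudes exceeding miniature amplitudes. Reports the mean
#' amplitude of each condition, their ratio, and the two-group comparison
#' routed through [select_two_group_test()]. A ratio > 1 together with a
#' significant difference is labeled "multiplicity present".
#'
#' @param sepsc,mepsc `event_table`s (or numeric amplitude vectors) for the
#'   two conditions.
#' @param alpha significance level.
#' @return list with `mean_sepsc`, `mean_mepsc`, `ratio`, `test`
#'   (a [select_two_group_test()] report) and `multiplicity_present`.
#' @export
multiplicity_compare <- function(sepsc, mepsc, alpha = 0.05) {
  amp_s <- if (is.data.frame(sepsc)) sepsc$peak_amp else sepsc
  amp_m <- if (is.data.frame(mepsc)) mepsc$peak_amp else mepsc
  if (!length(amp_s) || !length(amp_m))
    stop("both event tables must be non-empty")
  test <- select_two_group_test(amp_s, amp_m, alpha = alpha)
  ratio <- mean(amp_s) / mean(amp_m)
  list(mean_sepsc = mean(amp_s), mean_mepsc = mean(amp_m), ratio = ratio,
       test = test,
       multiplicity_present = ratio > 1 && test$p_value < alpha)
}

# peak EPSC magnitude of one sweep relative to a pre-stimulus baseline,
# with the stimulus artifact blanked
.evoked_peak <- function(sweep, stim_ms, blank_ms, window_ms, sign = -1,
                         baseline_ms = 10) {
  fs <- sweep$sampling_rate
  base <- .epoch_mean(sweep, max(0, stim_ms - baseline_ms), stim_ms)
  i0 <- .t2i(stim_ms + blank_ms, fs)
  i1 <- min(length(sweep$values), .t2i(stim_ms + window_ms, fs))
  max(sign * (sweep$values[i0:i1] - base))
}

#' Evoked EPSC input-output curve
#'
#' Per stimulus strength, the peak EPSC magnitude relative to the
#' pre-stimulus baseline; a configurable window after stimulus onset is
#' blanked to exclude the stimulus artifact. Repeat sweeps per stimulus are
#' averaged point-wise before the peak is measured.
#'
#' @param series list of [sweep_trace()]s, or list of lists (repeats per
#'   stimulus, averaged point-wise).
#' @param stimuli_uA stimulus strengths; length must match `series`.
#' @param stim_ms stimulus onset within each sweep, ms (default: from each
#'   sweep's `stim1` epoch).
#' @param blank_ms artifact blanking window after stimulus onset, ms.
#' @param window_ms search window for the peak after stimulus onset, ms.
#' @param sign -1 for inward EPSCs.
#' @return An object of class `"evoked_result"`: list with `io_points`
#'   (data.frame stimulus_uA, peak_pA) and `n_traces_averaged`.
#' @export
io_curve <- function(series, stimuli_uA, stim_ms = NULL, blank_ms = 1,
                     window_ms = 50, sign = -1) {
  if (length(series) != length(stimuli_uA))
    stop("'series' and 'stimuli_uA' lengths differ")
  peaks <- vapply(seq_along(series), function(s) {
    sws <- series[[s]]
    if (inherits(sws, "sweep")) sws <- list(sws)
    avg <- .average_sweeps(sws)
    t0 <- if (is.null(stim_ms)) avg$epochs$stim1[1] else stim_ms
    .evoked_peak(avg, t0, blank_ms, window_ms, sign)
  }, numeric(1))
  n_rep <- if (inherits(series[[1]], "sweep")) 1L else length(series[[1]])
  structure(list(io_points = data.frame(stimulus_uA = stimuli_uA,
                                        peak_pA = peaks),
                 n_traces_averaged = n_rep),
            class = "evoked_result")
}

.average_sweeps <- function(sws) {
  lens <- vapply(sws, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) stop("sweeps differ in length")
  avg <- Reduce(`+`, lapply(sws, `[[`, "values")) / length(sws)
  sweep_trace(avg, sws[[1]]$sampling_rate, sws[[1]]$units,
              epochs = sws[[1]]$epochs, meta = sws[[1]]$meta)
}

#' Paired-pulse ratio from repeated two-stimulus traces
#'
#' Traces are averaged point-wise first (the six-trace convention); the
#' first amplitude A1 is measured from the pre-first-stimulus baseline and
#' the second amplitude A2 from a local baseline immediately before the
#' second stimulus, both with the artifact window blanked. PPR = A2/A1.
#' With `a2_baseline = "decay"` the first response's fitted decay is
#' extrapolated and subtracted instead of using the local baseline.
#'
#' @param traces list of [sweep_trace()]s (>= 2 stimuli marked as `stim1`,
#'   `stim2` epochs).
#' @param blank_ms artifact blank after each stimulus, ms.
#' @param window_ms peak search window after each stimulus, ms.
#' @param sign -1 for inward EPSCs.
#' @param local_baseline_ms window immediately before the second stimulus
#'   used as A2 baseline, ms.
#' @param a2_baseline `"local"` or `"decay"`.
#' @param noise_floor_sd A1 must exceed this multiple of the baseline SD,
#'   otherwise the ratio is undefined and an error is raised.
#' @return An object of class `"evoked_result"`: list with `A1`, `A2`
#'   (pA magnitudes), `ppr`, `n_traces_averaged`.
#' @export
paired_pulse_ratio <- function(traces, blank_ms = 1, window_ms = 40,
                               sign = -1, local_baseline_ms = 2,
                               a2_baseline = c("local", "decay"),
                               noise_floor_sd = 3) {
  a2_baseline <- match.arg(a2_baseline)
  if (length(traces) < 1L) stop("need at least one trace")
  avg <- .average_sweeps(traces)
  ep <- avg$epochs
  if (is.null(ep$stim1) || is.null(ep$stim2))
    stop("traces must carry 'stim1' and 'stim2' epochs")
  fs <- avg$sampling_rate
  t1 <- ep$stim1[1]; t2 <- ep$stim2[1]
  base1 <- .epoch_mean(avg, max(0, t1 - 10), t1)
  b_i0 <- max(1L, .t2i(t1 - 10, fs)); b_i1 <- .t2i(t1, fs) - 1L
  base_sd <- stats::sd(avg$values[b_i0:b_i1])
  A1 <- .evoked_peak(avg, t1, blank_ms, min(window_ms, t2 - t1 - 1), sign)
  if (!is.finite(A1) || (base_sd > 0 && A1 < noise_floor_sd * base_sd))
    stop("undefined ratio: A1 is below the noise floor")
  if (a2_baseline == "local") {
    base2 <- .epoch_mean(avg, t2 - local_baseline_ms, t2)
    i0 <- .t2i(t2 + blank_ms, fs)
    i1 <- min(length(avg$values), .t2i(t2 + window_ms, fs))
    A2 <- max(sign * (avg$values[i0:i1] - base2))
  } else {
    # extrapolate the first response's mono-exponential decay under pulse 2
    i_pk1 <- .t2i(t1 + blank_ms, fs) - 1L +
      which.max(sign * (avg$values[.t2i(t1 + blank_ms, fs):
                                     .t2i(t2, fs)] - base1))
    dec <- sign * (avg$values[i_pk1:( .t2i(t2, fs) - 1L)] - base1)
    tau <- .fast_monoexp_tau(dec, fs)
    i0 <- .t2i(t2 + blank_ms, fs)
    i1 <- min(length(avg$values), .t2i(t2 + window_ms, fs))
    tt <- (seq.int(i0, i1) - i_pk1) / fs
    pred <- dec[1] * exp(-tt / tau)
    A2 <- max(sign * (avg$values[i0:i1] - base1) - pred)
  }
  structure(list(A1 = A1, A2 = A2, ppr = A2 / A1,
                 n_traces_averaged = length(traces)),
            class = "evoked_result")
}

#' @export
print.evoked_result <- function(x, ...) {
  if (!is.null(x$ppr))
    cat(sprintf("<evoked_result> A1 %.1f pA, A2 %.1f pA, PPR %.3f (n=%d averaged)\n",
                x$A1, x$A2, x$ppr, x$n_traces_averaged))
  else
    cat(sprintf("<evoked_result> I/O curve, %d stimuli, max peak %.1f pA\n",
                nrow(x$io_points), max(x$io_points$peak_pA)))
  invisible(x)
}
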