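#' Build an onset-aligned average event
#'
#' Extracts a snippet around every detected event, subtracts a local
#' baseline, aligns the snippets at the detected onset (first sample
#' exceeding 10% of the event peak) and averages them point-wise. Events too
#' close to the trace edges, or whose window collides with the next event,
#' are skipped.
#'
#' @param events an `event_table` from [detect_events_template()].
#' @param sweep the source pA [sweep_trace()].
#' @param min_n minimum number of usable events (default 50, the averaging
#'   convention for per-cell mean mEPSCs).
#' @param pre_ms,post_ms snippet extent around the onset, ms.
#' @param condition label (`"dual"` or `"AMPA_only"`).
#' @return An object of class `"average_event"`: list with `waveform`
#'   (pA, baseline-subtracted, onset at `t = 0`), `t_ms`, `n_events`,
#'   `sampling_rate`, `condition`.
#' @export
build_average_event <- function(events, sweep, min_n = 50, pre_ms = 5,
                                post_ms = 150, condition = "dual") {
  fs <- sweep$sampling_rate
  y <- sweep$values
  pre_n <- round(pre_ms * fs); post_n <- round(post_ms * fs)
  used <- 0L
  acc <- numeric(pre_n + post_n + 1L)
  for (e in seq_len(nrow(events))) {
    i_on <- .event_onset_index(events, e, y, fs)
    if (is.na(i_on)) next
    if (i_on - pre_n < 1L || i_on + post_n > length(y)) next
    if (e < nrow(events) &&
        events$time[e + 1L] * fs + 1 < i_on + post_n * 0.25) next
    # a preceding event inside the baseline window spoils the alignment
    if (e > 1L && events$peak_time[e - 1L] * fs + 1 > i_on - pre_n -
          round(20 * fs)) next
    snip <- y[(i_on - pre_n):(i_on + post_n)]
    base <- mean(snip[seq_len(max(1L, pre_n - round(0.5 * fs)))])
    acc <- acc + (snip - base)
    used <- used + 1L
  }
  if (used < min_n)
    stop(sprintf("insufficient events: %d usable, %d required", used, min_n))
  structure(list(waveform = acc / used,
                 t_ms = (seq_along(acc) - pre_n - 1L) / fs,
                 n_events = used, sampling_rate = fs, condition = condition),
            class = "average_event")
}

# onset = first sample of the rising limb exceeding 10% of the event peak
# (the last upward 10% crossing before the peak, so the tail of a preceding
# event cannot masquerade as the onset)
.event_onset_index <- function(events, e, y, fs) {
  i_pk <- .t2i(events$peak_time[e], fs)
  i0 <- max(1L, .t2i(events$time[e], fs) - round(1 * fs))
  base <- mean(y[max(1L, i0 - round(2 * fs)):i0])
  seg <- abs(y[i0:i_pk] - base)
  pk <- max(seg)
  if (pk <= 0 || length(seg) < 2L) return(NA_integer_)
  thr <- 0.1 * pk
  cross <- which(seg[-1] > thr & seg[-length(seg)] <= thr)
  if (!length(cross)) return(NA_integer_)
  i0 + cross[length(cross)]
}

#' @export
print.average_event <- function(x, ...) {
  cat(sprintf("<average_event> %s, n=%d events, peak %.1f pA\n",
              x$condition, x$n_events, max(abs(x$waveform))))
  invisible(x)
}

#' AMPA/NMDA charge decomposition of averaged events
#'
#' The NMDA waveform is the point-wise difference between the average
#' dual-component (Mg-free) event and the average pharmacologically
#' isolated AMPA-only event, both aligned at onset. Charges are trapezoidal
#' areas of the magnitude waveforms from onset to return-to-baseline
#' (capped at `cap_ms` after onset); the ratio is Q_ampa / Q_nmda.
#'
#' @param dual,ampa_only [build_average_event()] objects at the same
#'   sampling rate.
#' @param cap_ms integration cap after onset, ms.
#' @param zero_tol charges below this fraction of Q_ampa mark the NMDA
#'   component as absent (ratio flagged undefined).
#' @return An object of class `"dual_component"`: list with `Q_ampa`,
#'   `Q_nmda` (fC), `ratio` (NA when flagged), `ratio_defined`,
#'   `nmda_waveform`, `t_ms`.
#' @export
decompose_ampa_nmda <- function(dual, ampa_only, cap_ms = 500,
                                zero_tol = 1e-3) {
  if (dual$sampling_rate != ampa_only$sampling_rate)
    stop("averages must share a sampling rate")
  n <- min(length(dual$waveform), length(ampa_only$waveform))
  w_d <- dual$waveform[seq_len(n)]
  w_a <- ampa_only$waveform[seq_len(n)]
  t_ms <- dual$t_ms[seq_len(n)]
  nmda <- w_d - w_a
  fs <- dual$sampling_rate
  Q_ampa <- .component_charge(w_a, t_ms, fs, cap_ms)
  Q_nmda <- .component_charge(nmda, t_ms, fs, cap_ms)
  defined <- Q_nmda > zero_tol * max(Q_ampa, 1e-12)
  structure(list(Q_ampa = Q_ampa, Q_nmda = Q_nmda,
                 ratio = if (defined) Q_ampa / Q_nmda else NA_real_,
                 ratio_defined = defined, nmda_waveform = nmda, t_ms = t_ms),
            class = "dual_component")
}

# area of the magnitude waveform from onset (t = 0) to return-to-baseline
.component_charge <- function(w, t_ms, fs, cap_ms) {
  sel <- which(t_ms >= 0 & t_ms <= cap_ms)
  if (!length(sel)) return(0)
  seg <- w[sel]
  sgn <- if (sum(seg) < 0) -1 else 1
  seg <- sgn * seg
  i_pk <- which.max(seg)
  ret <- which(seg[seq.int(i_pk, length(seg))] <= 0)
  end <- if (length(ret)) i_pk + ret[1] - 2L else length(seg)
  .trapz(pmax(seg[seq_len(max(end, 2L))], 0), 1 / fs)
}

#' @export
print.dual_component <- function(x, ...) {
  cat(sprintf("<dual_component> Q_ampa %.0f fC, Q_nmda %.0f fC, ratio %s\n",
              x$Q_ampa, x$Q_nmda,
              if (x$ratio_defined) sprintf("%.3f", x$ratio) else "undefined"))
  invisible(x)
}

#' Single-event AMPA peak and late NMDA measurements
#'
#' For every detected event on a dual-component (Mg-free) trace, the AMPA
#' peak is the mean current over a 1 ms window centered on the event peak
#' and the NMDA measurement the mean over a 5 ms window 22-27 ms after that
#' peak, both baseline-subtracted magnitudes. Events are retained only if
#' the AMPA peak is at least `min_amp_pA` (|peak| >= 30 pA convention for
#' inward currents) and at least `rms_factor` times the RMS baseline noise;
#' events whose late window collides with the next event are dropped.
#'
#' @param events an `event_table`.
#' @param sweep the source pA [sweep_trace()].
#' @param rms_noise RMS baseline noise in pA.
#' @param min_amp_pA absolute inclusion threshold, pA.
#' @param rms_factor noise-significance gate (multiples of `rms_noise`).
#' @param sign -1 for inward events.
#' @param window_ms c(late window start, end) after the peak, ms.
#' @return data.frame with columns `time`, `ampa_peak`, `nmda_meas` (pA
#'   magnitudes); zero rows is a valid result.
#' @export
single_event_components <- function(events, sweep, rms_noise,
                                    min_amp_pA = 30, rms_factor = 3,
                                    sign = -1, window_ms = c(22, 27)) {
  fs <- sweep$sampling_rate
  y <- sweep$values
  half <- round(0.5 * fs)
  rows <- lapply(seq_len(nrow(events)), function(e) {
    i_pk <- .t2i(events$peak_time[e], fs)
    i_on <- .t2i(events$time[e], fs)
    b0 <- max(1L, i_on - round(2 * fs)); b1 <- max(1L, i_on - 1L)
    base <- mean(y[b0:b1])
    w0 <- max(1L, i_pk - half); w1 <- min(length(y), i_pk + half)
    ampa <- sign * (mean(y[w0:w1]) - base)
    l0 <- .t2i(events$peak_time[e] + window_ms[1], fs)
    l1 <- .t2i(events$peak_time[e] + window_ms[2], fs)
    if (l1 > length(y)) return(NULL)
    if (e < nrow(events) &&
        events$time[e + 1L] <= events$peak_time[e] + window_ms[2])
      return(NULL)
    nmda <- sign * (mean(y[l0:l1]) - base)
    data.frame(time = events$time[e], ampa_peak = ampa, nmda_meas = nmda)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(time = numeric(0), ampa_peak = numeric(0),
                       nmda_meas = numeric(0))
  rows[rows$ampa_peak >= min_amp_pA &
         rows$ampa_peak >= rms_factor * rms_noise, , drop = FALSE]
}

#' Correlate single-event NMDA measurements with AMPA peaks across groups
#'
#' Per group, the Pearson correlation of the late NMDA measurement against
#' the AMPA peak; across groups, a common-slope linear model with additive
#' group offsets (classical ANCOVA with the AMPA peak as covariate) whose
#' group term is tested by sequential sums of squares.
#'
#' @param rows data.frame with columns `ampa_peak`, `nmda_meas` (from
#'   [single_event_components()]).
#' @param group factor/character of group labels, one per row.
#' @return list with `per_group` (data.frame group, n, r, p), `slope`,
#'   `offsets` (named intercept offsets vs the first group, pA),
#'   `group_p` (ANCOVA group effect), `model` (the fitted `lm`).
#' @export
correlate_components <- function(rows, group) {
  group <- factor(group)
  if (nrow(rows) != length(group)) stop("group labels must match rows")
  tab <- table(group)
  if (any(tab < 3L))
    stop("need at least 3 rows per group (got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  per <- do.call(rbind, lapply(levels(group), function(g) {
    d <- rows[group == g, ]
    ct <- suppressWarnings(stats::cor.test(d$ampa_peak, d$nmda_meas))
    data.frame(group = g, n = nrow(d), r = unname(ct$estimate),
               p = ct$p.value)
  }))
  d <- data.frame(nmda = rows$nmda_meas, ampa = rows$ampa_peak, g = group)
  if (nlevels(group) < 2L) {
    fit <- stats::lm(nmda ~ ampa, data = d)
    return(list(per_group = per, slope = unname(stats::coef(fit)[["ampa"]]),
                offsets = numeric(0), group_p = NA_real_, model = fit))
  }
  fit <- stats::lm(nmda ~ ampa + g, data = d)
  an <- stats::anova(fit)
  cf <- stats::coef(fit)
  offs <- cf[grep("^g", names(cf))]
  names(offs) <- sub("^g", "", names(offs))
  list(per_group = per, slope = unname(cf[["ampa"]]), offsets = offs,
       group_p = an["g", "Pr(>F)"], model = fit)
}

#' Tonic current and RMS noise around a pharmacological block
#'
#' The drug-sensitive current is the mean holding current over a 10 s
#' window before drug application minus the mean over a 10 s window after
#' it. RMS noise per side is the average SD over ten automatically selected
#' 100 ms regions free of synaptic events (no detected event within
#' `event_clearance_ms`); selection is a greedy left-to-right scan.
#'
#' @param sweep the holding-current pA [sweep_trace()].
#' @param drug_ms drug application time, ms.
#' @param event_times detected event times in ms (e.g. from
#'   [detect_events_template()]); `NULL` runs the template detector.
#' @param window_s width of the mean-current windows, s.
#' @param n_regions regions per side for the RMS estimate.
#' @param region_ms region duration, ms.
#' @param event_clearance_ms exclusion zone around events, ms.
#' @param settle_ms dead time after `drug_ms` excluded from the "after"
#'   analyses, ms.
#' @return An object of class `"tonic_result"`: list with
#'   `I_drug_sensitive` (pA), `rms_before`, `rms_after`, `rms_change` (pA),
#'   and the selected region start times.
#' @export
tonic_current <- function(sweep, drug_ms, event_times = NULL, window_s = 10,
                          n_regions = 10, region_ms = 100,
                          event_clearance_ms = 20, settle_ms = 500) {
  fs <- sweep$sampling_rate
  dur <- sweep_duration(sweep)
  win <- window_s * 1000
  if (drug_ms < win || dur - drug_ms - settle_ms < win)
    stop(sprintf("need >= %g s of trace on each side of drug_ms", window_s))
  if (is.null(event_times))
    event_times <- detect_events_template(sweep, fit_decay = FALSE)$time
  mean_before <- .epoch_mean(sweep, drug_ms - win, drug_ms)
  mean_after <- .epoch_mean(sweep, drug_ms + settle_ms,
                            drug_ms + settle_ms + win)
  pick <- function(t_lo, t_hi) {
    starts <- numeric(0)
    t <- t_lo
    while (t + region_ms <= t_hi && length(starts) < n_regions) {
      clear <- !any(event_times > t - event_clearance_ms &
                      event_times < t + region_ms + event_clearance_ms)
      if (clear) {
        starts <- c(starts, t)
        t <- t + region_ms
      } else t <- t + region_ms / 2
    }
    starts
  }
  reg_b <- pick(max(0, drug_ms - win), drug_ms - region_ms)
  reg_a <- pick(drug_ms + settle_ms, dur - region_ms)
  for (nm in c("before", "after")) {
    rg <- if (nm == "before") reg_b else reg_a
    if (length(rg) < n_regions)
      stop(sprintf("only %d event-free %g ms regions found %s the drug (%d required)",
                   length(rg), region_ms, nm, n_regions))
  }
  region_sd <- function(starts) {
    mean(vapply(starts, function(t0) {
      i0 <- .t2i(t0, fs); i1 <- .t2i(t0 + region_ms, fs) - 1L
      stats::sd(sweep$values[i0:i1])
    }, numeric(1)))
  }
  rms_b <- region_sd(reg_b); rms_a <- region_sd(reg_a)
  structure(list(I_drug_sensitive = mean_before - mean_after,
                 rms_before = rms_b, rms_after = rms_a,
                 rms_change = rms_b - rms_a,
                 regions_before = reg_b, regions_after = reg_a),
            class = "tonic_result")
}

#' @export
print.tonic_result <- function(x, ...) {
  cat(sprintf("<tonic_result> drug-sensitive current %.2f pA, RMS %.2f -> %.2f pA\n",
              x$I_drug_sensitive, x$rms_before, x$rms_after))
  invisible(x)
}
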