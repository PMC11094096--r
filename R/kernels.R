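#' Bi-exponential synaptic kernel
#'
#' The canonical difference-of-exponentials postsynaptic current waveform
#' \deqn{g(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r}), \quad t \ge 0,}
#' with rise constant \eqn{\tau_r} and decay constant \eqn{\tau_d}
#' (\eqn{\tau_d > \tau_r > 0}). With `normalize_peak = TRUE` (the default)
#' the waveform is rescaled so that its maximum equals `amp`, i.e. `amp` is
#' the planted event peak; with `FALSE`, `amp` is the raw multiplier and the
#' time integral is exactly `amp * (tau_decay - tau_rise)`.
#'
#' @param t time in ms (numeric vector); values < 0 give 0.
#' @param amp amplitude in pA (magnitude; sign applied by callers).
#' @param tau_rise,tau_decay rise and decay time constants in ms.
#' @param normalize_peak logical; see Details.
#' @return numeric vector of kernel values (pA).
#' @export
biexp_kernel <- function(t, amp, tau_rise, tau_decay, normalize_peak = TRUE) {
  .check_taus(tau_rise, tau_decay)
  g <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  if (normalize_peak) g <- g / .biexp_peak_factor(tau_rise, tau_decay)
  amp * g
}

.check_taus <- function(tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("kernel requires tau_decay > tau_rise > 0")
}

# value of the raw difference-of-exponentials at its peak
.biexp_peak_factor <- function(tau_rise, tau_decay) {
  tpk <- biexp_peak_time(tau_rise, tau_decay)
  exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
}

#' @rdname biexp_kernel
#' @return `biexp_peak_time`: time of the kernel maximum in ms.
#' @export
biexp_peak_time <- function(tau_rise, tau_decay) {
  .check_taus(tau_rise, tau_decay)
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Analytic charge and window mean of the bi-exponential kernel
#'
#' `biexp_charge` is the full time integral (pA * ms = fC);
#' `biexp_window_mean` the mean current over a window `[t0, t1]` ms, used as
#' the closed form for late residuals of fast kernels.
#'
#' @inheritParams biexp_kernel
#' @param t0,t1 window bounds in ms.
#' @return charge in fC, or mean current in pA.
#' @export
biexp_charge <- function(amp, tau_rise, tau_decay, normalize_peak = TRUE) {
  q <- amp * (tau_decay - tau_rise)
  if (normalize_peak) q <- q / .biexp_peak_factor(tau_rise, tau_decay)
  q
}

#' @rdname biexp_charge
#' @export
biexp_window_mean <- function(amp, tau_rise, tau_decay, t0, t1,
                              normalize_peak = TRUE) {
  .check_taus(tau_rise, tau_decay)
  stopifnot(t1 > t0, t0 >= 0)
  int <- tau_decay * (exp(-t0 / tau_decay) - exp(-t1 / tau_decay)) -
    tau_rise * (exp(-t0 / tau_rise) - exp(-t1 / tau_rise))
  s <- amp / (t1 - t0)
  if (normalize_peak) s <- s / .biexp_peak_factor(tau_rise, tau_decay)
  s * int
}

# trapezoidal integral with uniform spacing dt
.trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}
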