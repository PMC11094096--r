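#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator in one validated object. Defaults
#' reflect typical CA1 whole-cell recording conditions: 20 kHz digitization,
#' quantal AMPA events of 20 pA peak riding on 4 pA Gaussian baseline noise
#' (peak/noise = 5), an mEPSC rate of 2 Hz, a fast AMPA kernel
#' (tau_r 0.5 ms / tau_d 5 ms) and a slow NMDA kernel (tau_r 5 ms /
#' tau_d 80 ms) so that currents 22-27 ms after the AMPA peak are almost
#' purely NMDA-mediated.
#'
#' @param seed integer seed; together with the config it fully determines
#'   every generated output.
#' @param sampling_rate sampling rate in kHz.
#' @param duration trace duration in ms.
#' @param noise_sd Gaussian current noise SD in pA.
#' @param event_rate Poisson synaptic event rate in Hz.
#' @param ampa_kernel,nmda_kernel lists `list(amp, tau_rise, tau_decay)`
#'   (pA, ms, ms).
#' @param multiplicity_mean mean of the Poisson count added to 1 to form the
#'   per-event release-site multiplicity k (k = 1 + Poisson(multiplicity_mean);
#'   0 gives the mEPSC-like k = 1 case).
#' @param membrane list `list(Rm, Rs, Cm, Vrest, Vth)` in MOhm, MOhm, pF, mV,
#'   mV.
#' @param refractory_ms floor between consecutive planted synaptic events, ms.
#' @param normalize_peak logical; if `TRUE` kernel `amp` is the event peak,
#'   if `FALSE` the raw bi-exponential multiplier (see [biexp_kernel()]).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       sampling_rate = 20,
                       duration = 60000,
                       noise_sd = 4,
                       event_rate = 2,
                       ampa_kernel = list(amp = 20, tau_rise = 0.5, tau_decay = 5),
                       nmda_kernel = list(amp = 5, tau_rise = 5, tau_decay = 80),
                       multiplicity_mean = 1,
                       membrane = list(Rm = 150, Rs = 10, Cm = 200,
                                       Vrest = -70, Vth = -50),
                       refractory_ms = 2,
                       normalize_peak = TRUE) {
  stopifnot(sampling_rate > 0, duration > 0, noise_sd >= 0, event_rate >= 0,
            multiplicity_mean >= 0, refractory_ms >= 0)
  for (k in list(ampa_kernel, nmda_kernel)) {
    .check_taus(k$tau_rise, k$tau_decay)
    if (k$amp < 0) stop("kernel amplitudes are magnitudes and must be >= 0")
  }
  with(membrane, {
    if (any(c(Rm, Rs, Cm) <= 0))
      stop("membrane Rm, Rs, Cm must be positive")
    if (Vth <= Vrest) stop("membrane Vth must exceed Vrest")
  })
  structure(list(seed = as.integer(seed), sampling_rate = sampling_rate,
                 duration = duration, noise_sd = noise_sd,
                 event_rate = event_rate, ampa_kernel = ampa_kernel,
                 nmda_kernel = nmda_kernel,
                 multiplicity_mean = multiplicity_mean, membrane = membrane,
                 refractory_ms = refractory_ms,
                 normalize_peak = normalize_peak),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, %g kHz, %g ms, noise %g pA, rate %g Hz\n",
              x$seed, x$sampling_rate, x$duration, x$noise_sd, x$event_rate))
  invisible(x)
}

# seed the RNG for one simulation call; sub-streams for secondary channels
# are derived deterministically by offsetting within 2^31
.sim_seed <- function(cfg, offset = 0L) {
  set.seed((cfg$seed + 1664525L * offset) %% .Machine$integer.max)
}
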