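#' Sampled electrophysiology trace
#'
#' Lightweight container for a single recorded or simulated sweep. Time is
#' always in milliseconds, current in pA, voltage in mV; inward (excitatory)
#' currents are negative.
#'
#' @param values numeric vector of samples.
#' @param sampling_rate sampling rate in kHz (samples per ms).
#' @param units `"pA"` or `"mV"`.
#' @param epochs named list of `c(start_ms, end_ms)` intervals (e.g. baseline,
#'   step) used by downstream analyses.
#' @param holding_potential optional holding potential in mV.
#' @param meta free-form list of metadata.
#' @return An object of class `"sweep"`.
#' @export
sweep_trace <- function(values, sampling_rate, units = c("pA", "mV"),
                        epochs = list(), holding_potential = NULL,
                        meta = list()) {
  units <- match.arg(units)
  if (!is.numeric(values) || length(values) < 2L)
    stop("'values' must be a numeric vector with at least two samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number (kHz)")
  dur <- length(values) / sampling_rate
  for (nm in names(epochs)) {
    ep <- epochs[[nm]]
    if (length(ep) != 2L || ep[1] < 0 || ep[2] > dur + 1e-9 || ep[1] >= ep[2])
      stop(sprintf("epoch '%s' must lie within [0, %.3f] ms", nm, dur))
  }
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 units = units, epochs = epochs,
                 holding_potential = holding_potential, meta = meta),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %d samples @ %g kHz (%.1f ms), units %s\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate, x$units))
  if (length(x$epochs))
    cat("  epochs:", paste(names(x$epochs), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of a sweep in ms
#'
#' @param sweep a [sweep_trace()] object.
#' @return numeric vector of sample times (ms); first sample at t = 0.
#' @export
sweep_time <- function(sweep) {
  (seq_along(sweep$values) - 1L) / sweep$sampling_rate
}

#' Sweep duration in ms
#' @param sweep a [sweep_trace()] object.
#' @export
sweep_duration <- function(sweep) length(sweep$values) / sweep$sampling_rate

# sample index of a time point (1-based, first sample is t = 0)
.t2i <- function(t_ms, sampling_rate) as.integer(round(t_ms * sampling_rate)) + 1L

# mean of a sweep over a time interval [t0, t1) in ms
.epoch_mean <- function(sweep, t0, t1) {
  i0 <- max(1L, .t2i(t0, sweep$sampling_rate))
  i1 <- min(length(sweep$values), .t2i(t1, sweep$sampling_rate) - 1L)
  mean(sweep$values[i0:i1])
}

#' Write / read a sweep as a plain-text trace container
#'
#' Samples go into a one-column CSV; sampling rate, units, epochs and metadata
#' into a JSON sidecar with the same stem and extension `.json`.
#'
#' @param sweep a [sweep_trace()] object.
#' @param path CSV file path.
#' @return `write_sweep` invisibly returns `path`; `read_sweep` returns a
#'   [sweep_trace()] object.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(data.frame(value = sweep$values), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- list(sampling_rate_khz = sweep$sampling_rate, units = sweep$units,
               epochs = sweep$epochs, holding_potential = sweep$holding_potential,
               meta = sweep$meta)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  vals <- utils::read.csv(path)$value
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  epochs <- lapply(side$epochs, as.numeric)
  sweep_trace(vals, side$sampling_rate_khz, side$units, epochs = epochs,
              holding_potential = side$holding_potential,
              meta = as.list(side$meta))
}
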