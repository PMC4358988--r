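# Synthetic-data generators: frequency surfaces with known composite
# structure, voltage traces with known spike/plateau/ADP geometry, and
# ADP-versus-frequency sigmoid datasets. Every generator is deterministic
# given its seed and exposes its ground truth, so downstream recovery tests
# need no oracle beyond the generator spec itself.

#' Specification of a synthetic frequency surface
#'
#' @param params ground-truth [composite_params()].
#' @param basal,tuft synapse-count grids.
#' @param sigma i.i.d. Gaussian noise standard deviation (Hz, >= 0);
#'   default 5.
#' @param seed RNG seed.
#' @return an object of class `surface_spec`.
#' @export
surface_spec <- function(params, basal = seq(0, 300, by = 20),
                         tuft = seq(0, 200, by = 20), sigma = 5, seed = 1) {
  stopifnot(inherits(params, "composite_params"))
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (length(basal) == 0 || length(tuft) == 0) stop("grids must be nonempty")
  structure(list(params = params, basal = basal, tuft = tuft,
                 sigma = sigma, seed = seed), class = "surface_spec")
}

#' Generate a synthetic frequency surface
#'
#' Evaluates the ground-truth composite model on the grid and adds i.i.d.
#' Gaussian noise, truncated at 0 (frequencies are non-negative).
#'
#' @param spec a [surface_spec()].
#' @return a [frequency_surface()] with provenance "synthetic"; the spec is
#'   attached as attribute `spec`.
#' @export
gen_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  n_T <- rep(spec$tuft, times = length(spec$basal))
  n_B <- rep(spec$basal, each = length(spec$tuft))
  mu <- eval_composite(spec$params, n_T, n_B)
  noise <- with_seed(spec$seed, rnorm(length(mu), 0, spec$sigma))
  freq <- matrix(pmax(mu + noise, 0), nrow = length(spec$tuft))
  s <- frequency_surface(spec$basal, spec$tuft, freq,
                         provenance = "synthetic")
  attr(s, "spec") <- spec
  s
}

#' Specification of a synthetic voltage trace
#'
#' Additive composition of a baseline, Gaussian-shaped spike templates at
#' known times, square plateau segments, an exponential-decay ADP segment
#' starting at the last spike, and Gaussian noise.
#'
#' @param baseline resting level (mV).
#' @param spike_times spike peak times (ms).
#' @param spike_amp,spike_width spike template amplitude (mV) and Gaussian
#'   SD (ms).
#' @param plateaus data frame with columns `onset`, `duration` (ms) and
#'   `level` (mV above baseline); may be empty.
#' @param adp_amp,adp_tau ADP amplitude (mV) and decay constant (ms); the
#'   ADP starts at the last spike time. 0 amplitude disables it.
#' @param sigma Gaussian noise SD (mV); default 0.5.
#' @param duration,dt trace length and sample interval (ms).
#' @param seed RNG seed.
#' @return an object of class `trace_spec`.
#' @export
trace_spec <- function(baseline = -70, spike_times = numeric(0),
                       spike_amp = 80, spike_width = 0.3,
                       plateaus = NULL, adp_amp = 0, adp_tau = 20,
                       sigma = 0.5, duration = 200, dt = 0.1, seed = 1) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (duration <= 0 || dt <= 0) stop("'duration' and 'dt' must be positive")
  if (is.null(plateaus))
    plateaus <- data.frame(onset = numeric(0), duration = numeric(0),
                           level = numeric(0))
  if (nrow(plateaus) > 0) {
    if (any(plateaus$onset < 0 |
            plateaus$onset + plateaus$duration > duration))
      stop("plateau segments must lie within the trace")
    o <- order(plateaus$onset)
    p <- plateaus[o, ]
    if (nrow(p) > 1 &&
        any(p$onset[-1] < (p$onset + p$duration)[-nrow(p)]))
      stop("plateau segments must not overlap")
  }
  if (any(spike_times < 0 | spike_times > duration))
    stop("spike times must lie within the trace")
  structure(list(baseline = baseline, spike_times = sort(spike_times),
                 spike_amp = spike_amp, spike_width = spike_width,
                 plateaus = plateaus, adp_amp = adp_amp, adp_tau = adp_tau,
                 sigma = sigma, duration = duration, dt = dt, seed = seed),
            class = "trace_spec")
}

#' Generate a synthetic voltage trace
#'
#' @param spec a [trace_spec()].
#' @param compartment label for the resulting trace.
#' @return a [voltage_trace()] with the spec attached as attribute `spec`.
#' @export
gen_trace <- function(spec, compartment = "soma") {
  stopifnot(inherits(spec, "trace_spec"))
  tt <- seq(0, spec$duration, by = spec$dt)
  v <- rep(spec$baseline, length(tt))
  for (ts in spec$spike_times)
    v <- v + spec$spike_amp * exp(-(tt - ts)^2 / (2 * spec$spike_width^2))
  if (nrow(spec$plateaus) > 0) {
    for (k in seq_len(nrow(spec$plateaus))) {
      p <- spec$plateaus[k, ]
      sel <- tt >= p$onset & tt < p$onset + p$duration
      v[sel] <- v[sel] + p$level
    }
  }
  if (spec$adp_amp != 0 && length(spec$spike_times) > 0) {
    t_last <- max(spec$spike_times)
    sel <- tt > t_last
    v[sel] <- v[sel] + spec$adp_amp * exp(-(tt[sel] - t_last) / spec$adp_tau)
  }
  if (spec$sigma > 0)
    v <- v + with_seed(spec$seed, rnorm(length(v), 0, spec$sigma))
  tr <- voltage_trace(v, spec$dt, 0, compartment)
  attr(tr, "spec") <- spec
  tr
}

#' Generate a synthetic ADP-versus-frequency dataset
#'
#' Samples of the 4-parameter logistic (the critical-frequency curve) plus
#' Gaussian noise, as a stand-in for the measured ADP sizes.
#'
#' @param inflection sigmoid inflection (Hz) — the ground-truth critical
#'   frequency; must lie within `freqs`.
#' @param plateau_low,plateau_high lower and upper plateaus (mV); the
#'   ground-truth ADP size is `plateau_high - plateau_low`.
#' @param slope slope scale (Hz).
#' @param freqs frequency samples (Hz).
#' @param sigma Gaussian noise SD (mV); default 0.2.
#' @param seed RNG seed.
#' @return list with `freqs`, `adps`, and `truth` (named list with
#'   `inflection`, `adp_size`, `plateau_low`, `plateau_high`, `slope`).
#' @export
gen_cf_dataset <- function(inflection = 84, plateau_low = 1,
                           plateau_high = 5.4, slope = 6,
                           freqs = seq(10, 200, by = 10), sigma = 0.2,
                           seed = 1) {
  if (inflection < min(freqs) || inflection > max(freqs))
    stop("'freqs' must span the inflection")
  if (sigma < 0) stop("'sigma' must be non-negative")
  mu <- logistic4(freqs, plateau_low, plateau_high - plateau_low,
                  inflection, slope)
  adps <- mu + with_seed(seed, rnorm(length(freqs), 0, sigma))
  list(freqs = freqs, adps = adps,
       truth = list(inflection = inflection,
                    adp_size = plateau_high - plateau_low,
                    plateau_low = plateau_low, plateau_high = plateau_high,
                    slope = slope))
}
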