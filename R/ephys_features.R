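# Feature extraction from voltage traces: spike detection, ISI statistics,
# dendritic plateau width, ADP measurement, critical-frequency sigmoid fit,
# event-order classification, slope test.

#' Detect spikes in a voltage trace
#'
#' Spikes are local maxima above `threshold`, separated by at least
#' `refractory` ms; when two candidate peaks fall within the refractory gap
#' the larger one is kept. Times are reported at the sample peaks.
#'
#' @param trace a [voltage_trace()].
#' @param threshold detection threshold (mV); default -20 mV, appropriate
#'   for somatic action potentials.
#' @param refractory minimum gap between spikes (ms).
#' @return an object of class `spike_train`: a list with `times` (ms,
#'   strictly increasing), `peaks` (mV), `threshold`, `compartment`.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$v
  n <- length(v)
  idx <- integer(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    cand <- i[v[i] > threshold & v[i] >= v[i - 1] & v[i] > v[i + 1]]
    # enforce refractory period, keeping the larger of two close peaks
    for (k in cand) {
      if (length(idx) == 0L) { idx <- k; next }
      gap <- (k - idx[length(idx)]) * trace$dt
      if (gap >= refractory) idx <- c(idx, k)
      else if (v[k] > v[idx[length(idx)]]) idx[length(idx)] <- k
    }
  }
  tt <- trace$t0 + (idx - 1) * trace$dt
  structure(list(times = tt, peaks = v[idx], threshold = threshold,
                 compartment = trace$compartment),
            class = "spike_train")
}

#' Spike-train constructor from known times
#' @param times spike times (ms), strictly increasing.
#' @param compartment label.
#' @param threshold detection threshold used (mV), if any.
#' @return a `spike_train` object.
#' @export
spike_train <- function(times, compartment = "soma", threshold = NA_real_) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  structure(list(times = times, peaks = rep(NA_real_, length(times)),
                 threshold = threshold, compartment = compartment),
            class = "spike_train")
}

#' Coefficient of variation of the interspike intervals
#'
#' `sd(ISI) / mean(ISI)` with the sample (n - 1) standard deviation. Low
#' values indicate regular firing; high values indicate bursting. Requires
#' at least 3 spikes (2 intervals); otherwise returns `NA`.
#'
#' @param spikes a `spike_train`.
#' @return dimensionless CV, or `NA_real_` if fewer than 3 spikes.
#' @export
isi_cv <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  if (length(spikes$times) < 3) return(NA_real_)
  isi <- diff(spikes$times)
  sd(isi) / mean(isi)
}

#' Somatic output frequency of a spike train
#'
#' Default (`mode = "span"`): `(N - 1) / (t_last - t_first) * 1000` Hz for
#' `N >= 2` spikes, and 0 for 0 or 1 spike — the instantaneous frequency of
#' the burst. `mode = "count"` instead reports `N / window * 1000` Hz.
#'
#' @param spikes a `spike_train`.
#' @param mode "span" (default) or "count".
#' @param window window length (ms) for `mode = "count"`.
#' @return frequency in Hz.
#' @export
output_frequency <- function(spikes, mode = c("span", "count"),
                             window = 100) {
  stopifnot(inherits(spikes, "spike_train"))
  mode <- match.arg(mode)
  n <- length(spikes$times)
  if (mode == "count") return(n / window * 1000)
  if (n <= 1) return(0)
  (n - 1) / (max(spikes$times) - min(spikes$times)) * 1000
}

#' Width of the dendritic plateau potential
#'
#' The longest depolarization sustained at 20% or more above the baseline
#' level during a dendritic current injection, where the baseline is the
#' most hyperpolarized membrane potential during the injection. "20% or
#' more above baseline" is read fractionally: the threshold is
#' `baseline + 0.2 * (peak - baseline)`. The measure deliberately includes
#' backpropagating-AP contributions riding on the plateau.
#'
#' @param dend_trace a dendritic [voltage_trace()].
#' @param stim_window numeric length-2 vector, start and end of the current
#'   injection (ms); must lie within the trace.
#' @return the longest contiguous above-threshold duration (ms); 0 for a
#'   flat trace.
#' @export
dp_width <- function(dend_trace, stim_window) {
  stopifnot(inherits(dend_trace, "voltage_trace"),
            length(stim_window) == 2, stim_window[1] < stim_window[2])
  tt <- trace_time(dend_trace)
  if (stim_window[1] < tt[1] - 1e-9 ||
      stim_window[2] > tt[length(tt)] + 1e-9)
    stop("stimulus window must lie within the trace")
  sel <- tt >= stim_window[1] & tt <= stim_window[2]
  v <- dend_trace$v[sel]
  baseline <- min(v)
  peak <- max(v)
  if (peak - baseline <= 0) return(0)
  thr <- baseline + 0.2 * (peak - baseline)
  above <- v >= thr
  r <- rle(above)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) return(0)
  max(runs) * dend_trace$dt
}

#' Afterdepolarization size at a fixed latency after the last spike
#'
#' Voltage at `last_spike + latency` minus the pre-protocol baseline. The
#' latency corresponds to the fixed time point (the "dotted line") at which
#' ADP size is read off the frequency-aligned traces.
#'
#' @param trace a somatic [voltage_trace()].
#' @param last_spike time of the last spike peak (ms).
#' @param latency readout latency after the last spike (ms); default 10.
#' @param baseline baseline voltage (mV). If `NULL`, the mean voltage over
#'   `baseline_window` is used.
#' @param baseline_window length-2 vector (ms) defining the pre-protocol
#'   baseline segment; default the first 50 ms of the trace.
#' @return ADP amplitude in mV.
#' @export
adp_size_at <- function(trace, last_spike, latency = 10, baseline = NULL,
                        baseline_window = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  tt <- trace_time(trace)
  t_read <- last_spike + latency
  if (latency < 0 || t_read > tt[length(tt)] + 1e-9)
    stop("readout latency falls outside the trace")
  if (is.null(baseline)) {
    if (is.null(baseline_window))
      baseline_window <- c(tt[1], min(tt[1] + 50, tt[length(tt)]))
    sel <- tt >= baseline_window[1] & tt <= baseline_window[2]
    baseline <- mean(trace$v[sel])
  }
  v_read <- trace$v[which.min(abs(tt - t_read))]
  v_read - baseline
}

# canonical 4-parameter logistic: offset + amplitude/(1 + exp(-(x - mid)/scale))
logistic4 <- function(x, offset, amplitude, midpoint, scale) {
  offset + amplitude / (1 + exp(-(x - midpoint) / scale))
}

# flip (amplitude, scale) sign pair so the slope scale is positive
canonicalize4 <- function(p) {
  if (p[["scale"]] < 0)
    p <- c(offset = unname(p[["offset"]] + p[["amplitude"]]),
           amplitude = unname(-p[["amplitude"]]),
           scale = unname(-p[["scale"]]),
           midpoint = unname(p[["midpoint"]]))[names(p)]
  p
}

# Multi-start fit of the 4-parameter logistic; returns list(par, rss,
# converged). The nonlinear pair (midpoint, scale) is profiled over a seeded
# grid-plus-random start set with the linear pair (offset, amplitude) solved
# exactly by least squares, then the best start is polished with
# Levenberg-Marquardt. The profiling step makes the fit robust for
# step-like data where a plain NLS run fails from most starts.
fit_logistic4 <- function(x, y, n_restarts = 30, seed = 1,
                          midpoint_range = range(x)) {
  dat <- data.frame(x = x, y = y)
  span_x <- max(diff(range(x)), 1e-9)
  scale_min <- 1e-3 * span_x
  # profile RSS: given (midpoint, scale), offset/amplitude are linear
  profile_fit <- function(m, s) {
    z <- 1 / (1 + exp(-(x - m) / s))
    X <- cbind(1, z)
    fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
    list(par = c(offset = unname(fit$coefficients[1]),
                 amplitude = unname(fit$coefficients[2]),
                 midpoint = m, scale = s),
         rss = sum(fit$residuals^2))
  }
  mids <- seq(midpoint_range[1], midpoint_range[2], length.out = 25)
  scales <- span_x * c(0.005, 0.02, 0.05, 0.1, 0.2, 0.4)
  cand <- expand.grid(m = mids, s = scales)
  extra <- with_seed(seed, data.frame(
    m = runif(n_restarts, midpoint_range[1], midpoint_range[2]),
    s = span_x * runif(n_restarts, 0.005, 0.5)))
  cand <- rbind(cand, setNames(extra, c("m", "s")))
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    pf <- profile_fit(cand$m[k], cand$s[k])
    if (!is.null(pf) && (is.null(best) || pf$rss < best$rss)) best <- pf
  }
  if (is.null(best)) return(list(par = NULL, rss = NA_real_,
                                 converged = FALSE))
  # polish with Levenberg-Marquardt from the profiled optimum
  lower <- c(-Inf, -Inf, midpoint_range[1] - 0.5 * span_x, scale_min)
  upper <- c(Inf, Inf, midpoint_range[2] + 0.5 * span_x, 2 * span_x)
  st <- pmin(pmax(best$par, lower), upper)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude / (1 + exp(-(x - midpoint) / scale)),
      data = dat, start = as.list(st), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    rss <- sum(residuals(fit)^2)
    if (rss < best$rss) best <- list(par = coef(fit), rss = rss)
  }
  best$par <- canonicalize4(best$par)
  best$converged <- TRUE
  best
}

#' Fit the critical-frequency sigmoid
#'
#' Least-squares fit of a 4-parameter sigmoid (lower plateau, amplitude,
#' inflection, slope scale) to ADP size versus 3-pulse frequency, with
#' multi-start Levenberg-Marquardt optimization. The critical frequency is
#' the inflection point of the fit, and the ADP size is the difference
#' between the two plateaus (amplitude of the canonicalized sigmoid).
#'
#' @param freqs pulse frequencies (Hz); at least 6 points spanning the
#'   transition.
#' @param adps ADP sizes (mV), same length.
#' @param n_restarts random restarts for the fit.
#' @param seed RNG seed for the restarts.
#' @return an object of class `cf_fit`: list with `critical_frequency`
#'   (Hz), `adp_size` (mV), `params` (named vector: offset, amplitude,
#'   midpoint, scale), `r_squared`, `converged`, `degenerate`.
#' @export
fit_cf_curve <- function(freqs, adps, n_restarts = 30, seed = 1) {
  stopifnot(length(freqs) == length(adps))
  keep <- is.finite(freqs) & is.finite(adps)
  freqs <- freqs[keep]
  adps <- adps[keep]
  if (length(freqs) < 6)
    stop("need at least 6 finite frequency points to fit the sigmoid")
  tss <- sum((adps - mean(adps))^2)
  best <- fit_logistic4(freqs, adps, n_restarts = n_restarts, seed = seed)
  if (!best$converged)
    stop("critical-frequency sigmoid fit did not converge")
  p <- best$par
  degenerate <- tss < 1e-12 ||
    abs(p[["amplitude"]]) < 0.05 * max(diff(range(adps)), 1e-12) ||
    p[["midpoint"]] < min(freqs) || p[["midpoint"]] > max(freqs)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  structure(list(critical_frequency = unname(p[["midpoint"]]),
                 adp_size = unname(p[["amplitude"]]),
                 params = p, r_squared = r2, rss = best$rss,
                 converged = TRUE, degenerate = degenerate),
            class = "cf_fit")
}

#' Classify dendrite-first versus soma-first electrogenesis
#'
#' Determines whether the dendritic suprathreshold depolarization begins
#' before the first somatic spike ("dendrite_first", the signature of a
#' dendritically initiated Ca2+ spike) or after it ("soma_first",
#' backpropagation only). The dendritic event threshold reuses the
#' fractional 20% rule of [dp_width()] within the stimulus window.
#'
#' @param soma_spikes a `spike_train` with at least one spike.
#' @param dend_trace the dendritic [voltage_trace()].
#' @param stim_window length-2 numeric, stimulation window (ms).
#' @return "dendrite_first" or "soma_first".
#' @export
classify_event_order <- function(soma_spikes, dend_trace, stim_window) {
  stopifnot(inherits(soma_spikes, "spike_train"),
            inherits(dend_trace, "voltage_trace"))
  if (length(soma_spikes$times) < 1)
    stop("need at least one somatic spike to classify")
  tt <- trace_time(dend_trace)
  sel <- tt >= stim_window[1] & tt <= stim_window[2]
  v <- dend_trace$v[sel]
  baseline <- min(v)
  peak <- max(v)
  if (peak - baseline <= 0) stop("flat dendritic trace: no event to order")
  thr <- baseline + 0.2 * (peak - baseline)
  onset_idx <- which(v >= thr)[1]
  dend_onset <- tt[sel][onset_idx]
  first_spike <- min(soma_spikes$times)
  if (dend_onset < first_spike) "dendrite_first" else "soma_first"
}

#' Test whether a least-squares slope differs from zero
#'
#' Ordinary least-squares linear fit of `y` on `x` with a two-tailed t-test
#' (n - 2 degrees of freedom) of the null hypothesis that the slope is 0.
#'
#' @param x,y numeric vectors of equal length, at least 3 points; `x` must
#'   not be constant.
#' @return list with `slope`, `intercept`, `p_value`, `std_error`, `df`.
#' @export
slope_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("'x' must not be constant")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sm) < 2 || any(!is.finite(sm["x", ]))) {
    # exactly collinear data: slope estimated, no residual variance
    return(list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                p_value = 0, std_error = 0, df = length(x) - 2))
  }
  list(slope = unname(sm["x", "Estimate"]),
       intercept = unname(coef(fit)[1]),
       p_value = unname(sm["x", "Pr(>|t|)"]),
       std_error = unname(sm["x", "Std. Error"]),
       df = length(x) - 2)
}

#' Extract the standard feature set from a simulation
#'
#' Convenience wrapper computing the per-protocol feature row: somatic
#' spike count, output frequency, ISI CV, dendritic plateau width, and
#' dendrite-first/soma-first classification.
#'
#' @param sim a `sim_result` from [simulate()].
#' @param stim_window length-2 numeric (ms); defaults to the protocol's
#'   onset and onset + duration.
#' @return a one-row data frame.
#' @export
feature_set <- function(sim, stim_window = NULL) {
  pr <- attr(sim, "protocol")
  if (is.null(stim_window))
    stim_window <- c(pr$onset, pr$onset + pr$duration)
  sp <- detect_spikes(sim$soma)
  order <- if (length(sp$times) >= 1)
    tryCatch(classify_event_order(sp, sim$dend, stim_window),
             error = function(e) NA_character_)
  else NA_character_
  data.frame(
    n_spikes = length(sp$times),
    output_frequency_hz = output_frequency(sp),
    isi_cv = isi_cv(sp),
    dp_width_ms = dp_width(sim$dend, stim_window),
    event_order = order,
    stringsAsFactors = FALSE
  )
}
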