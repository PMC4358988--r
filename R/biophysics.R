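# Reduced two-compartment L5 pyramidal neuron model: parameters, synapses,
# stimulation protocols, and the simulation front end.

#' Model parameters for the two-compartment neuron
#'
#' Builds the parameter set of the reduced layer 5 pyramidal neuron model.
#' Compartment 1 ("soma") lumps the soma and basal dendrites and carries the
#' fast Na+/delayed-rectifier K+ spike machinery; compartment 2 ("dendrite")
#' lumps the distal apical trunk and tuft and carries a low-threshold
#' voltage-gated Ca2+ current (the Ca2+-spike generator), a slow K+ current
#' that terminates the Ca2+ spike, and a spatially uniform h-current. The two
#' are connected by a fixed axial coupling conductance.
#'
#' Units are absolute: capacitance in pF, conductances in nS, potentials in
#' mV, currents in pA, time in ms.
#'
#' @param c_soma,c_dend membrane capacitance per compartment (pF).
#' @param gl_soma,gl_dend leak conductance per compartment (nS).
#' @param el_soma,el_dend leak reversal potential per compartment (mV).
#' @param g_na somatic fast Na+ maximal conductance (nS).
#' @param g_kd somatic delayed-rectifier K+ maximal conductance (nS).
#' @param g_ca dendritic Ca2+ maximal conductance (nS); lumps the low- and
#'   high-threshold channels of the apical Ca2+ spike initiation zone.
#' @param g_ks dendritic slow K+ maximal conductance (nS); terminates the
#'   Ca2+ spike.
#' @param g_h dendritic h-current conductance (nS), spatially uniform.
#' @param g_c soma-dendrite coupling conductance (nS).
#' @param e_na,e_k,e_h reversal potentials of Na+, K+ and h currents (mV).
#' @param g_syn per-synapse peak conductance calibration constant (nS); all
#'   synapses have equal postsynaptic conductance, with NMDA:AMPA maximal
#'   conductance ratio fixed at 1:1.
#' @param ca_scale dimensionless multiplier in `[0, 1]` applied to `g_ca`
#'   (Ca2+ channel block experiments use 0.5 and 0.25).
#' @param e_ca effective Ca2+ reversal potential (mV).
#' @param mca_mid,mca_slope midpoint and slope (mV) of the steady-state
#'   activation of the dendritic Ca2+ current.
#' @param tau_mca Ca2+ activation time constant (ms).
#' @param q_mid,q_slope midpoint and slope (mV) of the slow K+ activation.
#' @param tau_q slow K+ activation time constant (ms); sets the Ca2+ spike
#'   duration.
#' @param tau_q_off slow K+ deactivation time constant (ms); the slow decay
#'   leaves a hyperpolarizing brake after each Ca2+ spike (the voltage-gated
#'   stand-in for the Ca2+-activated K+ tail), making the burst
#'   self-terminating.
#' @param g_adapt somatic adaptation (slow AHP) maximal conductance (nS);
#'   builds rapidly during each action potential and decays slowly,
#'   producing spike-frequency adaptation.
#' @param z_mid activation midpoint (mV) of the adaptation gate.
#' @param tau_z_on,tau_z_off activation/deactivation time constants (ms) of
#'   the adaptation gate.
#' @param c_bas,gl_bas,el_bas capacitance (pF), leak conductance (nS) and
#'   leak reversal (mV) of the passive basal-dendrite compartment carrying
#'   the basal synapses.
#' @param g_cb basal-soma coupling conductance (nS).
#' @param g_m somatic M-type slow K+ maximal conductance (nS); activates
#'   below spike threshold with time constant `tau_m`, opposing slow
#'   depolarizing drive while sparing brief pulses and fast bursts.
#' @param tau_m M-current activation time constant (ms).
#' @return an object of class `model_params` (a named list).
#' @seealso [default_params()], [scale_ca()]
#' @export
model_params <- function(c_soma, c_dend, gl_soma, gl_dend,
                         el_soma, el_dend, g_na, g_kd, g_ca, g_ks, g_h, g_c,
                         e_na = 55, e_k = -90, e_h = -35,
                         g_syn = 1, ca_scale = 1,
                         e_ca = 80, mca_mid = -42, mca_slope = 4.5,
                         tau_mca = 3, q_mid = -40, q_slope = 4,
                         tau_q = 15, tau_q_off = 250,
                         g_adapt = 60, z_mid = -35, tau_z_on = 1.5,
                         tau_z_off = 150, c_bas = 80, gl_bas = 10,
                         el_bas = -72, g_cb = 50, g_m = 0, tau_m = 80) {
  p <- list(c_soma = c_soma, c_dend = c_dend, gl_soma = gl_soma,
            gl_dend = gl_dend, el_soma = el_soma, el_dend = el_dend,
            g_na = g_na, g_kd = g_kd, g_ca = g_ca, g_ks = g_ks, g_h = g_h,
            g_c = g_c, e_na = e_na, e_k = e_k, e_h = e_h, g_syn = g_syn,
            ca_scale = ca_scale, e_ca = e_ca, mca_mid = mca_mid,
            mca_slope = mca_slope, tau_mca = tau_mca, q_mid = q_mid,
            q_slope = q_slope, tau_q = tau_q, tau_q_off = tau_q_off,
            g_adapt = g_adapt, z_mid = z_mid, tau_z_on = tau_z_on,
            tau_z_off = tau_z_off, c_bas = c_bas, gl_bas = gl_bas,
            el_bas = el_bas, g_cb = g_cb, g_m = g_m, tau_m = tau_m)
  conds <- c("c_soma", "c_dend", "gl_soma", "gl_dend", "g_na", "g_kd",
             "g_ca", "g_ks", "g_h", "g_c", "g_syn", "mca_slope", "tau_mca",
             "q_slope", "tau_q", "tau_q_off", "g_adapt", "tau_z_on", "tau_z_off", "c_bas", "gl_bas", "g_cb", "g_m", "tau_m")
  for (nm in conds) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  if (!is.numeric(ca_scale) || ca_scale < 0 || ca_scale > 1)
    stop("'ca_scale' must lie in [0, 1]")
  structure(p, class = "model_params")
}

#' Frozen default model parameters
#'
#' Reads the calibrated parameter fixture shipped with the package
#' (`extdata/default_params.yaml`). This parameter set is frozen: it is the
#' one that passes the calibration suite (critical frequency in the
#' experimental band, coincidence-detection spike counts, Ca2+-block
#' ceilings) and all simulation-level results in the documentation refer
#' to it.
#'
#' @return a `model_params` object.
#' @export
default_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "tuftburst")
  read_params(path)
}

#' Scale the dendritic Ca2+ conductance
#'
#' Returns a copy of `params` with the Ca2+ conductance multiplied by
#' `factor`, emulating partial block of both high- and low-threshold Ca2+
#' channels in the apical dendrites. All other fields are unchanged. The
#' scaling is tracked in the `ca_scale` field (multiplicative, so scaling
#' twice by 0.5 gives `ca_scale` 0.25).
#'
#' @param params a `model_params` object.
#' @param factor dimensionless scale in `[0, 1]`.
#' @return a `model_params` object.
#' @export
scale_ca <- function(params, factor) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor < 0 || factor > 1)
    stop("'factor' must be a single number in [0, 1]")
  params$ca_scale <- params$ca_scale * factor
  params
}

# fixed-order numeric vector handed to the C++ core
param_vector <- function(params) {
  with(params, c(c_soma, c_dend, gl_soma, gl_dend, el_soma, el_dend,
                 g_na, g_kd, g_ca, g_ks, g_h, g_c, e_na, e_k, e_h, ca_scale,
                 e_ca, mca_mid, mca_slope, tau_mca, q_mid, q_slope, tau_q,
                 tau_q_off, g_adapt, z_mid, tau_z_on, tau_z_off,
                 c_bas, gl_bas, el_bas, g_cb, g_m, tau_m))
}

#' NMDA synaptic conductance time course
#'
#' Voltage-dependent NMDA conductance of a single synapse at time `t` after
#' its onset:
#' \deqn{g(v, t) = g_{max} \frac{e^{-t/70} - e^{-t/3}}
#'   {1 + 0.3\, e^{-0.08 v}}}
#' with `t` in ms and `v` in mV. The denominator models the voltage-dependent
#' magnesium block; the numerator is a dual-exponential with 3 ms rise and
#' 70 ms decay time constants.
#'
#' @param v membrane potential (mV); vectorised.
#' @param t time since synapse onset (ms, non-negative); vectorised.
#' @param g_max maximal conductance (non-negative).
#' @return conductance, same units as `g_max`; in `[0, g_max)`.
#' @export
nmda_conductance <- function(v, t, g_max) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(g_max < 0)) stop("'g_max' must be non-negative")
  g_max * (exp(-t / 70) - exp(-t / 3)) / (1 + 0.3 * exp(-0.08 * v))
}

#' AMPA synaptic conductance time course
#'
#' Single-synapse AMPA conductance: instantaneous rise to `g_max` at onset
#' and exponential decay with a 0.5 ms time constant,
#' \eqn{g(t) = g_{max} e^{-t/0.5}}.
#'
#' @param t time since synapse onset (ms, non-negative); vectorised.
#' @param g_max maximal conductance (non-negative).
#' @return conductance, same units as `g_max`.
#' @export
ampa_conductance <- function(t, g_max) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(g_max < 0)) stop("'g_max' must be non-negative")
  g_max * exp(-t / 0.5)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build a random synaptic barrage
#'
#' Draws `n_tuft` synapses onto the dendritic (tuft) compartment and
#' `n_basal` synapses onto the somatic (basal) compartment, with onset times
#' i.i.d. uniform on `[0, window]` ms. Each synapse has an NMDA and an AMPA
#' component with maximal conductance ratio 1:1; `g_max` is a per-synapse
#' weight multiplied by the global calibration constant `g_syn` of the model
#' parameters at simulation time ("synapses of equal postsynaptic
#' conductance").
#'
#' @param n_tuft,n_basal synapse counts (non-negative integers).
#' @param window barrage window length (ms, positive).
#' @param seed integer RNG seed; the same seed reproduces the same barrage.
#'   `NULL` uses the current RNG state.
#' @param g_max per-synapse relative weight (default 1).
#' @return an object of class `synaptic_events`: a data frame with columns
#'   `compartment` ("soma" or "dend"), `onset` (ms), `g_nmda`, `g_ampa`,
#'   with attributes `window` and `seed`.
#' @export
make_barrage <- function(n_tuft, n_basal, window = 100, seed = NULL,
                         g_max = 1) {
  if (n_tuft < 0 || n_basal < 0) stop("synapse counts must be non-negative")
  if (window <= 0) stop("'window' must be positive")
  onsets <- with_seed(seed, runif(n_tuft + n_basal, 0, window))
  ev <- data.frame(
    compartment = rep(c("dend", "soma"), c(n_tuft, n_basal)),
    onset = onsets,
    g_nmda = rep(g_max, n_tuft + n_basal),
    g_ampa = rep(g_max, n_tuft + n_basal),
    stringsAsFactors = FALSE
  )
  structure(ev, window = window, seed = seed,
            class = c("synaptic_events", "data.frame"))
}

#' Stimulation protocols
#'
#' Constructors for the three in-silico experiment types:
#' * `protocol_dc_step()` — a constant current step at the soma or dendrite
#'   (the 1 s dendritic injections and DC f-I protocols).
#' * `protocol_pulse_train()` — `n_pulses` brief pulses at a given frequency
#'   (the 3-pulse critical-frequency protocol uses 2 ms pulses, 10-200 Hz).
#' * `protocol_barrage()` — a [make_barrage()] synaptic barrage.
#'
#' All protocols support a constant `holding` current applied at the soma for
#' the whole simulation (e.g. -200 pA for the hyperpolarized subthreshold
#' probe) and start at `onset` ms, leaving a settling period beforehand.
#'
#' @param site "soma" or "dend": compartment receiving the injection.
#' @param amplitude injected current (pA).
#' @param duration step duration (ms).
#' @param n_pulses number of pulses.
#' @param pulse_width single pulse width (ms).
#' @param frequency pulse rate (Hz); inter-pulse interval is
#'   `1000/frequency` ms and must be at least `pulse_width`.
#' @param events a `synaptic_events` object.
#' @param onset protocol start time (ms).
#' @param holding somatic holding current (pA, may be negative).
#' @return an object of class `stimulus_protocol`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_dc_step <- function(site = c("soma", "dend"), amplitude, duration,
                             onset = 100, holding = 0) {
  site <- match.arg(site)
  if (duration <= 0) stop("'duration' must be positive")
  structure(list(kind = "dc_step", site = site, amplitude = amplitude,
                 duration = duration, onset = onset, holding = holding),
            class = "stimulus_protocol")
}

#' @rdname protocols
#' @export
protocol_pulse_train <- function(site = "soma", amplitude, n_pulses = 3,
                                 pulse_width = 2, frequency, onset = 100,
                                 holding = 0) {
  if (frequency <= 0) stop("'frequency' must be positive")
  interval <- 1000 / frequency
  if (interval < pulse_width)
    stop("inter-pulse interval (1000/frequency) must be >= pulse_width")
  duration <- (n_pulses - 1) * interval + pulse_width
  structure(list(kind = "pulse_train", site = site, amplitude = amplitude,
                 n_pulses = n_pulses, pulse_width = pulse_width,
                 frequency = frequency, interval = interval,
                 duration = duration, onset = onset, holding = holding),
            class = "stimulus_protocol")
}

#' @rdname protocols
#' @export
protocol_barrage <- function(events, onset = 100, holding = 0) {
  stopifnot(inherits(events, "synaptic_events"))
  structure(list(kind = "barrage", site = "both", events = events,
                 duration = attr(events, "window"), onset = onset,
                 holding = holding),
            class = "stimulus_protocol")
}

#' Uniformly sampled membrane-potential trace
#'
#' @param v voltage samples (mV).
#' @param dt sample interval (ms).
#' @param t0 time of the first sample (ms).
#' @param compartment label, e.g. "soma" or "dend".
#' @return an object of class `voltage_trace`.
#' @export
voltage_trace <- function(v, dt, t0 = 0, compartment = "soma") {
  if (!all(is.finite(v))) stop("voltage samples must be finite")
  if (dt <= 0) stop("'dt' must be positive")
  structure(list(v = as.numeric(v), dt = dt, t0 = t0,
                 compartment = compartment),
            class = "voltage_trace")
}

#' Time base of a voltage trace
#' @param trace a `voltage_trace`.
#' @return numeric vector of sample times (ms).
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  trace$t0 + (seq_along(trace$v) - 1) * trace$dt
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %s: %d samples, dt = %g ms, [%g, %g] ms\n",
              x$compartment, length(x$v), x$dt, x$t0,
              x$t0 + (length(x$v) - 1) * x$dt))
  invisible(x)
}

# build injected-current vectors and event tables for the C++ core
build_inputs <- function(protocol, params, dt, n_steps) {
  i_soma <- rep(protocol$holding, n_steps + 1)
  i_dend <- numeric(n_steps + 1)
  t_grid <- (0:n_steps) * dt
  if (protocol$kind == "dc_step") {
    on <- t_grid >= protocol$onset &
      t_grid < protocol$onset + protocol$duration
    if (protocol$site == "soma") i_soma[on] <- i_soma[on] + protocol$amplitude
    else i_dend[on] <- i_dend[on] + protocol$amplitude
  } else if (protocol$kind == "pulse_train") {
    starts <- protocol$onset + (seq_len(protocol$n_pulses) - 1) *
      protocol$interval
    for (s in starts) {
      on <- t_grid >= s & t_grid < s + protocol$pulse_width
      if (protocol$site == "soma")
        i_soma[on] <- i_soma[on] + protocol$amplitude
      else i_dend[on] <- i_dend[on] + protocol$amplitude
    }
  }
  ev_s_step <- integer(0); ev_s_g <- numeric(0)
  ev_d_step <- integer(0); ev_d_g <- numeric(0)
  if (protocol$kind == "barrage") {
    ev <- protocol$events
    step <- as.integer(floor((ev$onset + protocol$onset) / dt))
    g <- ev$g_nmda * params$g_syn
    soma <- ev$compartment == "soma"
    o_s <- order(step[soma]); o_d <- order(step[!soma])
    ev_s_step <- step[soma][o_s]; ev_s_g <- g[soma][o_s]
    ev_d_step <- step[!soma][o_d]; ev_d_g <- g[!soma][o_d]
  }
  list(i_soma = i_soma, i_dend = i_dend,
       ev_s_step = ev_s_step, ev_s_g = ev_s_g,
       ev_d_step = ev_d_step, ev_d_g = ev_d_g)
}

#' Simulate the two-compartment model under a stimulation protocol
#'
#' Integrates the model ODEs (leak, somatic Na+/K+, dendritic Ca2+ / slow K+
#' / h currents, axial coupling, synaptic currents) with a fixed time step.
#' Gating variables advance by exponential Euler and the membrane potentials
#' by a linearly implicit update, which is stable at the default step.
#'
#' @param protocol a `stimulus_protocol`.
#' @param params a `model_params` object (default [default_params()]).
#' @param dt integration step (ms); default 0.025.
#' @param total total simulated time (ms). Defaults to the protocol onset
#'   plus duration plus a 200 ms tail, enough to measure afterdepolarizations.
#' @return a list of class `sim_result` with elements `soma` and `dend`
#'   (each a [voltage_trace()]), and the protocol, parameters and `dt` kept
#'   as attributes.
#' @export
simulate <- function(protocol, params = default_params(), dt = 0.025,
                     total = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(params, "model_params"))
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(total)) total <- protocol$onset + protocol$duration + 200
  if (total < protocol$onset + protocol$duration)
    stop("'total' must cover the protocol")
  n_steps <- as.integer(round(total / dt))
  inp <- build_inputs(protocol, params, dt, n_steps)
  out <- simulate_core(dt, n_steps, param_vector(params),
                       inp$i_soma, inp$i_dend,
                       inp$ev_s_step, inp$ev_s_g,
                       inp$ev_d_step, inp$ev_d_g)
  structure(list(soma = voltage_trace(out$v_soma, dt, 0, "soma"),
                 dend = voltage_trace(out$v_dend, dt, 0, "dend"),
                 basal = voltage_trace(out$v_basal, dt, 0, "basal")),
            protocol = protocol, params = params, dt = dt,
            class = "sim_result")
}

#' Run the 3-pulse critical-frequency protocol
#'
#' For each frequency, injects `n_pulses` brief somatic current pulses and
#' simulates long enough to measure the afterdepolarization at least 100 ms
#' past the last pulse. Each pulse is expected to elicit exactly one somatic
#' action potential at the default amplitude; runs where the somatic spike
#' count differs from the pulse count are flagged (`ok = FALSE`), not
#' dropped.
#'
#' @param params a `model_params` object.
#' @param freqs pulse frequencies (Hz); default 10 to 200 in steps of 10.
#' @param pulse_amp pulse amplitude (pA); the default is calibrated so that
#'   each 2 ms pulse triggers one action potential.
#' @param dt integration step (ms).
#' @param n_pulses,pulse_width pulse count and width (ms).
#' @param onset protocol start (ms).
#' @return a list of class `cf_run` with one entry per frequency:
#'   `freq`, `soma`, `dend`, `n_spikes`, `last_spike` (ms), `ok`.
#' @export
run_cf_protocol <- function(params = default_params(),
                            freqs = seq(10, 200, by = 10),
                            pulse_amp = 7000, dt = 0.025,
                            n_pulses = 3, pulse_width = 2, onset = 100) {
  runs <- lapply(freqs, function(f) {
    pr <- protocol_pulse_train(site = "soma", amplitude = pulse_amp,
                               n_pulses = n_pulses,
                               pulse_width = pulse_width,
                               frequency = f, onset = onset)
    total <- onset + pr$duration + 250
    sim <- simulate(pr, params, dt = dt, total = total)
    sp <- detect_spikes(sim$soma)
    last <- if (length(sp$times)) max(sp$times) else NA_real_
    list(freq = f, soma = sim$soma, dend = sim$dend,
         n_spikes = length(sp$times), last_spike = last,
         ok = length(sp$times) == n_pulses)
  })
  structure(runs, class = "cf_run", onset = onset)
}

#' The frozen calibration barrage
#'
#' The standard coincidence-detection stimulus used for calibration: 100
#' tuft and 175 basal synapses elicited at uniform random times within
#' 100 ms, drawn with the package's fixed calibration seed (42). On the
#' frozen default parameters this barrage elicits 4 somatic action
#' potentials and 1 dendritic Ca2+ spike; basal-only and tuft-only
#' variants elicit 1 and 0 action potentials respectively.
#'
#' @param n_tuft,n_basal synapse counts (defaults: the standard 100/175).
#' @param window barrage window (ms).
#' @return a `synaptic_events` object.
#' @export
calibration_barrage <- function(n_tuft = 100, n_basal = 175, window = 100) {
  make_barrage(n_tuft, n_basal, window, seed = 42L)
}

#' Derive a reproducible per-condition seed
#'
#' Deterministic seed for a single barrage, derived from the master seed and
#' the grid coordinates so that every grid point and replicate has an
#' independent, reproducible RNG stream.
#'
#' @param master master seed (integer).
#' @param n_basal,n_tuft synapse counts of the grid point.
#' @param replicate replicate index (1-based).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, n_basal, n_tuft, replicate = 1) {
  as.integer((abs(master) %% 1000003) * 1009 +
               n_basal * 7919 + n_tuft * 104729 +
               replicate * 15485863) %% 2147483647L
}

#' Sweep somatic output frequency over basal and tuft input counts
#'
#' For every combination of `n_basal` and `n_tuft` synapse counts (and every
#' Ca2+ scale), simulates `n_seeds` independent 100 ms barrages and reports
#' the somatic output frequency, averaged over seeds. This reproduces the
#' input-output surfaces used to compare the phenomenological models.
#'
#' @param params a `model_params` object.
#' @param basal_grid,tuft_grid synapse-count grids (standard ranges: basal
#'   0-300, tuft 0-200).
#' @param ca_scales Ca2+ conductance scales to simulate (e.g.
#'   `c(1, 0.5, 0.25)`).
#' @param window barrage window (ms).
#' @param n_seeds replicates per grid point.
#' @param master_seed master seed; per-replicate seeds come from
#'   [derive_seed()].
#' @param dt integration step (ms).
#' @param mode output-frequency definition, see [output_frequency()].
#' @param seed_policy "nested" (default): each replicate draws one random
#'   synapse pool covering the largest grid values, and a grid point uses
#'   the first `n_basal`/`n_tuft` events of that pool, so moving along the
#'   grid adds synapses to a fixed set (the incremental design of an
#'   input-count sweep, which keeps thresholds smooth along the grid);
#'   "independent" draws a fresh barrage per grid point.
#' @return a list with one [frequency_surface()] per Ca2+ scale.
#' @export
run_sweep <- function(params = default_params(),
                      basal_grid = seq(0, 300, by = 20),
                      tuft_grid = seq(0, 200, by = 20),
                      ca_scales = 1.0, window = 100, n_seeds = 2,
                      master_seed = 1, dt = 0.025, mode = "span",
                      seed_policy = c("nested", "independent")) {
  stopifnot(all(basal_grid >= 0), all(tuft_grid >= 0), n_seeds >= 1)
  seed_policy <- match.arg(seed_policy)
  max_b <- max(basal_grid)
  max_t <- max(tuft_grid)
  pools <- lapply(seq_len(n_seeds), function(rep)
    make_barrage(max_t, max_b, window,
                 seed = derive_seed(master_seed, 0, 0, rep)))
  lapply(ca_scales, function(cs) {
    p <- params
    p$ca_scale <- cs
    freq <- matrix(NA_real_, nrow = length(tuft_grid),
                   ncol = length(basal_grid))
    for (i in seq_along(tuft_grid)) {
      for (j in seq_along(basal_grid)) {
        fs <- vapply(seq_len(n_seeds), function(rep) {
          ev <- if (seed_policy == "nested")
            subset_barrage(pools[[rep]], tuft_grid[i], basal_grid[j])
          else
            make_barrage(tuft_grid[i], basal_grid[j], window,
                         seed = derive_seed(master_seed, basal_grid[j],
                                            tuft_grid[i], rep))
          sim <- simulate(protocol_barrage(ev), p, dt = dt,
                          total = 100 + window + 100)
          output_frequency(detect_spikes(sim$soma), mode = mode,
                           window = window)
        }, numeric(1))
        freq[i, j] <- mean(fs)
      }
    }
    frequency_surface(basal_grid, tuft_grid, freq, ca_scale = cs,
                      provenance = "simulated", n_seeds = n_seeds)
  })
}

# first n_tuft dendritic and n_basal somatic events of a larger barrage
subset_barrage <- function(pool, n_tuft, n_basal) {
  dend <- which(pool$compartment == "dend")
  soma <- which(pool$compartment == "soma")
  if (n_tuft > length(dend) || n_basal > length(soma))
    stop("requested counts exceed the event pool")
  ev <- pool[c(dend[seq_len(n_tuft)], soma[seq_len(n_basal)]), ]
  structure(ev, window = attr(pool, "window"), seed = attr(pool, "seed"),
            class = c("synaptic_events", "data.frame"))
}
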