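# shared fixtures: all built in code at test time

# a flat trace at a given level
flat_trace <- function(level = -70, duration = 100, dt = 0.1,
                       compartment = "soma") {
  voltage_trace(rep(level, duration / dt + 1), dt, 0, compartment)
}

# noiseless composite parameter set with comfortable structure over the
# standard grid ranges (basal 0-300, tuft 0-200)
truth_composite <- function() {
  composite_params(
    M = sigmoid_params(offset = 20, amplitude = 140, midpoint = 80,
                       scale = 30),
    T = sigmoid_params(offset = 220, amplitude = -140, midpoint = 100,
                       scale = 35))
}

# small noiseless surfaces for the three model kinds on a shared grid
grid_basal <- seq(0, 300, by = 25)
grid_tuft <- seq(0, 200, by = 25)

noiseless_surface <- function(kind) {
  n_T <- rep(grid_tuft, times = length(grid_basal))
  n_B <- rep(grid_basal, each = length(grid_tuft))
  f <- switch(kind,
    composite = eval_composite(truth_composite(), n_T, n_B),
    multiplicative = eval_multiplicative(
      sigmoid_params(0.4, 0.8, 90, 35), sigmoid_params(10, 150, 150, 40),
      n_T, n_B),
    additive = eval_additive(
      sigmoid_params(5, 70, 90, 35), sigmoid_params(5, 90, 150, 40),
      n_T, n_B))
  frequency_surface(grid_basal, grid_tuft,
                    matrix(f, nrow = length(grid_tuft)),
                    provenance = "synthetic")
}

# mean frequency over replicates for one barrage condition
rep_frequency <- function(params, n_tuft, n_basal, ca_scale = 1,
                          n_seeds = 3, master = 5, mode = "span") {
  mean(vapply(seq_len(n_seeds), function(r) {
    ev <- make_barrage(n_tuft, n_basal, 100,
                       seed = derive_seed(master, n_basal, n_tuft, r))
    sim <- simulate(protocol_barrage(ev), scale_ca(params, ca_scale),
                    total = 300)
    output_frequency(detect_spikes(sim$soma), mode = mode)
  }, numeric(1)))
}

# monotone non-decreasing allowing a one-grid-step tolerance
skip_one_nondecreasing <- function(v, tol = 1e-9) {
  length(v) < 3 || all(v[-(1:2)] - v[seq_len(length(v) - 2)] >= -tol)
}
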