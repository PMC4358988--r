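# Orientation-tuning mechanism analysis: von Mises input generation, the
# four candidate mechanisms, circular variance, and the kappa sweep.

#' Orientation grid
#'
#' Evenly spaced orientations covering one full period `(-pi, pi]`.
#'
#' @param n number of grid points (default 360).
#' @return numeric vector of orientations (radians).
#' @export
orientation_grid <- function(n = 360) {
  if (n < 2) stop("need at least 2 grid points")
  seq(-pi, pi, length.out = n + 1)[-1]
}

#' von Mises orientation-tuned synapse counts
#'
#' Number of synaptic inputs as a function of stimulus orientation,
#' following a von Mises distribution with preferred orientation 0 radians
#' and compression factor `kappa` (1/kappa is the circular analog of
#' variance), peak-normalized so that the count at the preferred
#' orientation is 90 synapses:
#' \deqn{n(\theta) = 90\, e^{\kappa(\cos\theta - 1)}}
#'
#' @param kappa compression factor (> 0); the analysis range is 0.1 to 1.
#' @param grid orientation grid (radians), default [orientation_grid()].
#' @param peak count at the preferred orientation (default 90).
#' @return an object of class `von_mises_input`: list with `kappa`, `grid`,
#'   `counts`.
#' @export
von_mises_counts <- function(kappa, grid = orientation_grid(),
                             peak = 90) {
  if (!is.numeric(kappa) || kappa <= 0) stop("'kappa' must be positive")
  if (length(grid) == 0) stop("'grid' must be nonempty")
  structure(list(kappa = kappa, grid = grid,
                 counts = peak * exp(kappa * (cos(grid) - 1))),
            class = "von_mises_input")
}

#' Default mechanism parameters for the tuning analysis
#'
#' The composite parameters are the frozen fixture fitted to the
#' control-condition biophysical frequency surface
#' (`extdata/composite_control_fit.yaml`), making the tuning analysis
#' downstream of the input-output surface fits. The single-sigmoid
#' parameters (midpoint 45, scale 9 synapses) are chosen for a dynamic
#' range matched to a maximum of 90 inputs.
#'
#' @return list with elements `composite` (a [composite_params()]),
#'   `sigmoid_midpoint`, `sigmoid_scale`.
#' @export
default_tuning_params <- function() {
  path <- system.file("extdata", "composite_control_fit.yaml",
                      package = "tuftburst")
  cp <- read_composite_params(path)
  list(composite = cp, sigmoid_midpoint = 45, sigmoid_scale = 9)
}

#' Orientation-tuning response of one mechanism
#'
#' Computes the per-orientation output of one of the candidate
#' tuning mechanisms given tuft and basal input-count curves:
#' * `composite` — the composite sigmoid model applied to
#'   `(count_T, count_B)`;
#' * `multiplicative` — `count_T * count_B`;
#' * `additive` — `count_T + count_B`;
#' * `single_sigmoid_tuft` / `single_sigmoid_basal` — a logistic of one
#'   input stream alone.
#'
#' The output curve is normalized to a maximum of 1.
#'
#' @param kind mechanism name.
#' @param tuft,basal [von_mises_counts()] inputs sharing the same grid.
#' @param params mechanism parameters, see [default_tuning_params()].
#' @return an object of class `tuning_curve`: list with `grid`, `response`
#'   (max 1), `kind`.
#' @export
mechanism_response <- function(kind = c("composite", "multiplicative",
                                        "additive", "single_sigmoid_tuft",
                                        "single_sigmoid_basal"),
                               tuft, basal,
                               params = default_tuning_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(tuft, "von_mises_input"),
            inherits(basal, "von_mises_input"))
  if (length(tuft$grid) != length(basal$grid) ||
      any(abs(tuft$grid - basal$grid) > 1e-12))
    stop("tuft and basal inputs must share the orientation grid")
  single <- function(x)
    1 / (1 + exp(-(x - params$sigmoid_midpoint) / params$sigmoid_scale))
  resp <- switch(kind,
    composite = eval_composite(params$composite, tuft$counts, basal$counts),
    multiplicative = tuft$counts * basal$counts,
    additive = tuft$counts + basal$counts,
    single_sigmoid_tuft = single(tuft$counts),
    single_sigmoid_basal = single(basal$counts))
  if (any(resp < 0)) resp <- pmax(resp, 0)
  m <- max(resp)
  if (m <= 0) stop("mechanism output is identically zero")
  structure(list(grid = tuft$grid, response = resp / m, kind = kind),
            class = "tuning_curve")
}

#' Circular variance of a tuning curve
#'
#' Response-weighted circular variance over the full period:
#' \deqn{CV = 1 - \frac{|\sum_j r_j e^{i\theta_j}|}{\sum_j r_j}}
#' 0 means all response mass at a single orientation (perfect tuning), 1
#' means a flat curve. With `period = "pi"` the orientation-domain variant
#' (angle doubling) is used instead.
#'
#' @param curve a `tuning_curve`, or any list with `grid` and `response`.
#' @param period "2pi" (default) or "pi".
#' @return circular variance in `[0, 1]`.
#' @export
circular_variance <- function(curve, period = c("2pi", "pi")) {
  period <- match.arg(period)
  r <- curve$response
  th <- curve$grid
  if (any(r < 0)) stop("responses must be non-negative")
  s <- sum(r)
  if (s <= 0) stop("all-zero curve has undefined circular variance")
  if (period == "pi") th <- 2 * th
  1 - Mod(sum(r * exp(1i * th))) / s
}

#' Sweep input width (kappa) across tuning mechanisms
#'
#' For each compression factor in `k_grid`, sets both tuft and basal input
#' curves to the same kappa, computes every mechanism's output tuning
#' curve, and reports its circular variance next to the circular variance of
#' the input curve itself (the reference).
#'
#' @param k_grid kappa values; default `seq(0.1, 1, by = 0.1)`.
#' @param mechanisms mechanism names, see [mechanism_response()].
#' @param params mechanism parameters.
#' @param grid orientation grid.
#' @return data frame with columns `kappa`, `mechanism`, `circ_var_output`,
#'   `circ_var_input`.
#' @export
k_sweep <- function(k_grid = seq(0.1, 1, by = 0.1),
                    mechanisms = c("composite", "multiplicative",
                                   "additive", "single_sigmoid_tuft"),
                    params = default_tuning_params(),
                    grid = orientation_grid()) {
  if (any(k_grid <= 0)) stop("kappa values must be positive")
  rows <- lapply(k_grid, function(k) {
    tuft <- von_mises_counts(k, grid)
    basal <- von_mises_counts(k, grid)
    cv_in <- circular_variance(list(grid = grid,
                                    response = tuft$counts / max(tuft$counts)))
    do.call(rbind, lapply(mechanisms, function(m) {
      curve <- mechanism_response(m, tuft, basal, params)
      data.frame(kappa = k, mechanism = m,
                 circ_var_output = circular_variance(curve),
                 circ_var_input = cv_in, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
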