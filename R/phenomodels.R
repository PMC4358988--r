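# Phenomenological input-output models: composite, multiplicative and
# additive sigmoid models, surface fitting, variance explained, and
# per-tuft-slice extraction of maximum (M) and threshold (T).

#' Sigmoid parameter set
#'
#' Parameters of the 4-parameter logistic used throughout the
#' phenomenological models:
#' \deqn{f(x) = \mathrm{offset} +
#'   \frac{\mathrm{amplitude}}{1 + e^{-(x - \mathrm{midpoint}) /
#'   \mathrm{scale}}}}
#' The amplitude may be negative: the fitting process decides whether each
#' sigmoid is increasing or decreasing.
#'
#' @param offset lower asymptote (for positive scale) (Hz or synapse count).
#' @param amplitude plateau difference; may be negative.
#' @param midpoint inflection location (synapse count).
#' @param scale slope scale (synapse count); must be nonzero.
#' @return an object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(offset, amplitude, midpoint, scale) {
  if (scale == 0) stop("'scale' must be nonzero")
  structure(list(offset = offset, amplitude = amplitude,
                 midpoint = midpoint, scale = scale),
            class = "sigmoid_params")
}

#' Evaluate a 4-parameter sigmoid
#' @param p a [sigmoid_params()].
#' @param x input (synapse count); vectorised.
#' @return sigmoid value.
#' @export
eval_sigmoid <- function(p, x) {
  stopifnot(inherits(p, "sigmoid_params"))
  logistic4(x, p$offset, p$amplitude, p$midpoint, p$scale)
}

#' Composite-model parameter set
#'
#' The composite model transforms basal input to output frequency through a
#' sigmoid whose maximum `M` and threshold `T` are themselves sigmoid
#' functions of tuft input:
#' \deqn{freq(n_B, n_T) = \frac{M(n_T)}{1 + e^{-(n_B - T(n_T))}}}
#' Note the unit slope of the basal exponent: the basal sigmoid's sharpness
#' is fixed, only its maximum and threshold move with tuft input.
#'
#' @param M a [sigmoid_params()] mapping tuft count to maximum frequency
#'   (Hz); typically increasing.
#' @param T a [sigmoid_params()] mapping tuft count to basal threshold
#'   (synapse count); typically decreasing.
#' @return an object of class `composite_params`.
#' @export
composite_params <- function(M, T) {
  stopifnot(inherits(M, "sigmoid_params"), inherits(T, "sigmoid_params"))
  structure(list(M = M, T = T), class = "composite_params")
}

#' Evaluate the additive model
#'
#' `freq = f(n_T) + g(n_B)`: two independent sigmoids of tuft and basal
#' input, summed.
#'
#' @param f_params,g_params [sigmoid_params()] for the tuft and basal
#'   sigmoids.
#' @param n_T,n_B tuft and basal synapse counts; vectorised.
#' @return frequency (Hz).
#' @export
eval_additive <- function(f_params, g_params, n_T, n_B) {
  eval_sigmoid(f_params, n_T) + eval_sigmoid(g_params, n_B)
}

#' Evaluate the multiplicative model
#'
#' `freq = f(n_T) * g(n_B)`: two independent sigmoids of tuft and basal
#' input, multiplied.
#'
#' @inheritParams eval_additive
#' @return frequency (Hz).
#' @export
eval_multiplicative <- function(f_params, g_params, n_T, n_B) {
  eval_sigmoid(f_params, n_T) * eval_sigmoid(g_params, n_B)
}

#' Evaluate the composite model
#'
#' @param p a [composite_params()].
#' @param n_T,n_B tuft and basal synapse counts; vectorised.
#' @return frequency (Hz): `M(n_T) / (1 + exp(-(n_B - T(n_T))))`.
#' @export
eval_composite <- function(p, n_T, n_B) {
  stopifnot(inherits(p, "composite_params"))
  eval_sigmoid(p$M, n_T) / (1 + exp(-(n_B - eval_sigmoid(p$T, n_T))))
}

#' Frequency surface over basal and tuft input counts
#'
#' @param basal,tuft synapse-count grids.
#' @param freq frequency matrix (Hz), `length(tuft)` rows by
#'   `length(basal)` columns.
#' @param ca_scale Ca2+ conductance scale the surface was simulated at.
#' @param provenance "simulated" or "synthetic".
#' @param n_seeds replicates averaged per grid point (simulated surfaces).
#' @return an object of class `frequency_surface`.
#' @export
frequency_surface <- function(basal, tuft, freq, ca_scale = 1,
                              provenance = c("simulated", "synthetic"),
                              n_seeds = 1) {
  provenance <- match.arg(provenance)
  freq <- as.matrix(freq)
  if (nrow(freq) != length(tuft) || ncol(freq) != length(basal))
    stop("'freq' must be |tuft| x |basal|")
  if (any(freq < 0)) stop("frequencies must be non-negative")
  structure(list(basal = basal, tuft = tuft, freq = freq,
                 ca_scale = ca_scale, provenance = provenance,
                 n_seeds = n_seeds),
            class = "frequency_surface")
}

#' @export
print.frequency_surface <- function(x, ...) {
  cat(sprintf(paste0("<frequency_surface> %d tuft x %d basal, ca_scale ",
                     "%g, %s, max %.1f Hz\n"),
              length(x$tuft), length(x$basal), x$ca_scale, x$provenance,
              max(x$freq)))
  invisible(x)
}

#' Long-format data frame of a frequency surface
#' @param x a `frequency_surface`.
#' @param ... unused.
#' @return data frame with columns `ca_scale`, `n_basal`, `n_tuft`,
#'   `frequency_hz`.
#' @export
as.data.frame.frequency_surface <- function(x, ...) {
  data.frame(ca_scale = x$ca_scale,
             n_basal = rep(x$basal, each = length(x$tuft)),
             n_tuft = rep(x$tuft, times = length(x$basal)),
             frequency_hz = as.vector(x$freq))
}

# model evaluators keyed by kind, on parameter vectors used by the fitter
eval_kind <- function(kind, par, n_T, n_B) {
  switch(kind,
    composite = {
      M <- logistic4(n_T, par[1], par[2], par[3], par[4])
      Tt <- logistic4(n_T, par[5], par[6], par[7], par[8])
      M / (1 + exp(-(n_B - Tt)))
    },
    multiplicative = logistic4(n_T, par[1], par[2], par[3], par[4]) *
      logistic4(n_B, par[5], par[6], par[7], par[8]),
    additive = logistic4(n_T, par[1], par[2], par[3], par[4]) +
      logistic4(n_B, par[5], par[6], par[7], par[8]),
    stop("unknown model kind: ", kind)
  )
}

# data-driven start: M from per-tuft-row maxima, T from per-row half-max
# basal crossings (composite); marginal profiles for the factorized models
informed_start <- function(kind, surface) {
  fr <- range(surface$freq)
  span <- max(diff(fr), 1e-9)
  tr <- range(surface$tuft)
  br <- range(surface$basal)
  row_max <- apply(surface$freq, 1, max)
  half_cross <- vapply(seq_along(surface$tuft), function(i) {
    v <- surface$freq[i, ]
    j <- which(v >= fr[1] + 0.5 * (max(v) - fr[1]))[1]
    if (is.na(j)) max(br) else surface$basal[j]
  }, numeric(1))
  if (kind == "composite")
    c(min(row_max), diff(range(row_max)), mean(tr), 0.15 * diff(tr) + 1,
      max(half_cross), min(half_cross) - max(half_cross), mean(tr),
      0.15 * diff(tr) + 1)
  else {
    col_prof <- apply(surface$freq, 2, mean)
    row_prof <- apply(surface$freq, 1, mean)
    if (kind == "multiplicative")
      c(0.5, 1, mean(tr), 0.15 * diff(tr) + 1,
        min(col_prof), diff(range(col_prof)) * 2, mean(br),
        0.15 * diff(br) + 1)
    else
      c(min(row_prof), diff(range(row_prof)), mean(tr),
        0.15 * diff(tr) + 1,
        min(col_prof), diff(range(col_prof)), mean(br),
        0.15 * diff(br) + 1)
  }
}

# random start draws for the 8-parameter fits (midpoints over the grids,
# amplitudes within [-2, 2] x data range)
draw_start <- function(kind, surface) {
  fr <- range(surface$freq)
  span <- max(diff(fr), 1e-9)
  tr <- range(surface$tuft)
  br <- range(surface$basal)
  amp1 <- runif(1, -2, 2) * span
  amp2 <- runif(1, -2, 2) * if (kind == "composite") diff(br) + 1 else span
  sc <- function(r) runif(1, 0.03, 0.5) * max(diff(r), 1)
  if (kind == "composite")
    c(runif(1, 0, fr[2]), amp1, runif(1, tr[1], tr[2]), sc(tr),
      runif(1, br[1], br[2] * 1.5), amp2, runif(1, tr[1], tr[2]), sc(tr))
  else
    c(runif(1, -span, span), amp1, runif(1, tr[1], tr[2]), sc(tr),
      runif(1, -span, span), amp2, runif(1, br[1], br[2]), sc(br))
}

#' Fit a phenomenological model to a frequency surface
#'
#' Nonlinear least squares over all grid points with multi-start randomized
#' initialization (Levenberg-Marquardt); the restart with the lowest
#' residual sum of squares is reported. Variance explained is
#' `100 * (1 - RSS / TSS)` with the total sum of squares taken about the
#' grand mean of the surface.
#'
#' @param surface a [frequency_surface()] with at least two distinct
#'   frequencies.
#' @param kind "composite", "multiplicative" or "additive".
#' @param n_restarts randomized restarts (default 50).
#' @param seed RNG seed for the restarts.
#' @return an object of class `fit_result`: list with `kind`, `params`
#'   (for "composite" a [composite_params()]; otherwise list of `f` and
#'   `g` [sigmoid_params()]), `variance_explained` (%), `rss`, `n_restarts`,
#'   `converged`.
#' @export
fit_surface <- function(surface,
                        kind = c("composite", "multiplicative", "additive"),
                        n_restarts = 50, seed = 1) {
  stopifnot(inherits(surface, "frequency_surface"))
  kind <- match.arg(kind)
  y <- as.vector(surface$freq)
  if (length(unique(y)) < 2)
    return(structure(list(kind = kind, params = NULL,
                          variance_explained = NA_real_, rss = NA_real_,
                          n_restarts = 0, converged = FALSE,
                          degenerate = TRUE),
                     class = "fit_result"))
  n_T <- rep(surface$tuft, times = length(surface$basal))
  n_B <- rep(surface$basal, each = length(surface$tuft))
  tss <- sum((y - mean(y))^2)
  obj <- function(par) eval_kind(kind, par, n_T, n_B) - y
  best <- NULL
  starts <- with_seed(seed,
    lapply(seq_len(n_restarts), function(i) draw_start(kind, surface)))
  starts <- c(list(informed_start(kind, surface)), starts)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = obj,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(structure(list(kind = kind, params = NULL,
                          variance_explained = NA_real_, rss = NA_real_,
                          n_restarts = n_restarts, converged = FALSE),
                     class = "fit_result"))
  par <- best$par
  canon <- function(v) {
    p <- c(offset = v[1], amplitude = v[2], midpoint = v[3], scale = v[4])
    p <- canonicalize4(p)
    sigmoid_params(p[["offset"]], p[["amplitude"]], p[["midpoint"]],
                   p[["scale"]])
  }
  params <- if (kind == "composite")
    composite_params(M = canon(par[1:4]), T = canon(par[5:8]))
  else list(f = canon(par[1:4]), g = canon(par[5:8]))
  structure(list(kind = kind, params = params,
                 variance_explained = 100 * (1 - best$rss / tss),
                 rss = best$rss, n_restarts = n_restarts, converged = TRUE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: VE = %.2f%%, RSS = %.3g (%d restarts)\n",
              x$kind, x$variance_explained, x$rss, x$n_restarts))
  invisible(x)
}

#' Evaluate a fitted phenomenological model on a grid
#' @param fit a `fit_result` from [fit_surface()].
#' @param n_T,n_B tuft and basal counts; vectorised.
#' @return fitted frequency (Hz).
#' @export
predict_fit <- function(fit, n_T, n_B) {
  stopifnot(inherits(fit, "fit_result"), fit$converged)
  if (fit$kind == "composite") eval_composite(fit$params, n_T, n_B)
  else if (fit$kind == "multiplicative")
    eval_multiplicative(fit$params$f, fit$params$g, n_T, n_B)
  else eval_additive(fit$params$f, fit$params$g, n_T, n_B)
}

#' Extract per-tuft maximum (M) and threshold (T) from surface slices
#'
#' Fits an independent 4-parameter sigmoid of basal count to each
#' tuft-constant slice of the surface and reports the upper plateau (M) and
#' midpoint (T) per tuft count. This is the second, fit-free-of-the-composite
#' route to the M and T curves: on composite-generated data the slice values
#' must agree with the composite fit's `M(n_T)` and `T(n_T)`.
#'
#' @param surface a [frequency_surface()]; each slice needs at least 5
#'   basal points.
#' @param n_restarts,seed multi-start control for the per-slice fits.
#' @return data frame with columns `n_tuft`, `M` (Hz), `T` (synapse count),
#'   `r_squared`, `ok` (FALSE for degenerate or failed slices, whose `M` is
#'   0 for all-zero slices and `T` is `NA`).
#' @export
extract_slice_MT <- function(surface, n_restarts = 20, seed = 1) {
  stopifnot(inherits(surface, "frequency_surface"))
  if (length(surface$basal) < 5)
    stop("each tuft-constant slice needs at least 5 basal points")
  rows <- lapply(seq_along(surface$tuft), function(i) {
    y <- surface$freq[i, ]
    x <- surface$basal
    if (max(y) - min(y) < 1e-9) {
      return(data.frame(n_tuft = surface$tuft[i],
                        M = if (max(abs(y)) < 1e-9) 0 else max(y),
                        T = NA_real_, r_squared = NA_real_, ok = FALSE))
    }
    b <- fit_logistic4(x, y, n_restarts = n_restarts,
                       seed = derive_seed(seed, i, 0, 1),
                       midpoint_range = range(x) + c(-0.25, 0.5) * diff(range(x)))
    if (!b$converged)
      return(data.frame(n_tuft = surface$tuft[i], M = NA_real_,
                        T = NA_real_, r_squared = NA_real_, ok = FALSE))
    tss <- sum((y - mean(y))^2)
    p <- b$par
    data.frame(n_tuft = surface$tuft[i],
               M = unname(p[["offset"]] + p[["amplitude"]]),
               T = unname(p[["midpoint"]]),
               r_squared = 1 - b$rss / tss,
               ok = p[["amplitude"]] > 0)
  })
  do.call(rbind, rows)
}
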