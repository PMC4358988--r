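# Plain-text input/output: YAML parameter files (versioned schema), trace
# and surface CSVs, fit-result JSON.

PARAMS_SCHEMA_VERSION <- 1L

#' Read and write model parameters as YAML
#'
#' The file is a flat key/value YAML document with a `schema_version` field;
#' the remaining keys are the [model_params()] fields.
#'
#' @param path file path.
#' @param params a `model_params` object (for writing).
#' @return `read_params()` returns a `model_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) ||
      x$schema_version != PARAMS_SCHEMA_VERSION)
    stop("unsupported or missing schema_version in ", path)
  x$schema_version <- NULL
  do.call(model_params, x)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  x <- c(list(schema_version = PARAMS_SCHEMA_VERSION), unclass(params))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read and write composite-model parameters as YAML
#'
#' @param path file path.
#' @param params a [composite_params()] (for writing).
#' @return `read_composite_params()` returns a `composite_params`.
#' @export
read_composite_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) ||
      x$schema_version != PARAMS_SCHEMA_VERSION)
    stop("unsupported or missing schema_version in ", path)
  s <- function(l) sigmoid_params(l$offset, l$amplitude, l$midpoint, l$scale)
  composite_params(M = s(x$M), T = s(x$T))
}

#' @rdname read_composite_params
#' @export
write_composite_params <- function(params, path) {
  stopifnot(inherits(params, "composite_params"))
  yaml::write_yaml(list(schema_version = PARAMS_SCHEMA_VERSION,
                        M = unclass(params$M), T = unclass(params$T)), path)
  invisible(path)
}

#' Write simulated traces to CSV
#'
#' Columns: `time_ms`, `v_soma_mV`, `v_dend_mV`.
#'
#' @param sim a `sim_result` from [simulate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  df <- data.frame(time_ms = trace_time(sim$soma),
                   v_soma_mV = sim$soma$v, v_dend_mV = sim$dend$v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces written by [write_trace_csv()]
#' @param path CSV file.
#' @return list with `soma` and `dend` [voltage_trace()]s.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  dt <- df$time_ms[2] - df$time_ms[1]
  list(soma = voltage_trace(df$v_soma_mV, dt, df$time_ms[1], "soma"),
       dend = voltage_trace(df$v_dend_mV, dt, df$time_ms[1], "dend"))
}

#' Write frequency surfaces to long-format CSV
#'
#' Columns: `ca_scale`, `n_basal`, `n_tuft`, `frequency_hz`. Multiple
#' surfaces (e.g. one per Ca2+ scale) are concatenated.
#'
#' @param surfaces a [frequency_surface()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surfaces, path) {
  if (inherits(surfaces, "frequency_surface")) surfaces <- list(surfaces)
  df <- do.call(rbind, lapply(surfaces, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read frequency surfaces from long-format CSV
#' @param path CSV file written by [write_surface_csv()].
#' @return list of [frequency_surface()], one per `ca_scale` value.
#' @export
read_surface_csv <- function(path) {
  df <- read.csv(path)
  lapply(sort(unique(df$ca_scale), decreasing = TRUE), function(cs) {
    d <- df[df$ca_scale == cs, ]
    basal <- sort(unique(d$n_basal))
    tuft <- sort(unique(d$n_tuft))
    m <- matrix(NA_real_, length(tuft), length(basal))
    m[cbind(match(d$n_tuft, tuft), match(d$n_basal, basal))] <-
      d$frequency_hz
    frequency_surface(basal, tuft, m, ca_scale = cs,
                      provenance = "simulated")
  })
}

#' Write a fit result to JSON
#' @param fit a `fit_result` from [fit_surface()].
#' @param path output file.
#' @param ... extra fields to record (e.g. seed).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, ...) {
  stopifnot(inherits(fit, "fit_result"))
  flat <- function(p) if (inherits(p, "sigmoid_params")) unclass(p) else p
  params <- if (fit$kind == "composite" && fit$converged)
    list(M = flat(fit$params$M), T = flat(fit$params$T))
  else if (fit$converged) lapply(fit$params, flat)
  else NULL
  jsonlite::write_json(
    list(kind = fit$kind, params = params,
         variance_explained = fit$variance_explained, rss = fit$rss,
         n_restarts = fit$n_restarts, converged = fit$converged, ...),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
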