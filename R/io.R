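#' Load and validate a run configuration
#'
#' Reads a YAML configuration and merges it over the model defaults. Every
#' model constant can be overridden; overrides are validated against the
#' parameter bounds and reported via a message so deviations from the
#' canonical constants are always visible. Unknown keys are rejected.
#'
#' Recognized top-level keys: any constant of [default_params()], plus
#' `scheme`, `scenario`, `seed`, `gamma`, `eta_bar`, `learn_scale`,
#' `duration`, `t_ph`, `record_every`.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return List with `const` (constants), `config` ([learning_config()])
#'   and the run-level fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  const <- default_params()
  run <- list(scheme = "full", scenario = "single", seed = 1L,
              gamma = 2, eta_bar = const$eta_bar, learn_scale = 5,
              duration = 500, t_ph = 500, record_every = 1)
  known <- c(names(const), names(run))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in intersect(names(raw), names(const))) {
    message("config override: ", k, " = ", raw[[k]],
            " (default ", const[[k]], ")")
    const[[k]] <- raw[[k]]
  }
  for (k in intersect(names(raw), names(run))) run[[k]] <- raw[[k]]
  if (const$U_min < 0 || const$U_max > 1 || const$U_min >= const$U_max)
    stop("utilization bounds must satisfy 0 <= U_min < U_max <= 1")
  if (const$tau_rec_min <= 0 || const$tau_rec_min >= const$tau_rec_max)
    stop("recovery bounds must satisfy 0 < tau_rec_min < tau_rec_max")
  if (const$tau_facil_min <= 0 || const$tau_facil_min >= const$tau_facil_max)
    stop("facilitation bounds must satisfy 0 < tau_facil_min < tau_facil_max")
  if (const$A_min <= 0 || const$A_min >= const$A_max)
    stop("strength bounds must satisfy 0 < A_min < A_max")
  if (const$dt <= 0) stop("dt must be > 0")
  if (!run$scenario %in% c("single", "double"))
    stop("scenario must be 'single' or 'double'")
  config <- learning_config(run$scheme, eta_bar = run$eta_bar,
                            gamma = run$gamma,
                            learn_scale = run$learn_scale)
  list(const = const, config = config, scenario = run$scenario,
       seed = as.integer(run$seed), duration = run$duration,
       t_ph = run$t_ph, record_every = run$record_every)
}

#' Save / load the full network state
#'
#' The state container is a named list of all arrays (weight and parameter
#' matrices, synaptic and neuronal state, clock) written with `saveRDS`;
#' the round trip is lossless.
#'
#' @param net An `stp_network`.
#' @param path Destination file.
#' @export
save_state <- function(net, path) {
  stopifnot(inherits(net, "stp_network"))
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  structure(readRDS(path), class = "stp_network")
}

#' Write a spike raster as columnar text
#'
#' @param raster data.frame with columns `time_ms`, `neuron` (as returned
#'   in `stp_run$raster`).
#' @param path Destination file (tab-separated with header).
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
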