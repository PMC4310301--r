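#' Network architecture specification
#'
#' Describes one of the two published architectures. The single scenario is
#' an all-to-all network of 40 neurons split into a 30-neuron input
#' population (receiving the wave stimulus) and a 10-neuron output
#' population. The double scenario mirrors it: two branches of
#' 30 input + 10 output neurons; cross connections between a branch's
#' populations and the other branch's functionally different populations
#' (in1 <-> out2, out1 <-> in2) are absent, and lateral connections between
#' homologous populations (in1 <-> in2, out1 <-> out2) start weak
#' (uniform in [1e-3, 1e-1]).
#'
#' @param scenario `"single"` or `"double"`.
#' @param n_in Input neurons per branch (30).
#' @param n_out Output neurons per branch (10).
#' @return List of class `network_spec` with `N`, named `populations`
#'   (integer index sets), `roles`, the logical `mask` of allowed synapses
#'   and `lateral` (logical matrix of the weakly initialized lateral
#'   synapses).
#' @export
network_spec <- function(scenario = c("single", "double"), n_in = 30,
                         n_out = 10) {
  scenario <- match.arg(scenario)
  if (scenario == "single") {
    N <- n_in + n_out
    pops <- list(input = seq_len(n_in), output = n_in + seq_len(n_out))
    roles <- c(input = "input", output = "output")
    mask <- matrix(TRUE, N, N); diag(mask) <- FALSE
    lateral <- matrix(FALSE, N, N)
  } else {
    N <- 2 * (n_in + n_out)
    pops <- list(in1 = seq_len(n_in),
                 in2 = n_in + seq_len(n_in),
                 out1 = 2 * n_in + seq_len(n_out),
                 out2 = 2 * n_in + n_out + seq_len(n_out))
    roles <- c(in1 = "input", in2 = "input", out1 = "output",
               out2 = "output")
    mask <- matrix(TRUE, N, N); diag(mask) <- FALSE
    # absent cross connections between functionally different populations
    # of different branches
    mask[pops$in1, pops$out2] <- FALSE; mask[pops$out2, pops$in1] <- FALSE
    mask[pops$out1, pops$in2] <- FALSE; mask[pops$in2, pops$out1] <- FALSE
    lateral <- matrix(FALSE, N, N)
    lateral[pops$in1, pops$in2] <- TRUE; lateral[pops$in2, pops$in1] <- TRUE
    lateral[pops$out1, pops$out2] <- TRUE; lateral[pops$out2, pops$out1] <- TRUE
    diag(lateral) <- FALSE
  }
  if (!setequal(unlist(pops), seq_len(N)))
    stop("populations must partition 1..N")
  structure(list(scenario = scenario, N = N, populations = pops,
                 roles = roles, mask = mask, lateral = lateral,
                 n_in = n_in, n_out = n_out),
            class = "network_spec")
}

#' Build a randomly initialized network state
#'
#' Draws the synaptic parameters of every allowed synapse from the uniform
#' initialization ranges (U in [0.05, 0.95], tau_rec in [100, 900] ms,
#' tau_facil in [1, 900] ms, A in [1e-3, 1]; lateral synapses of the
#' double scenario draw A from [1e-3, 1e-1]), sets the synaptic variables
#' to their rest values (r = 1, u = U) and zeroes all activity state.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the initialization RNG stream.
#' @param const Constants from [default_params()].
#' @return Object of class `stp_network`: named list of state arrays plus
#'   the spec. Matrix entry (i, j) describes the synapse j -> i.
#' @export
build_network <- function(spec, seed = 1L, const = default_params()) {
  stopifnot(inherits(spec, "network_spec"))
  N <- spec$N
  rng <- local({ set.seed(seed); list(
    U = matrix(stats::runif(N * N, const$U_min, const$U_max), N, N),
    tr = matrix(stats::runif(N * N, const$tau_rec_min, const$tau_rec_max), N, N),
    tf = matrix(stats::runif(N * N, const$tau_facil_min, const$tau_facil_max), N, N),
    A = matrix(stats::runif(N * N, const$A_min, const$A_max), N, N),
    Alat = matrix(stats::runif(N * N, const$A_min, 0.1), N, N))
  })
  A <- rng$A
  A[spec$lateral] <- rng$Alat[spec$lateral]
  A[!spec$mask] <- 0
  pop_id <- integer(N)
  for (k in seq_along(spec$populations)) pop_id[spec$populations[[k]]] <- k
  structure(list(
    spec = spec, const = const, t = 0,
    V = numeric(N), ref_until = rep(-Inf, N),
    g = matrix(0, N, N), r = matrix(1, N, N), u = rng$U,
    U = rng$U, tau_rec = rng$tr, tau_facil = rng$tf, A = A,
    m1 = numeric(N), m2 = numeric(N), o1 = numeric(N), o2 = numeric(N),
    nu = numeric(N), mask = spec$mask, pop_id = pop_id, seed = seed
  ), class = "stp_network")
}

#' @export
print.stp_network <- function(x, ...) {
  cat("<stp_network>", x$spec$scenario, "scenario |", x$spec$N, "neurons |",
      sum(x$mask), "synapses | t =", x$t / 1000, "s\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(x$spec$populations),
                    lengths(x$spec$populations)), collapse = ", "), "\n")
  invisible(x)
}

# default recording groups: symmetry of each output population; STP
# parameter means over synapses onto each output population (from the
# whole network in the single scenario, from the union of the output
# populations in the double scenario, matching the reported projection
# groups)
recording_groups <- function(spec) {
  pops <- spec$populations
  outs <- names(spec$roles)[spec$roles == "output"]
  sym <- lapply(outs, function(p) as.integer(pops[[p]] - 1L))
  names(sym) <- outs
  if (spec$scenario == "single") {
    pg <- list(output = list(targets = as.integer(pops$output - 1L),
                             sources = as.integer(seq_len(spec$N) - 1L)))
  } else {
    src <- as.integer(c(pops$out1, pops$out2) - 1L)
    pg <- list(out1 = list(targets = as.integer(pops$out1 - 1L), sources = src),
               out2 = list(targets = as.integer(pops$out2 - 1L), sources = src))
  }
  list(sym = sym, param = pg)
}

#' Run a simulation through a phase schedule
#'
#' Advances the network with the compiled per-step loop through every phase
#' of the schedule, regenerating nothing between phases except the task
#' targets and the STDP rate gamma. The wave stimulus covers the whole run;
#' its jitter stream is the only randomness (seeded separately from the
#' initialization so ablations do not shift unrelated draws).
#'
#' @param net A [build_network()] state.
#' @param schedule A [phase_schedule()]; targets have one column per
#'   population in the order of `net$spec$populations`.
#' @param config A [learning_config()].
#' @param protocol Optional [build_protocol()] stimulus; by default a wave
#'   over all input neurons at 10 Hz is generated for the run duration.
#' @param stim_seed Seed for the stimulus jitter stream.
#' @param record_every Sampling interval for the recorded summaries (s).
#' @param record_raster Keep the full spike raster (step, neuron).
#' @return Object of class `stp_run`: the final `net`, a `recordings`
#'   data.frame (time, population rates, output symmetry, projection-group
#'   parameter means), per-phase final-state `snapshots` (weight and STP
#'   parameter matrices), and the raster if requested.
#' @export
run_simulation <- function(net, schedule, config, protocol = NULL,
                           stim_seed = net$seed + 1000L, record_every = 1,
                           record_raster = FALSE) {
  stopifnot(inherits(net, "stp_network"), inherits(schedule, "phase_schedule"),
            inherits(config, "learning_config"))
  const <- net$const
  dt <- const$dt
  total_ms <- sum(schedule$durations) * 1000
  if (ncol(schedule$targets) != length(net$spec$populations))
    stop("schedule targets must have one column per population")
  if (total_ms == 0) {
    return(structure(list(net = net, recordings = NULL, snapshots = list(),
                          schedule = schedule, config = config),
                     class = "stp_run"))
  }
  inputs <- unlist(net$spec$populations[net$spec$roles == "input"],
                   use.names = FALSE)
  if (is.null(protocol)) {
    set.seed(stim_seed)
    protocol <- build_protocol(length(inputs), horizon = total_ms,
                               nu_in = const$nu_in,
                               amplitude = const$stim_amp)
  }
  ev_step_all <- as.integer(floor(protocol$events$time_ms / dt))
  ev_neuron_all <- as.integer(inputs[protocol$events$neuron] - 1L)
  grp <- recording_groups(net$spec)
  rec_steps <- as.integer(round(record_every * 1000 / dt))

  state <- net[c("V", "ref_until", "g", "r", "u", "U", "tau_rec",
                 "tau_facil", "A", "m1", "m2", "o1", "o2", "nu", "mask")]
  recs <- list(); snapshots <- list()
  raster <- list(step = integer(0), neuron = integer(0))
  t0 <- net$t
  for (ph in seq_along(schedule$durations)) {
    n_steps <- as.integer(round(schedule$durations[ph] * 1000 / dt))
    if (n_steps == 0) next
    cfg <- list(gamma = schedule$gamma[ph], eta_bar = config$eta_bar,
                learn_scale = config$learn_scale, learn = config$learn,
                facil_first = config$facil_first,
                g_scale = if (is.null(config$g_scale))
                  const$coupling / net$spec$N else config$g_scale,
                refrac_gate = isTRUE(config$refrac_gate))
    in_phase <- ev_step_all >= (t0 - net$t) / dt &
      ev_step_all < (t0 - net$t) / dt + n_steps
    res <- sim_phase_cpp(state, const, cfg, net$pop_id,
                         schedule$targets[ph, ],
                         as.integer(ev_step_all[in_phase] - (t0 - net$t) / dt),
                         ev_neuron_all[in_phase], protocol$amplitude,
                         n_steps, t0, rec_steps, grp$sym, grp$param,
                         record_raster)
    state <- res[c("V", "ref_until", "g", "r", "u", "U", "tau_rec",
                   "tau_facil", "A", "m1", "m2", "o1", "o2", "nu")]
    state$mask <- net$mask
    rec <- res$rec
    df <- data.frame(time_s = rec$time_ms / 1000, phase = ph)
    rates <- as.data.frame(rec$rates)
    names(rates) <- paste0("rate_", names(net$spec$populations))
    sym <- as.data.frame(rec$symmetry)
    names(sym) <- paste0("s_", names(grp$sym))
    par_tr <- as.data.frame(rec$tau_rec)
    names(par_tr) <- paste0("tau_rec_", names(grp$param))
    par_u <- as.data.frame(rec$U)
    names(par_u) <- paste0("U_", names(grp$param))
    par_tf <- as.data.frame(rec$tau_facil)
    names(par_tf) <- paste0("tau_facil_", names(grp$param))
    recs[[ph]] <- cbind(df, rates, sym, par_tr, par_u, par_tf)
    snapshots[[ph]] <- list(time_s = (t0 + n_steps * dt) / 1000,
                            A = res$A, U = res$U, tau_rec = res$tau_rec,
                            tau_facil = res$tau_facil)
    if (record_raster) {
      raster$step <- c(raster$step, res$raster$step + as.integer((t0 - net$t) / dt))
      raster$neuron <- c(raster$neuron, res$raster$neuron + 1L)
    }
    t0 <- t0 + n_steps * dt
  }
  for (nm in names(state)) net[[nm]] <- state[[nm]]
  net$t <- t0
  structure(list(net = net, recordings = do.call(rbind, recs),
                 snapshots = snapshots, schedule = schedule, config = config,
                 protocol_params = protocol[c("n_in", "nu_in", "t_delay",
                                              "jitter_sd", "amplitude")],
                 raster = if (record_raster)
                   data.frame(time_ms = net$t - total_ms + raster$step * dt,
                              neuron = raster$neuron)),
            class = "stp_run")
}

#' @export
print.stp_run <- function(x, ...) {
  cat("<stp_run>", x$net$spec$scenario, "scenario | scheme", x$config$scheme,
      "|", length(x$schedule$durations), "phase(s),",
      sum(x$schedule$durations), "s total\n")
  if (!is.null(x$recordings)) {
    last <- x$recordings[nrow(x$recordings), ]
    rates <- unlist(last[grep("^rate_", names(last))])
    cat("  final population rates (Hz):",
        paste(sprintf("%s=%.1f", sub("rate_", "", names(rates)), rates),
              collapse = ", "), "\n")
    s <- unlist(last[grep("^s_", names(last))])
    if (length(s))
      cat("  final symmetry:",
          paste(sprintf("%s=%.2f", sub("s_", "", names(s)), s),
                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Canonical double-population schedule
#'
#' One phase with fixed branch targets: 30 Hz for branch 1 (in1, out1) and
#' 5 Hz for branch 2 (in2, out2), STDP rate gamma = 2 throughout.
#'
#' @param duration Phase length in seconds.
#' @param high,low Branch targets (Hz).
#' @export
double_phase_schedule <- function(duration = 500, high = 30, low = 5) {
  phase_schedule(duration, matrix(c(high, low, high, low), nrow = 1),
                 gamma = 2)
}
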