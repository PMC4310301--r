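# Independent reference implementations used as oracles.

# Plain-R step loop mirroring the documented per-step order of the
# compiled engine: stimulus -> decays -> membrane -> threshold -> STP
# release/injection -> STDP (pre-increment traces) -> trace increments ->
# error-driven learning -> clipped weight update -> rate EMA -> record.
ref_phase_r <- function(state, const, cfg, pop_id, targets,
                        stim_step, stim_neuron, stim_amp, n_steps, t0) {
  V <- state$V; ref_until <- state$ref_until
  g <- state$g; r <- state$r; u <- state$u
  U <- state$U; trec <- state$tau_rec; tfac <- state$tau_facil
  A <- state$A
  m1 <- state$m1; m2 <- state$m2; o1 <- state$o1; o2 <- state$o2
  nu <- state$nu; mask <- state$mask
  N <- length(V); dt <- const$dt
  eg <- exp(-dt / const$tau_g); enu <- exp(-dt / const$tau_nu)
  dm1 <- exp(-dt / const$tau_m1); dm2 <- exp(-dt / const$tau_m2)
  do1 <- exp(-dt / const$tau_o1); do2 <- exp(-dt / const$tau_o2)
  learn <- cfg$learn
  raster <- list()
  popmean <- tapply(nu, pop_id, mean)[as.character(seq_along(targets))]
  popmean[is.na(popmean)] <- 0
  for (s in seq_len(n_steps) - 1L) {
    t_now <- t0 + s * dt
    due <- stim_neuron[stim_step == s]
    for (n in due) if (t_now >= ref_until[n]) V[n] <- V[n] + stim_amp
    g <- g * eg
    r <- r + (1 - r) * (1 - exp(-dt / trec))
    u <- u + (U - u) * (1 - exp(-dt / tfac))
    m1 <- m1 * dm1; m2 <- m2 * dm2; o1 <- o1 * do1; o2 <- o2 * do2
    gin <- rowSums(g)
    act <- t_now >= ref_until
    V[act] <- V[act] + dt * (-const$g_L * V[act] +
                               gin[act] * (const$E_rev - V[act]))
    V[!act] <- 0
    spikes <- act & (V >= const$V_thr)
    V[spikes] <- 0
    ref_until[spikes] <- t_now + const$t_ref
    sp <- which(spikes)
    if (length(sp)) {
      raster[[length(raster) + 1L]] <- cbind(s, sp)
      for (j in sp) {
        i <- setdiff(seq_len(N), j)
        if (cfg$facil_first) {
          u[i, j] <- u[i, j] + U[i, j] * (1 - u[i, j])
          rel <- r[i, j] * u[i, j]
          r[i, j] <- r[i, j] - rel
        } else {
          rel <- r[i, j] * u[i, j]
          r[i, j] <- r[i, j] - rel
          u[i, j] <- u[i, j] + U[i, j] * (1 - u[i, j])
        }
        tgt_ok <- if (isTRUE(cfg$refrac_gate)) t_now >= ref_until[i] else TRUE
        g[i, j] <- g[i, j] + rel * A[i, j] * cfg$g_scale * tgt_ok
      }
      m1p <- m1; m2p <- m2; o1p <- o1; o2p <- o2
      dA <- matrix(0, N, N)
      for (i in sp) {
        pot <- cfg$gamma * (const$A2_plus + const$A3_plus * o2p[i])
        dep <- cfg$gamma * (const$A2_minus + const$A3_minus * m2p[i])
        j <- setdiff(seq_len(N), i)
        dA[i, j] <- dA[i, j] + pot * m1p[j] * mask[i, j]
        dA[j, i] <- dA[j, i] - dep * o1p[j] * mask[j, i]
      }
      m1[sp] <- m1[sp] + 1; m2[sp] <- m2[sp] + 1
      o1[sp] <- o1[sp] + 1; o2[sp] <- o2[sp] + 1
      for (i in sp) {
        p <- pop_id[i]
        err <- targets[p] - popmean[p]
        if (err != 0) {
          eta <- cfg$eta_bar * (1 + err / const$nu_lim)^2 * cfg$learn_scale
          nl2 <- const$nu_lim^2
          j <- which(mask[i, ])
          trs <- trec[i, j] / 1000
          a <- A[i, j]
          if (learn[["A"]])
            dA[i, j] <- dA[i, j] + 2 * cfg$gamma * cfg$learn_scale * err / (nl2 * trs)
          if (learn[["taurec"]])
            trec[i, j] <- pmin(const$tau_rec_max, pmax(const$tau_rec_min,
              trec[i, j] - 2 * eta * err * a / (nl2 * trs^2) * 1000))
          if (learn[["U"]])
            U[i, j] <- pmin(const$U_max, pmax(const$U_min,
              U[i, j] - 2 * eta * err * a / (nl2 * U[i, j]^2)))
          if (learn[["taufacil"]])
            tfac[i, j] <- pmin(const$tau_facil_max, pmax(const$tau_facil_min,
              tfac[i, j] + 2 * eta * err * a / nl2 * 1000))
        }
      }
      upd <- dA != 0
      A[upd] <- pmin(const$A_max, pmax(const$A_min, A[upd] + dA[upd]))
    }
    nu <- nu * enu
    nu[sp] <- pmin(nu[sp] + 1, const$nu_lim)
    pm <- tapply(nu, pop_id, mean)
    popmean[as.integer(names(pm))] <- pm
  }
  list(V = V, ref_until = ref_until, g = g, r = r, u = u, U = U,
       tau_rec = trec, tau_facil = tfac, A = A, m1 = m1, m2 = m2,
       o1 = o1, o2 = o2, nu = nu,
       raster = if (length(raster)) do.call(rbind, raster) else
         matrix(0L, 0, 2))
}

# All-to-all pair-STDP drift for one synapse pair, computed directly from
# two spike trains (times in ms). Simultaneous spikes contribute nothing
# (traces are read before the triggering step's increments).
pair_stdp_oracle <- function(pre, post, gamma, const = default_params()) {
  ltp <- 0
  for (tp in post) {
    d <- tp - pre[pre < tp]
    ltp <- ltp + sum(exp(-d / const$tau_m1)) * const$A2_plus
  }
  ltd <- 0
  for (tj in pre) {
    d <- tj - post[post < tj]
    ltd <- ltd + sum(exp(-d / const$tau_o1)) * const$A2_minus
  }
  gamma * (ltp - ltd)
}

# Drive a network through the compiled engine with forced spikes (strong
# stimulus pulses, transmission optionally disabled) and return final
# state. Used by the STDP oracle tests.
force_spikes_cpp <- function(N, spike_step, spike_neuron, consts, cfg,
                             n_steps, A0 = 0.5, raster = FALSE) {
  mask <- matrix(TRUE, N, N); diag(mask) <- FALSE
  state <- list(V = numeric(N), ref_until = rep(-Inf, N),
                g = matrix(0, N, N), r = matrix(1, N, N),
                u = matrix(0.5, N, N), U = matrix(0.5, N, N),
                tau_rec = matrix(500, N, N), tau_facil = matrix(450, N, N),
                A = matrix(A0, N, N) * mask,
                m1 = numeric(N), m2 = numeric(N), o1 = numeric(N),
                o2 = numeric(N), nu = numeric(N), mask = mask)
  stpnet:::sim_phase_cpp(state, consts, cfg, rep(1L, N), 0,
                         as.integer(spike_step), as.integer(spike_neuron - 1L),
                         2.0, as.integer(n_steps), 0, 0L, list(), list(),
                         raster)
}

# cfg builder for direct sim_phase_cpp calls
raw_cfg <- function(gamma = 1, eta_bar = 0.1, learn_scale = 1,
                    learn = c(U = FALSE, taurec = FALSE, taufacil = FALSE,
                              A = FALSE),
                    facil_first = TRUE, g_scale = 0, refrac_gate = FALSE) {
  list(gamma = gamma, eta_bar = eta_bar, learn_scale = learn_scale,
       learn = learn, facil_first = facil_first, g_scale = g_scale,
       refrac_gate = refrac_gate)
}

# Poisson-like spike train with refractory thinning, on the ms grid.
ref_poisson_train <- function(rate_hz, dur_ms, t_ref = 10) {
  p <- rate_hz / 1000
  cand <- which(stats::runif(dur_ms) < p) - 1L
  keep <- integer(0); last <- -Inf
  for (t in cand) if (t - last >= t_ref + 1) { keep <- c(keep, t); last <- t }
  keep
}
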