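test_that("rate EMA estimates steady firing rates and decays to zero", {
  const <- default_params()
  nu <- 5
  for (k in 1:3000) nu <- rate_ema_step(nu, FALSE, const)
  expect_lt(nu, 0.3)                       # no spikes: decays toward 0
  # periodic 20 Hz train over 30 s estimates ~20 Hz
  nu <- 0
  for (k in 1:30000) nu <- rate_ema_step(nu, k %% 50 == 0, const)
  expect_equal(as.numeric(nu), 20, tolerance = 0.05 * 20)
  # EMA never exceeds the refractory limit
  nu <- 0
  for (k in 1:3000) nu <- rate_ema_step(nu, k %% 10 == 0, const)
  expect_lte(nu, const$nu_lim)
})

test_that("error and adaptive learning rate follow their closed forms", {
  expect_equal(compute_error(30, 30), 0)
  expect_equal(compute_error(30, 5), 0.0625)
  expect_equal(compute_error(5, 30), compute_error(30, 5))
  expect_equal(adaptive_learning_rate(30, 30), 0.1)
  expect_equal(adaptive_learning_rate(30, 5), 0.15625)
  expect_equal(adaptive_learning_rate(5, 30), 0.05625)
})

test_that("per-spike deltas descend the surrogate error by finite differences", {
  const <- default_params()
  cfg <- learning_config("full", learn_scale = 1)
  fd <- function(f, p, h = 1e-7) (f(p + h) - f(p - h)) / (2 * h)
  nu_targ <- 5
  for (U in c(0.1, 0.4, 0.8)) for (tr_s in c(0.15, 0.5, 0.85)) {
    for (A in c(0.05, 0.5, 1)) {
      tf_s <- 0.4
      # surrogate rate relations (seconds units) evaluated self-consistently
      surr <- list(
        taurec = list(nu = function(p) A / p, p0 = tr_s,
                      get = function(d) d$dtau_rec),
        U = list(nu = function(p) A / p, p0 = U, get = function(d) d$dU),
        taufacil = list(nu = function(p) A * p, p0 = tf_s,
                        get = function(d) d$dtau_facil),
        A = list(nu = function(p) p / tr_s, p0 = A,
                 get = function(d) d$dA_stp))
      for (nm in names(surr)) {
        sg <- surr[[nm]]
        nu_meas <- sg$nu(sg$p0)
        if (abs(nu_targ - nu_meas) < 1e-9) next
        d <- stp_learning_deltas(U, tr_s * 1000, tf_s * 1000, A,
                                 nu_targ, nu_meas, cfg, const)
        E <- function(p) ((nu_targ - sg$nu(p)) / const$nu_lim)^2
        expect_equal(sign(sg$get(d)), -sign(fd(E, sg$p0)),
                     info = paste(nm, U, tr_s, A))
      }
    }
  }
})

test_that("deltas are linear in A, scheme flags zero excluded parameters", {
  const <- default_params()
  cfg <- learning_config("full", learn_scale = 1)
  d1 <- stp_learning_deltas(0.5, 500, 400, 0.2, 30, 10, cfg, const)
  d2 <- stp_learning_deltas(0.5, 500, 400, 0.4, 30, 10, cfg, const)
  expect_equal(d2$dtau_rec, 2 * d1$dtau_rec)
  expect_equal(d2$dU, 2 * d1$dU)
  expect_equal(d2$dtau_facil, 2 * d1$dtau_facil)
  expect_equal(d2$dA_stp, d1$dA_stp)       # the A rule does not scale with A
  # zero error: all deltas vanish
  d0 <- stp_learning_deltas(0.5, 500, 400, 0.2, 30, 30, cfg, const)
  expect_true(all(unlist(d0) == 0))
  # scheme exclusions
  dm <- stp_learning_deltas(0.5, 500, 400, 0.2, 30, 10,
                            learning_config("minimal_taurec_A"), const)
  expect_equal(dm$dU, 0)
  expect_equal(dm$dtau_facil, 0)
  expect_true(dm$dtau_rec != 0 && dm$dA_stp != 0)
  dua <- stp_learning_deltas(0.5, 500, 400, 0.2, 30, 10,
                             learning_config("U_A"), const)
  expect_equal(dua$dtau_rec, 0)
  expect_true(dua$dU != 0)
})

test_that("sustained one-sided error saturates parameters at their bounds", {
  const <- default_params()
  cfg <- learning_config("full", learn_scale = 1)
  U <- 0.5; tr <- 500; tf <- 400; A <- 0.8
  for (k in 1:5000) {
    d <- stp_learning_deltas(U, tr, tf, A, 5, 40, cfg, const)  # firing too high
    cl <- clip_stp_params(U + d$dU, tr + d$dtau_rec, tf + d$dtau_facil, const)
    U <- cl$U; tr <- cl$tau_rec; tf <- cl$tau_facil
  }
  expect_equal(tr, const$tau_rec_max)      # maximally depressing
  expect_equal(U, const$U_max)
  expect_equal(tf, const$tau_facil_min)
  # and the opposite side
  U <- 0.5; tr <- 500; tf <- 400
  for (k in 1:5000) {
    d <- stp_learning_deltas(U, tr, tf, A, 30, 5, cfg, const)  # firing too low
    cl <- clip_stp_params(U + d$dU, tr + d$dtau_rec, tf + d$dtau_facil, const)
    U <- cl$U; tr <- cl$tau_rec; tf <- cl$tau_facil
  }
  expect_equal(tr, const$tau_rec_min)      # maximally facilitating
  expect_equal(U, const$U_min)
  expect_equal(tf, const$tau_facil_max)
})

test_that("closed-loop control reaches a high-rate target in the network", {
  net <- build_network(network_spec("single"), seed = 3)
  cfg <- learning_config("U_taurec_A", gamma = 1)
  sch <- phase_schedule(120, matrix(30, 1, 2), gamma = 1)
  run <- run_simulation(net, sch, cfg)
  late <- tail(run$recordings$rate_output, 30)
  expect_true(all(abs(late - 30) / 30 < 0.2))  # within the 20% band and stays
})
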