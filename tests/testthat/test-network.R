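test_that("network builders produce the published architectures", {
  s <- network_spec("single")
  expect_equal(s$N, 40)
  expect_equal(lengths(s$populations), c(input = 30, output = 10))
  expect_equal(sum(s$mask), 40 * 39)           # all-to-all, no self synapses
  expect_false(any(diag(s$mask)))

  d <- network_spec("double")
  expect_equal(d$N, 80)
  expect_equal(lengths(d$populations),
               c(in1 = 30, in2 = 30, out1 = 10, out2 = 10))
  # cross connections between functionally different populations are absent
  expect_false(any(d$mask[d$populations$out2, d$populations$in1]))
  expect_false(any(d$mask[d$populations$in1, d$populations$out2]))
  expect_false(any(d$mask[d$populations$in2, d$populations$out1]))
  expect_false(any(d$mask[d$populations$out1, d$populations$in2]))
  # lateral homologous connections exist
  expect_true(all(d$mask[d$populations$out1, d$populations$out2]))

  net <- build_network(d, seed = 9)
  lat <- net$A[d$populations$out1, d$populations$out2]
  expect_true(all(lat >= 1e-3 & lat <= 0.1))   # weak lateral initialization
  within <- net$A[d$populations$out1, d$populations$out1]
  within <- within[row(within) != col(within)]
  expect_true(any(within > 0.1))               # full-range elsewhere
  expect_true(all(net$r == 1))
  expect_equal(net$u, net$U)                   # synaptic rest state
  expect_true(all(net$A[!net$mask] == 0))
})

test_that("identical seeds give bit-identical builds and runs", {
  spec <- network_spec("single")
  n1 <- build_network(spec, seed = 4)
  n2 <- build_network(spec, seed = 4)
  expect_identical(n1$A, n2$A)
  expect_identical(n1$tau_rec, n2$tau_rec)
  cfg <- learning_config("U_taurec_A")
  sch <- phase_schedule(5, matrix(c(5, 5), 1, 2), gamma = 2)
  r1 <- run_simulation(n1, sch, cfg)
  r2 <- run_simulation(n2, sch, cfg)
  expect_identical(r1$net$A, r2$net$A)
  expect_identical(r1$recordings, r2$recordings)
})

test_that("a zero-duration schedule returns the initial state unchanged", {
  net <- build_network(network_spec("single"), seed = 1)
  run <- run_simulation(net, phase_schedule(numeric(0),
                                            matrix(0, 0, 2), gamma = 2),
                        learning_config("full"))
  expect_identical(run$net$A, net$A)
  expect_null(run$recordings)
})

test_that("compiled engine matches the plain-R reference loop step for step", {
  spec <- network_spec("single", n_in = 9, n_out = 4)
  net <- build_network(spec, seed = 6)
  const <- net$const
  set.seed(61)
  proto <- build_protocol(9, horizon = 400, nu_in = 10)
  inputs <- spec$populations$input
  ev_step <- as.integer(floor(proto$events$time_ms))
  ev_neuron <- as.integer(inputs[proto$events$neuron])
  cfg <- raw_cfg(gamma = 2, eta_bar = 0.1, learn_scale = 5,
                 learn = c(U = TRUE, taurec = TRUE, taufacil = TRUE, A = TRUE),
                 g_scale = const$coupling / spec$N)
  state <- net[c("V", "ref_until", "g", "r", "u", "U", "tau_rec",
                 "tau_facil", "A", "m1", "m2", "o1", "o2", "nu", "mask")]
  pop_id <- net$pop_id
  targets <- c(5, 5)
  res_c <- stpnet:::sim_phase_cpp(state, const, cfg, pop_id, targets,
                                  ev_step, ev_neuron - 1L, 2.0, 400L, 0,
                                  0L, list(), list(), TRUE)
  res_r <- ref_phase_r(state, const, cfg, pop_id, targets,
                       ev_step, ev_neuron, 2.0, 400L, 0)
  expect_equal(length(res_c$raster$step), nrow(res_r$raster))
  expect_equal(res_c$raster$step, res_r$raster[, 1], ignore_attr = TRUE)
  expect_equal(res_c$raster$neuron + 1L, res_r$raster[, 2],
               ignore_attr = TRUE)
  for (nm in c("V", "g", "r", "u", "U", "tau_rec", "tau_facil", "A",
               "m1", "m2", "o1", "o2", "nu"))
    expect_equal(res_c[[nm]], res_r[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE, label = nm)
})

test_that("high-target phases end more facilitating and more symmetric than low", {
  for (seed in 1:3) {
    net <- build_network(network_spec("single"), seed = seed)
    cfg <- learning_config("U_taurec")
    sch <- phase_schedule(c(100, 100),
                          matrix(c(5, 5, 30, 30), 2, 2, byrow = TRUE),
                          gamma = c(2, 1))
    run <- run_simulation(net, sch, cfg)
    r <- run$recordings
    low <- r[r$phase == 1, ]; high <- r[r$phase == 2, ]
    expect_lt(tail(high$tau_rec_output, 1), tail(low$tau_rec_output, 1))
    expect_lt(tail(high$U_output, 1), tail(low$U_output, 1))
    expect_gte(tail(high$s_output, 1), tail(low$s_output, 1) - 0.05)
  }
})

test_that("double scenario develops target-specific recovery time constants", {
  net <- build_network(network_spec("double"), seed = 1)
  run <- run_simulation(net, double_phase_schedule(150),
                        learning_config("full"))
  pops <- net$spec$populations
  both <- c(pops$out1, pops$out2)
  tr1 <- run$net$tau_rec[pops$out1, both][run$net$mask[pops$out1, both]]
  tr2 <- run$net$tau_rec[pops$out2, both][run$net$mask[pops$out2, both]]
  # synapses onto the high-rate target are systematically faster-recovering
  expect_lt(mean(tr1), mean(tr2))
  expect_lt(stats::wilcox.test(tr1, tr2)$p.value, 1e-4)
})
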