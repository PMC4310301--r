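test_that("traces decay exponentially and increment by one per spike", {
  const <- default_params()
  tr <- triplet_traces(2)
  tr$m1[1] <- 1
  for (k in 1:17) tr <- traces_step(tr, c(FALSE, FALSE), const)
  expect_equal(tr$m1[1], exp(-17 / 16.8), tolerance = 1e-12)
  tr2 <- traces_step(triplet_traces(2), c(TRUE, FALSE), const)
  expect_equal(tr2$m1[1], 1)
  expect_equal(tr2$m2[1], 1)
  expect_equal(tr2$o1[1], 1)
  expect_equal(tr2$o2[1], 1)
  expect_equal(tr2$m1[2], 0)
  # two spikes dt apart: m1 = 1 + exp(-dt/tau) just after the second
  for (k in 1:5) tr2 <- traces_step(tr2, c(FALSE, FALSE), const)
  tr3 <- traces_step(tr2, c(TRUE, FALSE), const)
  expect_equal(tr3$m1[1], 1 + exp(-6 / 16.8), tolerance = 1e-12)
})

test_that("triplet deltas vanish without prior activity and match hand values", {
  const <- default_params()
  mask <- matrix(TRUE, 2, 2); diag(mask) <- FALSE
  # all traces zero: no change anywhere
  dA <- stdp_deltas(triplet_traces(2), c(TRUE, FALSE), mask, gamma = 1, const)
  expect_equal(dA, matrix(0, 2, 2))
  # single pre spike (neuron 2) 10 ms before a post spike (neuron 1):
  # potentiation = gamma * exp(-10/16.8) * A2_plus, o2(t-eps) = 0
  tr <- traces_step(triplet_traces(2), c(FALSE, TRUE), const)
  for (k in 1:10) tr <- traces_step(tr, c(FALSE, FALSE), const)
  # traces now at the state just before neuron 1's spike increments
  dA <- stdp_deltas(tr, c(TRUE, FALSE), mask, gamma = 1, const)
  expect_equal(dA[1, 2], exp(-10 / 16.8) * const$A2_plus, tolerance = 1e-12)
  # depression on the outgoing synapse 1 -> 2 uses the target's o1 trace
  expect_equal(dA[2, 1], -exp(-10 / const$tau_o1) * const$A2_minus,
               tolerance = 1e-12)
})

test_that("with triplet amplitudes zeroed the engine matches a pair-STDP oracle", {
  consts <- default_params()
  consts$A3_plus <- 0
  consts$A3_minus <- 0
  set.seed(11)
  for (rep in 1:4) {
    pre <- ref_poisson_train(12, 3000)
    post <- ref_poisson_train(12, 3000)
    steps <- c(pre, post)
    neurons <- c(rep(1, length(pre)), rep(2, length(post)))
    o <- order(steps)
    res <- force_spikes_cpp(2, steps[o], neurons[o], consts,
                            raw_cfg(gamma = 1), n_steps = 3100, A0 = 0.5)
    # synapse 1 -> 2 (pre = neuron 1, post = neuron 2) is entry (2, 1)
    dA_sim <- res$A[2, 1] - 0.5
    dA_oracle <- pair_stdp_oracle(pre, post, gamma = 1, consts)
    expect_equal(dA_sim, dA_oracle, tolerance = 1e-10)
    # and the reverse synapse
    dA_sim_rev <- res$A[1, 2] - 0.5
    dA_oracle_rev <- pair_stdp_oracle(post, pre, gamma = 1, consts)
    expect_equal(dA_sim_rev, dA_oracle_rev, tolerance = 1e-10)
  }
})

test_that("triplet drift over Poisson pairs is potentiating and frequency dependent", {
  consts <- default_params()
  set.seed(5)
  drift <- sapply(c(5, 30), function(rate) {
    mean(replicate(12, {
      pre <- ref_poisson_train(rate, 4000)
      post <- ref_poisson_train(rate, 4000)
      steps <- c(pre, post)
      neurons <- c(rep(1, length(pre)), rep(2, length(post)))
      o <- order(steps)
      res <- force_spikes_cpp(2, steps[o], neurons[o], consts,
                              raw_cfg(gamma = 1), n_steps = 4100, A0 = 0.5)
      (res$A[2, 1] - 0.5) + (res$A[1, 2] - 0.5)
    }))
  })
  expect_gt(drift[2], 0)          # 30 Hz: fire together, wire together
  expect_gt(drift[2], drift[1])   # and much more so than at 5 Hz
})

test_that("weight updates respect the hard bounds and the mask", {
  const <- default_params()
  mask <- matrix(TRUE, 3, 3); diag(mask) <- FALSE
  A <- matrix(0.5, 3, 3); A[!mask] <- 0
  up <- total_weight_update(A, matrix(10, 3, 3), matrix(0, 3, 3), mask, const)
  expect_true(all(up[mask] == const$A_max))
  dn <- total_weight_update(A, matrix(-10, 3, 3), matrix(0, 3, 3), mask, const)
  expect_true(all(dn[mask] == const$A_min))
  expect_true(all(diag(up) == 0))
  # both deltas zero: unchanged
  expect_equal(total_weight_update(A, 0 * A, 0 * A, mask, const), A)
})
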