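pp_default <- plasticity_params()

test_that("STP decay follows the exact exponential closed form", {
  # from u = 1, one second of decay lands at the baseline U = 0.80
  d <- stp_decay(1, 1, pp_default, dt = 1000)
  expect_lt(abs(d$u - 0.80), 1e-4)
  # resting state is a fixed point for any dt
  for (dt in c(0.1, 7, 900)) {
    r <- stp_decay(pp_default$U, 1, pp_default, dt)
    expect_equal(r$u, pp_default$U, tolerance = 1e-15)
    expect_equal(r$x, 1, tolerance = 1e-15)
  }
  # x recovery closed form: x(900 ms) from 0.04 with tau_d = 900 ms
  r <- stp_decay(pp_default$U, 0.04, pp_default, dt = 900)
  expect_equal(r$x, 1 - 0.96 * exp(-1), tolerance = 1e-12)
})

test_that("STP spike jumps reproduce the hand-computed values", {
  j <- stp_on_spike(0.80, 1, pp_default)
  expect_equal(j$u, 0.96, tolerance = 1e-12)
  expect_equal(j$x, 0.04, tolerance = 1e-12)
  expect_equal(j$release, 0.96, tolerance = 1e-12)
  # U = 0 limit: no facilitation, and at u = 0 a fully transparent synapse
  pp0 <- plasticity_params(U = 0)
  j0 <- stp_on_spike(0, 0.7, pp0)
  expect_equal(j0$u, 0)
  expect_equal(j0$x, 0.7)
})

test_that("high-rate spiking drives short-term depression to dominance", {
  u <- pp_default$U; x <- 1
  for (k in 1:50) {               # 100 Hz train
    j <- stp_on_spike(u, x, pp_default)
    u <- j$u; x <- j$x
    d <- stp_decay(u, x, pp_default, dt = 10)
    u <- d$u; x <- d$x
  }
  expect_lt(x, 0.05)
  expect_lt(j$release, 0.05)
})

test_that("STP variables stay in their invariant ranges under any train", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      u <- pp_default$U; x <- 1
      for (k in 1:200) {
        if (runif(1) < 0.5) {
          j <- stp_on_spike(u, x, pp_default)
          u <- j$u; x <- j$x
          expect_true(j$release >= 0 && j$release <= 1)
        } else {
          d <- stp_decay(u, x, pp_default, dt = runif(1, 0.1, 500))
          u <- d$u; x <- d$x
        }
        expect_true(u >= pp_default$U - 1e-12 && u < 1)
        expect_true(x > 0 && x <= 1)
      }
    }
  })
})

test_that("STDP increments match direct evaluation of the update rule", {
  # saturation at the multiplicative bounds
  expect_equal(stdp_delta(1, 10, pp_default), 0)
  expect_equal(stdp_delta(0, -10, pp_default), 0)
  # hand-evaluated LTP at J = 0.5, dt = +20 ms
  expect_equal(stdp_delta(0.5, 20, pp_default), 5e-5 * 0.5 * exp(-1),
               tolerance = 1e-15)
  expect_equal(stdp_delta(0.5, 20, pp_default), 9.197e-6, tolerance = 1e-3)
  # dt = 0 falls in the LTD branch
  expect_equal(stdp_delta(0.5, 0, pp_default),
               -25e-5 * 2 * 0.5, tolerance = 1e-15)
})

test_that("LTP/LTD magnitudes decay with |dt| and LTD dominates at J = 0.5", {
  dts <- c(1, 5, 10, 25, 60)
  ltp <- stdp_delta(0.5, dts, pp_default)
  ltd <- abs(stdp_delta(0.5, -dts, pp_default))
  expect_true(all(diff(ltp) < 0))
  expect_true(all(diff(ltd) < 0))
  expect_true(all(ltd / ltp > 1))
})

test_that("excitatory weights stay in [0, 1] without clamping at mu = 1", {
  withr::with_seed(99, {
    J <- runif(200)
    for (k in 1:500) {
      J <- J + stdp_delta(J, runif(200, -80, 80), pp_default)
      expect_true(all(J >= 0 & J <= 1))
    }
  })
})

test_that("inhibitory efficacies drift monotonically toward zero and beyond", {
  J <- -1
  path <- numeric(300)
  for (k in 1:300) {
    # sustained near-coincident pairing, alternating branch
    J <- J + stdp_delta(J, 5, pp_default)
    J <- J + stdp_delta(J, -5, pp_default)
    path[k] <- J
  }
  expect_true(all(diff(path) > 0))      # monotone upward drift
  expect_gt(path[300], -1)
  # pushed far enough the efficacy crosses into excitatory territory
  for (k in 1:20000) J <- J + stdp_delta(J, 5, pp_default) +
    stdp_delta(J, -5, pp_default)
  expect_gt(J, 0)
})

test_that("apply_stdp reproduces the two-spike script hand trace", {
  st <- tiny_state(2)
  st$C[2, 1] <- 1L
  st$J[2, 1] <- 0.5
  # unit 1 (pre) fires at t = 0, unit 2 (post) at t = 20 ms
  st$t <- 0
  st$last_spike[1] <- 0
  st <- apply_stdp(st, spikers = 1L, pp = pp_default)
  expect_equal(st$J[2, 1], 0.5)     # LTP side: partner never fired -> no-op
  st$t <- 20
  st$last_spike[2] <- 20
  st <- apply_stdp(st, spikers = 2L, pp = pp_default)
  expect_equal(st$J[2, 1], 0.5 + stdp_delta(0.5, 20, pp_default),
               tolerance = 1e-15)
  # the reverse synapse was created structurally by the LTD branch at J = 0
  expect_identical(st$C[1, 2], 1L)
  expect_equal(st$J[1, 2], 0)
})

test_that("apply_stdp without spikes leaves weights untouched", {
  st <- build_network(network_params(c_prob = 0.2, N_E = 8, N_I = 2),
                      seed = 2)
  st2 <- apply_stdp(st, integer(0), plasticity_params())
  expect_identical(st2$J, st$J)
  expect_identical(st2$C, st$C)
})

test_that("per-spike amplitudes carry sign and scale", {
  pp <- plasticity_params(g_scale = 1000)
  expect_equal(per_spike_amplitude(0.65, 1L, 0.8, pp), 520)
  expect_equal(per_spike_amplitude(-1, 1L, 0.8, pp), -800)
  expect_equal(per_spike_amplitude(c(0.5, 0.5), c(1L, 0L), 0, pp), c(0, 0))
  # absent synapse contributes nothing even with nonzero release
  expect_equal(per_spike_amplitude(0.65, 0L, 0.9, pp), 0)
})

test_that("postsynaptic current decays exactly and integrates to G * tau_syn", {
  np <- neuron_params()
  expect_equal(syn_current_step(100, 0, np, dt = 5), 100 * exp(-1),
               tolerance = 1e-12)
  expect_equal(syn_current_step(0, 0, np, dt = 1), 0)
  # Riemann integral of the impulse response
  G <- 750
  I <- syn_current_step(0, G, np, dt = 0.1)
  dt <- 0.01
  total <- 0
  for (k in seq_len(5000)) {      # 50 ms = 10 tau_syn
    total <- total + I * dt
    I <- syn_current_step(I, 0, np, dt = dt)
  }
  expect_equal(total, G * np$tau_syn, tolerance = G * np$tau_syn * 0.01)
})
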