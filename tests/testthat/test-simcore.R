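# The compiled phase integrator is checked against the pure-R module
# functions, which define the model semantics.

core_args <- function(st, I_ext, t0, t_end, dt, bg_trains,
                      transmit_somatic = TRUE, bg_stdp = FALSE,
                      continuous = FALSE, eval_dt = dt,
                      t_sync = NULL) {
  N <- length(st$V)
  if (is.null(t_sync))
    t_sync <- if (continuous) matrix(0, N, N) else matrix(0, 1, 1)
  list(J = st$J + 0, C = st$C + 0L, V = st$V + 0, w = st$w + 0,
       u = st$u + 0, x = st$x + 0, I_syn = st$I_syn + 0,
       last_spike = st$last_spike + 0,
       t0 = t0, t_end = t_end, dt = dt, I_ext = I_ext,
       bg_trains = bg_trains, bg_pos = integer(N),
       np = unclass(st$np), pp = unclass(st$pp),
       transmit_somatic = transmit_somatic,
       background_drives_stdp = bg_stdp,
       allow_self = TRUE, record_every = -1,
       stdp_continuous = continuous, stdp_eval_dt = eval_dt,
       t_sync = t_sync)
}

small_net <- function(seed = 5) {
  pp <- plasticity_params(g_scale = 500)
  build_network(network_params(c_prob = 0.3, N_E = 8, N_I = 2,
                               J_EE = 0.3, J_IE = 0.3,
                               J_II = -0.4, J_EI = -0.4),
                seed = seed, pp = pp)
}

test_that("the compiled core matches the R reference step for step", {
  st <- small_net()
  N <- 10
  dt <- 0.1
  steps <- 400
  # scripted background: three units with fixed spike times
  bg <- rep(list(numeric(0)), N)
  bg[[2]] <- c(3.05, 17.2, 30.11)
  bg[[5]] <- c(10.0, 10.04)
  bg[[9]] <- seq(5, 39, by = 7)
  I_ext <- c(rep(800, 4), rep(0, 6))

  a <- core_args(st, I_ext, 0, steps * dt, dt, bg)
  res <- do.call(spikewm:::sim_phase_cpp, a)

  # R reference trajectory: additive clock and per-unit spike cursors,
  # mirroring the core's consumption rule exactly
  rst <- st
  tcur <- 0
  pos <- integer(N)
  for (k in seq_len(steps)) {
    t1 <- tcur + dt
    bg_units <- integer(0)
    for (j in seq_len(N)) {
      while (pos[j] < length(bg[[j]]) && bg[[j]][pos[j] + 1] < t1) {
        bg_units <- c(bg_units, j)
        pos[j] <- pos[j] + 1L
      }
    }
    out <- r_reference_step(rst, I_ext, bg_units, st$np, st$pp, dt)
    rst <- out$state
    tcur <- t1
  }

  expect_equal(a$V, rst$V, tolerance = 1e-10)
  expect_equal(a$w, rst$w, tolerance = 1e-10)
  expect_equal(a$u, rst$u, tolerance = 1e-12)
  expect_equal(a$x, rst$x, tolerance = 1e-12)
  expect_equal(a$I_syn, rst$I_syn, tolerance = 1e-9)
  expect_equal(a$J, rst$J, tolerance = 1e-12)
  expect_identical(a$C, rst$C)
  expect_equal(a$last_spike, rst$last_spike)
  expect_gt(length(res$spike_t), 5)    # the script actually spiked
})

test_that("continuous STDP closed form matches the per-step brute force", {
  st <- small_net(seed = 8)
  N <- 10
  dt <- 0.1
  steps <- 500
  bg <- rep(list(numeric(0)), N)
  bg[[3]] <- c(7.3, 22.0)
  I_ext <- c(rep(900, 3), rep(0, 7))

  a <- core_args(st, I_ext, 0, steps * dt, dt, bg,
                 continuous = TRUE, eval_dt = dt)
  res <- do.call(spikewm:::sim_phase_cpp, a)
  spikes <- data.frame(t = res$spike_t, unit = res$spike_unit)
  expect_gt(nrow(spikes), 5)

  # brute force: replay the emitted spike train, applying the pair rule at
  # every evaluation step for every ordered pair with defined last spikes
  J <- st$J + 0
  last <- rep(NA_real_, N)
  pp <- st$pp
  for (k in seq_len(steps)) {
    t1 <- k * dt
    def <- which(!is.na(last))
    for (i in def) for (j in def)
      J[i, j] <- J[i, j] + stdp_delta(J[i, j], last[i] - last[j], pp)
    sp <- spikes$unit[abs(spikes$t - t1) < 1e-9]
    last[sp] <- t1
  }
  expect_equal(a$J, J, tolerance = 1e-8)
})

test_that("identical seeds give identical runs; different seeds differ", {
  sched <- event_schedule(0, "STIM_LEFT", horizon = 300)
  r1 <- run_simulation(sched, seed = 17, keep_final_state = FALSE)
  r2 <- run_simulation(sched, seed = 17, keep_final_state = FALSE)
  r3 <- run_simulation(sched, seed = 18, keep_final_state = FALSE)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$trace, r2$trace)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a null (OFF-only) schedule stays at background-driven baseline", {
  sched <- event_schedule(0, "STIM_OFF", horizon = 2000)
  run <- run_simulation(sched, seed = 4, keep_final_state = FALSE)
  m <- phase_metrics(run)
  expect_identical(m$dominance, "NONE")
  # background-driven baseline sits far below evoked rates (~60-100 Hz)
  expect_lt(m$rate_left, 20)
  expect_lt(m$rate_right, 20)
})
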