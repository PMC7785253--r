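# Shared fixtures: all built in code at test time.

# Minimal hand-built network state for unit-level dynamics tests: n isolated
# units (no synapses), resting initial conditions.
tiny_state <- function(n = 1, np = neuron_params(), pp = plasticity_params()) {
  st <- list(t = 0,
             V = rep(np$E_L, n), w = rep(0, n),
             u = rep(pp$U, n), x = rep(1, n),
             I_syn = rep(0, n),
             last_spike = rep(NA_real_, n),
             is_excitatory = rep(TRUE, n),
             J = matrix(0, n, n), C = matrix(0L, n, n),
             params = NULL, np = np, pp = pp)
  class(st) <- "network_state"
  st
}

# Integrate a single isolated unit under a constant current; returns spike
# times and the V/w traces sampled every step.
integrate_unit <- function(I, t_max, dt = 0.1, np = neuron_params()) {
  st <- tiny_state(1, np = np)
  steps <- round(t_max / dt)
  Vs <- ws <- numeric(steps)
  spikes <- numeric(0)
  for (k in seq_len(steps)) {
    out <- membrane_step(st, I, np = np, dt = dt)
    st <- out$state
    if (length(out$spikers)) spikes <- c(spikes, st$t)
    Vs[k] <- st$V
    ws[k] <- st$w
  }
  list(V = Vs, w = ws, spikes = spikes,
       t = seq_len(steps) * dt, state = st)
}

# Pure-R reference of one simulation step in event-wise STDP mode, mirroring
# the compiled core's ordering: STP decay, background delivery, I_syn decay +
# impulses, membrane Euler step, STP jump + recurrent delivery for spikers,
# event STDP. Used as the independent oracle for sim_phase_cpp.
r_reference_step <- function(st, I_ext, bg_spikes_units, np, pp,
                             dt, transmit_somatic = TRUE) {
  dec <- stp_decay(st$u, st$x, pp, dt)
  st$u <- dec$u
  st$x <- dec$x
  incoming <- rep(0, length(st$V))
  for (j in bg_spikes_units) {
    jump <- stp_on_spike(st$u[j], st$x[j], pp)
    st$u[j] <- jump$u
    st$x[j] <- jump$x
    incoming <- incoming +
      per_spike_amplitude(st$J[, j], st$C[, j], jump$release, pp)
  }
  st$I_syn <- syn_current_step(st$I_syn, incoming, np, dt)
  out <- membrane_step(st, I_ext, np = np, dt = dt)
  st <- out$state
  for (s in out$spikers) {
    jump <- stp_on_spike(st$u[s], st$x[s], pp)
    st$u[s] <- jump$u
    st$x[s] <- jump$x
    if (transmit_somatic)
      st$I_syn <- st$I_syn +
        per_spike_amplitude(st$J[, s], st$C[, s], jump$release, pp)
  }
  st <- apply_stdp(st, out$spikers, pp)
  list(state = st, spikers = out$spikers)
}
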