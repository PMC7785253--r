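## Phase-driven simulation: the R driver expands an event schedule into
## constant-stimulus phases, precomputes the per-phase external current and
## the frozen background realization, and advances the compiled core one
## phase at a time, snapshotting weights at every phase boundary.

#' Run the embodied network over an event schedule
#'
#' Builds the initial network from `seed`, draws one frozen Poisson
#' background realization for the whole horizon, and integrates the coupled
#' membrane / short-term plasticity / STDP / structural plasticity dynamics
#' with time step `dt`. All randomness derives from the single seed; repeated
#' calls with identical arguments give identical spike records and weights.
#'
#' @param schedule An [event_schedule()].
#' @param net A [network_params()] object.
#' @param np A [neuron_params()] object.
#' @param pp A [plasticity_params()] object.
#' @param sp A [stimulus_params()] object.
#' @param seed Single integer seed.
#' @param dt Integration step (ms), default 0.1.
#' @param bg_rate Background Poisson rate per unit (Hz), default 10.
#' @param transmit_somatic Deliver somatic spikes through the recurrent
#'   weights (default TRUE). With FALSE the network is driven purely by the
#'   background trains and somatic spikes only feed the motor decoder.
#' @param background_drives_stdp Treat background spikes as presynaptic
#'   events for the STDP clock (default FALSE: pairing uses somatic spikes
#'   only, so learning stays stimulus-driven).
#' @param stdp_mode `"continuous"` (default): the nearest-neighbour rule is
#'   re-evaluated every `stdp_eval_dt` while a pairing holds, applied in
#'   exact closed form between spike events; `"event"`: each pairing is
#'   applied once, at spike times. See the methods vignette for why the
#'   continuous reading is the default.
#' @param stdp_eval_dt Evaluation interval of the continuous rule (ms,
#'   default 4). The learning rates are per evaluation, so this interval sets
#'   the overall speed of long-term plasticity; the default places structure
#'   formation at a timescale of roughly ten seconds of evoked activity (see
#'   the methods vignette).
#' @param allow_self_connections Permit structural formation of
#'   self-connections (default TRUE).
#' @param record_every Sampling interval (ms) of the mean-efficacy trace.
#' @param keep_final_state Attach the full final `network_state` (default
#'   TRUE).
#' @return An object of class `wm_run`: list with `spikes` (data.frame
#'   `t_ms`, `unit`), `phases` (schedule segments), `trace` (time, mean
#'   efficacy over present synapses, density), `snapshots` (per phase
#'   boundary: time, connectivity stats), `final_state`, `seed`, `dt`,
#'   and the parameter blocks.
#' @export
run_simulation <- function(schedule,
                           net = network_params(),
                           np = neuron_params(),
                           pp = plasticity_params(),
                           sp = stimulus_params(),
                           seed = 1L,
                           dt = 0.1,
                           bg_rate = 10,
                           transmit_somatic = TRUE,
                           background_drives_stdp = FALSE,
                           stdp_mode = c("continuous", "event"),
                           stdp_eval_dt = 4,
                           allow_self_connections = TRUE,
                           record_every = 250,
                           keep_final_state = TRUE) {
  stopifnot(inherits(schedule, "event_schedule"))
  stdp_mode <- match.arg(stdp_mode)
  if (dt <= 0) stop("run_simulation: dt must be > 0", call. = FALSE)
  if (stdp_eval_dt <= 0)
    stop("run_simulation: stdp_eval_dt must be > 0", call. = FALSE)
  if (stdp_mode == "continuous" && pp$mu != 1)
    stop("run_simulation: continuous STDP evaluation requires mu = 1 ",
         "(the closed-form accrual is exact only for the linear rule)",
         call. = FALSE)
  N <- net$N_E + net$N_I
  if (sp$N != N)
    stop("run_simulation: stimulus_params$N must match the network size",
         call. = FALSE)

  sub <- withr::with_seed(as.integer(seed),
                          sample.int(.Machine$integer.max - 1L, 2L))
  st <- build_network(net, seed = sub[1], np = np, pp = pp)
  phases <- schedule_phases(schedule)
  horizon <- phases$end[nrow(phases)]
  bg <- make_background(N, bg_rate, horizon, seed = sub[2])

  ## Dedicated copies: the compiled core updates these in place across phases.
  J <- st$J + 0
  C <- st$C + 0L
  V <- st$V + 0
  w <- st$w + 0
  u <- st$u + 0
  x <- st$x + 0
  I_syn <- st$I_syn + 0
  last_spike <- st$last_spike + 0
  bg_pos <- integer(N)
  continuous <- stdp_mode == "continuous"
  t_sync <- if (continuous) matrix(0, N, N) else matrix(0, 1, 1)

  spike_t <- vector("list", nrow(phases))
  spike_u <- vector("list", nrow(phases))
  trace <- vector("list", nrow(phases))
  snapshots <- vector("list", nrow(phases))
  t_cur <- 0

  for (k in seq_len(nrow(phases))) {
    ph <- phases[k, ]
    sp_k <- sp
    sp_k$intensity_scale <- sp$intensity_scale * ph$intensity_scale
    cfg <- switch(ph$event, STIM_LEFT = "LEFT", STIM_RIGHT = "RIGHT",
                  STIM_OFF = "OFF")
    I_ext <- 1000 * bimodal_input(cfg, sp_k)   # nA -> pA
    res <- sim_phase_cpp(J, C, V, w, u, x, I_syn, last_spike,
                         t_cur, ph$end, dt, I_ext,
                         bg$trains, bg_pos,
                         unclass(np), unclass(pp),
                         transmit_somatic, background_drives_stdp,
                         allow_self_connections, record_every,
                         continuous, stdp_eval_dt, t_sync)
    t_cur <- res$t
    bg_pos <- res$bg_pos
    spike_t[[k]] <- res$spike_t
    spike_u[[k]] <- res$spike_unit
    trace[[k]] <- data.frame(t_ms = res$trace_t, mean_J = res$trace_mean_J,
                             density = res$trace_density)
    snap_state <- list(J = J, C = C, is_excitatory = st$is_excitatory)
    snapshots[[k]] <- c(list(t_ms = t_cur, phase = ph$event),
                        connection_stats(snap_state))
  }

  final_state <- NULL
  if (keep_final_state) {
    final_state <- st
    final_state$t <- t_cur
    final_state$V <- V
    final_state$w <- w
    final_state$u <- u
    final_state$x <- x
    final_state$I_syn <- I_syn
    final_state$last_spike <- last_spike
    final_state$J <- J
    final_state$C <- C
  }

  out <- list(spikes = data.frame(t_ms = unlist(spike_t),
                                  unit = unlist(spike_u)),
              phases = phases,
              trace = do.call(rbind, trace),
              snapshots = snapshots,
              final_state = final_state,
              seed = as.integer(seed), dt = dt, bg_rate = bg_rate,
              stdp_mode = stdp_mode, stdp_eval_dt = stdp_eval_dt,
              transmit_somatic = transmit_somatic,
              background_drives_stdp = background_drives_stdp,
              allow_self_connections = allow_self_connections,
              net = net, np = np, pp = pp, sp = sp)
  class(out) <- "wm_run"
  out
}

#' @export
print.wm_run <- function(x, ...) {
  cat("<wm_run> ", nrow(x$phases), " phases, horizon ",
      x$phases$end[nrow(x$phases)] / 1000, " s, ",
      nrow(x$spikes), " spikes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## Mean firing rate (Hz) of a unit set in a time window.
window_rate <- function(spikes, units, t0, t1) {
  n <- sum(spikes$t_ms > t0 & spikes$t_ms <= t1 & spikes$unit %in% units)
  1000 * n / (length(units) * (t1 - t0))
}
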