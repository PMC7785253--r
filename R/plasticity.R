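## Short-term plasticity (per presynaptic unit), nearest-neighbour
## multiplicative STDP with structural plasticity, and the current-based
## synapse. These R functions define the model semantics; the compiled core
## in src/ applies the identical rules step by step and is checked against
## them in the test suite.

#' Inter-spike decay of the short-term plasticity variables
#'
#' Between presynaptic spikes the release probability `u` relaxes toward its
#' baseline `U` with time constant `tau_f` and the resource variable `x`
#' recovers toward 1 with `tau_d`. The update is the exact exponential
#' solution, not an Euler step, so arbitrarily large `dt` is allowed.
#'
#' @param u,x Numeric vectors (or scalars) of STP state.
#' @param pp A [plasticity_params()] object.
#' @param dt Elapsed time (ms).
#' @return List with decayed `u` and `x`.
#' @export
stp_decay <- function(u, x, pp = plasticity_params(), dt) {
  if (dt <= 0) stop("stp_decay: dt must be > 0", call. = FALSE)
  list(u = pp$U + (u - pp$U) * exp(-dt / pp$tau_f),
       x = 1 + (x - 1) * exp(-dt / pp$tau_d))
}

#' Presynaptic spike update of the short-term plasticity variables
#'
#' On a presynaptic spike the release probability jumps,
#' u -> u + U (1 - u), and the resource pool is then decremented by the
#' released fraction, x -> (1 - u') x. The fraction transmitted by the spike
#' is `u' * x` with `x` taken before its decrement (the jump in `u` is
#' applied first, then the release consumes the pre-spike pool).
#'
#' @param u,x Scalars (or aligned vectors) of STP state.
#' @param pp A [plasticity_params()] object.
#' @return List with post-spike `u`, `x` and the `release` fraction.
#' @examples
#' stp_on_spike(0.80, 1)  # u' = 0.96, x' = 0.04, release = 0.96
#' @export
stp_on_spike <- function(u, x, pp = plasticity_params()) {
  u2 <- u + pp$U * (1 - u)
  release <- u2 * x
  list(u = u2, x = (1 - u2) * x, release = release)
}

#' STDP weight increment for a single pre/post spike-time difference
#'
#' The pair-based rule with multiplicative soft bounds:
#' \deqn{\Delta J = \lambda_+ (1-J)^\mu e^{-\Delta t/\tau_+}} for
#' \eqn{\Delta t > 0} (post after pre, LTP), and
#' \deqn{\Delta J = -\lambda_- \alpha J^\mu e^{\Delta t/\tau_-}} for
#' \eqn{\Delta t \le 0} (LTD; a simultaneous pair falls in this branch).
#' At `mu = 1` excitatory weights in [0, 1] stay in [0, 1] without clamping;
#' for inhibitory weights (J < 0) both branches are non-negative, so
#' sustained pairing drives them monotonically toward 0 and beyond — the
#' documented drift that eventually violates Dale's law.
#'
#' @param J Signed weight of the synapse pre -> post.
#' @param delta_t Spike-time difference t_post - t_pre (ms), under the
#'   nearest-neighbour convention.
#' @param pp A [plasticity_params()] object.
#' @return The increment \eqn{\Delta J}.
#' @export
stdp_delta <- function(J, delta_t, pp = plasticity_params()) {
  pow <- function(v, mu) sign(v) * abs(v)^mu   # sign-preserving for J < 0
  ifelse(delta_t > 0,
         pp$lambda_plus * pow(1 - J, pp$mu) * exp(-delta_t / pp$tau_plus),
         -pp$lambda_minus * pp$alpha * pow(J, pp$mu) *
           exp(delta_t / pp$tau_minus))
}

#' Apply nearest-neighbour STDP for one step's spikes
#'
#' For each unit `s` that spiked at the current time `state$t`, every partner
#' `p` with a defined last spike contributes two evaluations: the synapse
#' p -> s receives `stdp_delta(J, t - last_spike[p])` (LTP when the partner
#' fired earlier), and the synapse s -> p receives
#' `stdp_delta(J, last_spike[p] - t)` (the LTD branch). Partners that spiked
#' in the same step enter with `delta_t = 0` (LTD branch). Each pair
#' interaction uses only the partner's most recent spike.
#'
#' Structural plasticity: when an update fires for an absent synapse
#' (`C[i, j] = 0`), the connection is created with `J = 0` before the update
#' is applied; with `allow_self` the diagonal can be created too. Weights are
#' finally clamped to [-1, 1] (unreachable under the default multiplicative
#' rule; a guard for pathological configurations).
#'
#' `state$last_spike` must already include the current step's spikes (as left
#' by [membrane_step()]).
#'
#' @param state A `network_state` whose clock and `last_spike` reflect the
#'   just-completed membrane step.
#' @param spikers Integer indices of units that spiked this step.
#' @param pp A [plasticity_params()] object.
#' @param allow_self Permit formation of self-connections (default TRUE).
#' @return The state with updated `J` and `C`.
#' @export
apply_stdp <- function(state, spikers, pp = state$pp, allow_self = TRUE) {
  if (!length(spikers)) return(state)
  t_now <- state$t
  N <- nrow(state$J)
  ## Partners' reference times: most recent spike, which for units spiking
  ## this step is t_now itself (delta_t = 0 -> LTD branch).
  ref <- state$last_spike
  for (s in spikers) {
    partners <- which(!is.na(ref))
    if (!allow_self) partners <- partners[partners != s]
    if (!length(partners)) next
    dt_post <- t_now - ref[partners]         # s as postsynaptic: p -> s
    Jrow <- state$J[s, partners]
    grow <- state$C[s, partners] == 0L
    dJ <- stdp_delta(ifelse(grow, 0, Jrow), dt_post, pp)
    state$J[s, partners] <- pmin(1, pmax(-1, ifelse(grow, 0, Jrow) + dJ))
    state$C[s, partners] <- 1L
    dt_pre <- ref[partners] - t_now          # s as presynaptic: s -> p
    Jcol <- state$J[partners, s]
    grow2 <- state$C[partners, s] == 0L
    dJ2 <- stdp_delta(ifelse(grow2, 0, Jcol), dt_pre, pp)
    state$J[partners, s] <- pmin(1, pmax(-1, ifelse(grow2, 0, Jcol) + dJ2))
    state$C[partners, s] <- 1L
  }
  state
}

#' Per-spike postsynaptic current amplitudes
#'
#' The current injected into each postsynaptic target by one spike of
#' presynaptic unit `j` is `g_scale * J[i, j] * release`, restricted to
#' existing synapses (`C[i, j] = 1`). The sign travels with `J`, so
#' inhibitory efferents hyperpolarize.
#'
#' @param J_col Column `j` of the weight matrix (efferents of unit `j`).
#' @param C_col Matching column of the connectivity matrix.
#' @param release Transmitted fraction from [stp_on_spike()].
#' @param pp A [plasticity_params()] object (supplies `g_scale`).
#' @return Per-target amplitude vector (pA).
#' @export
per_spike_amplitude <- function(J_col, C_col, release,
                                pp = plasticity_params()) {
  (pp$g_scale * release) * J_col * (C_col == 1L)
}

#' Exponential decay and impulse update of the postsynaptic current
#'
#' `I_syn` decays exponentially with `tau_syn` (exact solution) and is then
#' raised instantaneously by the summed amplitudes of this step's presynaptic
#' spikes. The time integral of the response to a single impulse of amplitude
#' G equals `G * tau_syn`.
#'
#' @param I_syn Per-unit current (pA).
#' @param incoming Per-unit summed spike amplitudes arriving this step (pA).
#' @param np A [neuron_params()] object (supplies `tau_syn`).
#' @param dt Time step (ms).
#' @return Updated current vector (pA).
#' @export
syn_current_step <- function(I_syn, incoming, np = neuron_params(), dt) {
  if (dt <= 0) stop("syn_current_step: dt must be > 0", call. = FALSE)
  I_syn * exp(-dt / np$tau_syn) + incoming
}
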