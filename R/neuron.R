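## aEIF membrane and adaptation dynamics. Forward Euler on
##   C_m dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T)
##               - w + I_syn + I_ext
##   tau_w dw/dt = a_w (V - E_L) - w
## A unit with V > V_T after the update spikes: V is recorded at V_peak for
## that instant, then reset to E_L, and w jumps by b_w. No refractory period.
## The exponential's argument is clamped at +20 so that a suprathreshold
## excursion inside one step cannot overflow before the reset.

EXP_ARG_CLAMP <- 20

#' One forward-Euler step of the membrane and adaptation equations
#'
#' Advances every unit by `dt`, applies the reset rule to threshold crossers
#' and returns the indices of units that spiked. This R implementation is the
#' reference for the compiled simulation core and is used directly in tests
#' and small-scale explorations; full runs go through [run_simulation()].
#'
#' @param state A `network_state`.
#' @param I_ext Per-unit external current (pA).
#' @param np A [neuron_params()] object.
#' @param dt Time step (ms).
#' @return A list with the updated `state` and integer vector `spikers`.
#' @export
membrane_step <- function(state, I_ext, np = state$np, dt = 0.1) {
  if (dt <= 0) stop("membrane_step: dt must be > 0", call. = FALSE)
  N <- length(state$V)
  if (length(I_ext) != N)
    stop("membrane_step: I_ext must have one entry per unit", call. = FALSE)
  V <- state$V
  w <- state$w
  arg <- pmin((V - np$V_T) / np$Delta_T, EXP_ARG_CLAMP)
  dV <- (-np$g_L * (V - np$E_L) + np$g_L * np$Delta_T * exp(arg) -
           w + state$I_syn + I_ext) / np$C_m
  dw <- (np$a_w * (V - np$E_L) - w) / np$tau_w
  V <- V + dt * dV
  w <- w + dt * dw
  if (any(!is.finite(V)) || any(!is.finite(w)))
    stop("membrane_step: non-finite state (numerical blow-up; reduce dt)",
         call. = FALSE)
  spikers <- which(V > np$V_T)
  t_new <- state$t + dt
  if (length(spikers)) {
    V[spikers] <- np$E_L
    w[spikers] <- w[spikers] + np$b_w
    state$last_spike[spikers] <- t_new
  }
  state$V <- V
  state$w <- w
  state$t <- t_new
  list(state = state, spikers = spikers)
}

#' Subthreshold fixed point of the membrane/adaptation system
#'
#' Solves for the rest point V* of the coupled equations under a constant
#' current, with the adaptation nullcline w = a_w (V - E_L) substituted in.
#' Used as a test oracle; signals an error when the injected current exceeds
#' the rheobase so that no subthreshold fixed point exists.
#'
#' @param I Constant injected current (pA).
#' @param np A [neuron_params()] object.
#' @return V* in mV.
#' @export
subthreshold_steady_state <- function(I, np = neuron_params()) {
  f <- function(V) {
    -np$g_L * (V - np$E_L) +
      np$g_L * np$Delta_T * exp((V - np$V_T) / np$Delta_T) -
      np$a_w * (V - np$E_L) + I
  }
  ## The stable subthreshold branch is the first downward zero crossing of f
  ## scanning upward in V (the exponential term turns f back up past the
  ## knee, so later crossings are the unstable branch).
  Vgrid <- seq(np$E_L - 40, np$V_T + 10, by = 0.01)
  fg <- f(Vgrid)
  sgn <- sign(fg)
  cross <- which(sgn[-1] <= 0 & sgn[-length(sgn)] > 0)
  if (!length(cross))
    stop("subthreshold_steady_state: no subthreshold fixed point ",
         "(current above rheobase)", call. = FALSE)
  lo <- Vgrid[cross[1]]
  hi <- Vgrid[cross[1] + 1]
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
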