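## Network construction and connectivity bookkeeping.
##
## Orientation convention (used everywhere in the package): J[i, j] and
## C[i, j] describe the synapse from presynaptic unit j onto postsynaptic
## unit i, i.e. column j holds the efferents of unit j.

#' Build the initial network state
#'
#' Assigns excitatory/inhibitory identity uniformly at random (independent of
#' ring position), samples exactly `round(c * N * (N - 1))` ordered
#' off-diagonal pairs without replacement as the initial synapses, and sets
#' every state variable to its resting value: V = E_L, w = 0, u = U, x = 1,
#' I_syn = 0, t = 0. Initial efficacies follow the presynaptic class
#' (Dale's law): `J_EE`/`J_IE` for excitatory efferents, `J_II`/`J_EI` for
#' inhibitory ones. Self-connections are excluded at initialization; they can
#' appear later through structural plasticity.
#'
#' A fixed connection count (rather than independent Bernoulli draws) makes
#' the 20% initial density exact and seed-independent.
#'
#' @param params A [network_params()] object.
#' @param seed Integer seed; identical params + seed give a bit-identical
#'   network.
#' @param np A [neuron_params()] object (supplies E_L).
#' @param pp A [plasticity_params()] object (supplies U).
#' @return An object of class `network_state`: a list with the simulation
#'   clock `t` (ms), vectors `V` (mV), `w` (pA), `u`, `x`, `I_syn` (pA),
#'   `last_spike` (ms, `NA` if the unit never fired), logical `is_excitatory`,
#'   dense matrices `J` (signed efficacy) and `C` (0/1 connectivity), and the
#'   originating parameter blocks.
#' @examples
#' st <- build_network(network_params(), seed = 1)
#' sum(st$C)            # 49900 connections at the default 20% density
#' @export
build_network <- function(params = network_params(), seed = 1L,
                          np = neuron_params(), pp = plasticity_params()) {
  validate_network_params(params)
  if (length(seed) != 1 || is.na(seed))
    stop("build_network: seed must be a single integer", call. = FALSE)
  N <- params$N_E + params$N_I
  n_conn <- round(params$c_prob * N * (N - 1))

  withr::local_seed(as.integer(seed))
  is_excitatory <- rep(FALSE, N)
  is_excitatory[sample.int(N, params$N_E)] <- TRUE

  ## Ordered off-diagonal pairs, sampled without replacement by linear index
  ## over the N*(N-1) admissible cells.
  idx <- sample.int(N * (N - 1L), n_conn)
  pre <- (idx - 1L) %/% (N - 1L) + 1L          # presynaptic unit (column)
  post <- (idx - 1L) %% (N - 1L) + 1L          # postsynaptic slot, skip diag
  post <- post + (post >= pre)                 # shift over the diagonal

  C <- matrix(0L, N, N)
  C[cbind(post, pre)] <- 1L
  J <- matrix(0, N, N)
  exc_pre <- is_excitatory[pre]
  exc_post <- is_excitatory[post]
  Jval <- ifelse(exc_pre,
                 ifelse(exc_post, params$J_EE, params$J_IE),
                 ifelse(exc_post, params$J_EI, params$J_II))
  J[cbind(post, pre)] <- Jval

  st <- list(t = 0,
             V = rep(np$E_L, N),
             w = rep(0, N),
             u = rep(pp$U, N),
             x = rep(1, N),
             I_syn = rep(0, N),
             last_spike = rep(NA_real_, N),
             is_excitatory = is_excitatory,
             J = J, C = C,
             params = params, np = np, pp = pp)
  class(st) <- "network_state"
  st
}

#' Connectivity summary statistics
#'
#' Density over ordered off-diagonal pairs, E/I counts, the number of
#' self-connections, and the number of Dale-law violations (synapses whose
#' sign contradicts the presynaptic unit's class). A freshly built network has
#' density `c`, no self-connections and no violations; structural plasticity
#' during a run can introduce both.
#'
#' @param state A `network_state`.
#' @return A list with `density`, `n_connections`, `n_E`, `n_I`,
#'   `n_self_connections`, `n_dale_violations`.
#' @export
connection_stats <- function(state) {
  N <- nrow(state$C)
  total <- sum(state$C)
  ## A violation is a present synapse whose weight sign is impossible for the
  ## presynaptic class: negative weight from an E unit, positive from an I
  ## unit. Zero-weight synapses (e.g. freshly formed) violate nothing.
  exc_pre <- matrix(state$is_excitatory, N, N, byrow = TRUE)
  viol <- state$C == 1L &
    ((exc_pre & state$J < 0) | (!exc_pre & state$J > 0))
  list(density = total / (N * (N - 1)),
       n_connections = total,
       n_E = sum(state$is_excitatory),
       n_I = sum(!state$is_excitatory),
       n_self_connections = sum(diag(state$C)),
       n_dale_violations = sum(viol))
}
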