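## Parameter blocks. Internal unit system: mV, ms, pA, nS, pF (pF*mV/ms = pA).
## Figure/table values quoted in nA are converted to pA (x1000) at this boundary.

#' Network architecture parameters
#'
#' Connection probability, population sizes and the four initial efficacy
#' classes of the embodied network. Defaults are the published network table:
#' 400 excitatory and 100 inhibitory units, 20% initial connectivity,
#' excitatory efferents at 0.65 and inhibitory efferents at -1.
#'
#' @param c_prob Initial probability of synaptic contact, in (0, 1].
#' @param N_E Number of excitatory units.
#' @param N_I Number of inhibitory units.
#' @param J_EE,J_IE Initial efficacy of excitatory efferents onto E and I
#'   targets (dimensionless, >= 0).
#' @param J_II,J_EI Initial efficacy of inhibitory efferents onto I and E
#'   targets (dimensionless, <= 0).
#' @return An object of class `network_params`.
#' @examples
#' p <- network_params()
#' p$N_E + p$N_I
#' @export
network_params <- function(c_prob = 0.2, N_E = 400L, N_I = 100L,
                           J_EE = 0.65, J_IE = 0.65,
                           J_II = -1, J_EI = -1) {
  p <- list(c_prob = c_prob, N_E = as.integer(N_E), N_I = as.integer(N_I),
            J_EE = J_EE, J_IE = J_IE, J_II = J_II, J_EI = J_EI)
  class(p) <- "network_params"
  validate_network_params(p)
  p
}

validate_network_params <- function(p) {
  stop_cfg <- function(msg) stop("network_params: ", msg, call. = FALSE)
  if (!is.numeric(p$c_prob) || length(p$c_prob) != 1 ||
      is.na(p$c_prob) || p$c_prob <= 0 || p$c_prob > 1)
    stop_cfg("c_prob must lie in (0, 1]")
  for (nm in c("N_E", "N_I")) {
    v <- p[[nm]]
    if (length(v) != 1 || is.na(v) || v != as.integer(v) || v <= 0)
      stop_cfg(sprintf("%s must be a positive integer", nm))
  }
  if (p$J_EE < 0 || p$J_IE < 0)
    stop_cfg("excitatory efferent efficacies J_EE, J_IE must be >= 0")
  if (p$J_II > 0 || p$J_EI > 0)
    stop_cfg("inhibitory efferent efficacies J_II, J_EI must be <= 0")
  invisible(p)
}

#' Single-unit aEIF parameters
#'
#' Membrane and adaptation parameters of the adaptive exponential
#' integrate-and-fire unit, plus the synaptic current decay constant. Defaults
#' are the standard regular-spiking cortical set used throughout the model
#' (C_m = 281 pF, g_L = 30 nS, E_L = -70.6 mV, V_T = -50.4 mV, Delta_T = 2 mV,
#' V_peak = 20 mV, tau_w = 144 ms, a_w = 4 nS, b_w = 0.0805 nA, tau_syn = 5 ms).
#' The reset potential equals `E_L` by definition.
#'
#' @param C_m Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Resting (and reset) potential (mV).
#' @param V_T Spike-initiation threshold (mV).
#' @param V_peak Value recorded at a spike (mV); cosmetic, not integrated.
#' @param Delta_T Slope factor of the exponential term (mV).
#' @param tau_w Adaptation time constant (ms).
#' @param a_w Subthreshold adaptation conductance (nS).
#' @param b_w Spike-triggered adaptation increment (pA; 80.5 pA = 0.0805 nA).
#' @param tau_syn Postsynaptic current decay time constant (ms).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 281, g_L = 30, E_L = -70.6, V_T = -50.4,
                          V_peak = 20, Delta_T = 2, tau_w = 144, a_w = 4,
                          b_w = 80.5, tau_syn = 5) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, V_T = V_T, V_peak = V_peak,
            Delta_T = Delta_T, tau_w = tau_w, a_w = a_w, b_w = b_w,
            tau_syn = tau_syn)
  class(p) <- "neuron_params"
  for (nm in c("C_m", "g_L", "Delta_T", "tau_w", "a_w", "b_w", "tau_syn"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("neuron_params: ", nm, " must be strictly positive", call. = FALSE)
  if (p$V_peak <= p$V_T)
    stop("neuron_params: V_peak must exceed V_T", call. = FALSE)
  p
}

#' Short- and long-term plasticity parameters
#'
#' Tsodyks-Markram short-term plasticity (facilitation variable u, resource
#' variable x) and the multiplicative nearest-neighbour STDP rule. Defaults are
#' the published depression-dominated set: tau_f = 100 ms, tau_d = 900 ms,
#' U = 0.80; tau_+ = 20 ms, tau_- = 50 ms, lambda_+ = 5e-5, lambda_- = 25e-5,
#' mu = 1, alpha = 2. `g_scale` converts dimensionless efficacy into current:
#' one unit of efficacy times one unit of release injects `g_scale` pA.
#'
#' @param tau_f Facilitation time constant (ms).
#' @param tau_d Depression recovery time constant (ms).
#' @param U Baseline release probability, in [0, 1].
#' @param tau_plus,tau_minus STDP window constants for LTP/LTD (ms);
#'   the published rule has `tau_minus > tau_plus`.
#' @param lambda_plus,lambda_minus LTP/LTD learning rates (dimensionless).
#' @param mu Weight-dependence exponent of the multiplicative soft bounds.
#' @param alpha LTD/LTP asymmetry factor (> 1 favours LTD).
#' @param g_scale Current per unit efficacy and unit release (pA); default
#'   2000 pA, calibrated so that a handful (3-4) of coincident excitatory
#'   spikes at the network's *operating* efficacies (J of order 0.1 under the
#'   depression-dominated STDP rule) is suprathreshold from rest. See the
#'   methods vignette.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(tau_f = 100, tau_d = 900, U = 0.80,
                              tau_plus = 20, tau_minus = 50,
                              lambda_plus = 5e-5, lambda_minus = 25e-5,
                              mu = 1, alpha = 2, g_scale = 2000) {
  p <- list(tau_f = tau_f, tau_d = tau_d, U = U, tau_plus = tau_plus,
            tau_minus = tau_minus, lambda_plus = lambda_plus,
            lambda_minus = lambda_minus, mu = mu, alpha = alpha,
            g_scale = g_scale)
  class(p) <- "plasticity_params"
  if (p$U < 0 || p$U > 1)
    stop("plasticity_params: U must lie in [0, 1]", call. = FALSE)
  for (nm in c("tau_f", "tau_d", "tau_plus", "tau_minus", "mu", "g_scale"))
    if (p[[nm]] <= 0)
      stop("plasticity_params: ", nm, " must be strictly positive",
           call. = FALSE)
  if (p$lambda_plus <= 0 || p$lambda_plus >= 1 ||
      p$lambda_minus <= 0 || p$lambda_minus >= 1)
    stop("plasticity_params: learning rates must lie in (0, 1)", call. = FALSE)
  p
}

#' Sensory stimulus parameters
#'
#' Bimodal mixture-of-Gaussians input current on the ring of unit indices.
#' Defaults: R_b = 0.5 nA baseline, R_p = 2.5 nA higher peak, R_n = 1.0 nA
#' lower peak, sigma = 35 index units, N = 500. `intensity_scale` multiplies
#' the whole profile (the distractor protocol uses 1/3).
#'
#' @param R_b Baseline amplitude (nA).
#' @param R_p Higher peak amplitude (nA).
#' @param R_n Lower peak amplitude (nA).
#' @param sigma Tuning width (unit-index units).
#' @param N Number of units on the ring.
#' @param intensity_scale Multiplicative factor on the whole profile.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(R_b = 0.5, R_p = 2.5, R_n = 1.0, sigma = 35,
                            N = 500L, intensity_scale = 1) {
  p <- list(R_b = R_b, R_p = R_p, R_n = R_n, sigma = sigma, N = as.integer(N),
            intensity_scale = intensity_scale)
  class(p) <- "stimulus_params"
  if (!(p$R_p > p$R_n) || p$R_n < 0 || p$R_b < 0)
    stop("stimulus_params: require R_p > R_n >= 0 and R_b >= 0", call. = FALSE)
  if (p$sigma <= 0) stop("stimulus_params: sigma must be > 0", call. = FALSE)
  if (p$N <= 0) stop("stimulus_params: N must be positive", call. = FALSE)
  if (p$intensity_scale < 0)
    stop("stimulus_params: intensity_scale must be >= 0", call. = FALSE)
  p
}

#' Motor decoder parameters
#'
#' Spike counts in consecutive non-overlapping 40 ms bins are mapped to wheel
#' speeds: subpopulation 1 (units 1-250) drives the left wheel, subpopulation 2
#' (units 251-500) the right wheel, so a bump at unit 125 turns the agent
#' clockwise. `gain` and `wheelbase` set the physical scale only; no
#' qualitative result depends on them.
#'
#' @param bin_width Bin width (ms).
#' @param gain Wheel speed per spike (mm/s per spike in a bin).
#' @param left_units,right_units 1-based unit index vectors feeding the left
#'   and right wheel; must be disjoint.
#' @param wheelbase Distance between wheels (mm).
#' @param margin Relative spike-count margin below which neither subpopulation
#'   is called dominant (tie band), as a fraction of the total count.
#' @param min_spikes Minimum total spike count in a window for a dominance
#'   call; below it the readout is `"NONE"` (a near-silent network moves the
#'   agent too little for a behavioural readout).
#' @return An object of class `decoder_params`.
#' @export
decoder_params <- function(bin_width = 40, gain = 0.5,
                           left_units = 1:250, right_units = 251:500,
                           wheelbase = 48, margin = 0.05, min_spikes = 20) {
  p <- list(bin_width = bin_width, gain = gain,
            left_units = as.integer(left_units),
            right_units = as.integer(right_units),
            wheelbase = wheelbase, margin = margin,
            min_spikes = min_spikes)
  class(p) <- "decoder_params"
  if (p$bin_width <= 0 || p$gain <= 0 || p$wheelbase <= 0)
    stop("decoder_params: bin_width, gain, wheelbase must be > 0",
         call. = FALSE)
  if (length(intersect(p$left_units, p$right_units)) > 0)
    stop("decoder_params: wheel unit ranges must be disjoint", call. = FALSE)
  if (p$margin < 0 || p$margin >= 1)
    stop("decoder_params: margin must lie in [0, 1)", call. = FALSE)
  p
}
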