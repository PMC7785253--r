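## Sensory input generation: bimodal Gaussian currents on the unit-index
## ring, frozen Poisson background trains, and the event schedules that stand
## in for the keyboard (<Left>/<Right>/<Enter>) of the original interactive
## protocol.

ring_gaussian <- function(i, centre, sigma, N) {
  d <- abs(i - centre)
  d <- pmin(d, N - d)                  # indices are circular
  exp(-d^2 / (2 * sigma^2))
}

#' Bimodal external input current
#'
#' The evoked input is a baseline plus two Gaussians of unequal amplitude
#' placed half a ring apart: the higher peak `R_p` sits at the preferred unit
#' of the selected configuration, the lower peak `R_n` at the diametrically
#' opposite unit. `"RIGHT"` (clockwise) centres the higher peak on unit 125,
#' `"LEFT"` (counter-clockwise) on unit 375; `"OFF"` returns zeros. The two
#' evoked configurations are exact ring-swap images of each other and share
#' the same mean intensity.
#'
#' @param config One of `"LEFT"`, `"RIGHT"`, `"OFF"`.
#' @param sp A [stimulus_params()] object.
#' @return Numeric vector of per-unit currents in nA (length `sp$N`).
#' @examples
#' which.max(bimodal_input("RIGHT", stimulus_params()))  # 125
#' @export
bimodal_input <- function(config = c("OFF", "LEFT", "RIGHT"),
                          sp = stimulus_params()) {
  config <- match.arg(config)
  N <- sp$N
  if (config == "OFF") return(rep(0, N))
  i_pref <- if (config == "RIGHT") 125L else 375L
  if (N != 500L) i_pref <- if (config == "RIGHT")
    as.integer(round(N / 4)) else as.integer(round(3 * N / 4))
  i_anti <- (i_pref + N %/% 2L - 1L) %% N + 1L
  i <- seq_len(N)
  I <- sp$R_b +
    sp$R_p * ring_gaussian(i, i_pref, sp$sigma, N) +
    sp$R_n * ring_gaussian(i, i_anti, sp$sigma, N)
  sp$intensity_scale * I
}

#' Frozen Poisson background trains
#'
#' One independent homogeneous Poisson spike train per presynaptic unit at
#' rate `rate` Hz, drawn once up front and reused unchanged for the whole run
#' ("frozen noise"): the same realization drives both evoked and spontaneous
#' phases. Identical seeds reproduce identical trains.
#'
#' @param N Number of units.
#' @param rate Rate in Hz (spikes per second per unit).
#' @param horizon Run length in ms.
#' @param seed Integer seed.
#' @return An object of class `background_noise`: list with `trains` (per-unit
#'   sorted spike-time vectors, ms), `rate`, `horizon`, `seed`.
#' @export
make_background <- function(N, rate, horizon, seed = 1L) {
  if (rate < 0) stop("make_background: rate must be >= 0", call. = FALSE)
  if (horizon <= 0) stop("make_background: horizon must be > 0", call. = FALSE)
  withr::local_seed(as.integer(seed))
  trains <- vector("list", N)
  for (j in seq_len(N)) {
    n <- stats::rpois(1, rate * horizon / 1000)
    trains[[j]] <- sort(stats::runif(n, 0, horizon))
  }
  structure(list(trains = trains, rate = rate, horizon = horizon,
                 seed = as.integer(seed)),
            class = "background_noise")
}

#' Empirical grand mean rate of a background object
#'
#' Total spike count divided by `N * horizon`; used to check the Poisson
#' generator against its nominal rate.
#'
#' @param bg A `background_noise` object.
#' @return Rate in Hz.
#' @export
background_rate <- function(bg) {
  total <- sum(vapply(bg$trains, length, integer(1)))
  1000 * total / (length(bg$trains) * bg$horizon)
}

#' Event schedule constructor
#'
#' @param time_ms Strictly increasing event times (ms), first at >= 0.
#' @param event Character vector of `"STIM_LEFT"`, `"STIM_RIGHT"`,
#'   `"STIM_OFF"`.
#' @param horizon End of the run (ms); defaults to the last event time plus
#'   the mean inter-event gap.
#' @param intensity_scale Per-event multiplicative intensity factor
#'   (default 1 for every event); the distractor protocol uses 1/3.
#' @return A data.frame of class `event_schedule` with columns `time_ms`,
#'   `event`, `intensity_scale`, and attribute `horizon`.
#' @export
event_schedule <- function(time_ms, event, horizon = NULL,
                           intensity_scale = rep(1, length(time_ms))) {
  ok <- c("STIM_LEFT", "STIM_RIGHT", "STIM_OFF")
  if (!all(event %in% ok))
    stop("event_schedule: unknown event type", call. = FALSE)
  if (length(time_ms) != length(event))
    stop("event_schedule: times and events must align", call. = FALSE)
  if (length(time_ms) == 0 || time_ms[1] < 0 ||
      any(diff(time_ms) <= 0))
    stop("event_schedule: times must be strictly increasing, first >= 0",
         call. = FALSE)
  if (is.null(horizon))
    horizon <- time_ms[length(time_ms)] +
      max(mean(diff(c(0, time_ms))), 1000)
  sched <- data.frame(time_ms = as.numeric(time_ms), event = event,
                      intensity_scale = intensity_scale,
                      stringsAsFactors = FALSE)
  attr(sched, "horizon") <- horizon
  class(sched) <- c("event_schedule", "data.frame")
  sched
}

#' Canonical schedules for the six working-memory protocols
#'
#' Builds the deterministic event schedule of each protocol. Durations are
#' configuration choices (the original experiments were driven live by an
#' operator); the defaults keep each run within about a minute of simulated
#' time while preserving each protocol's defining ordering:
#' \describe{
#'   \item{exp1}{single learning and recall: one cue, then stimulus off.}
#'   \item{exp2}{incremental learning: repeated (cue, off) pairs with
#'     monotonically lengthening cues.}
#'   \item{exp3}{task switching: alternating LEFT/RIGHT cues of equal
#'     duration with off gaps.}
#'   \item{exp4}{interference resistance: long cue, off, brief opposite
#'     interferer, off.}
#'   \item{exp5}{interference submission: cue, extended off (washout), brief
#'     opposite interferer, off.}
#'   \item{exp6}{distraction resistance: cue, off, opposite distractor of
#'     similar duration at one third of the cue intensity, off.}
#' }
#'
#' @param name `"exp1"` ... `"exp6"`.
#' @param durations Named list overriding any of `cue` (ms, default 20000),
#'   `recall` (10000), `interferer` (4000), `washout` (60000),
#'   `distractor_scale` (1/3), `n_increments` (3 for exp2),
#'   `n_switches` (1 for exp3).
#' @return An `event_schedule`.
#' @export
schedule_for_experiment <- function(name, durations = list()) {
  d <- utils::modifyList(list(cue = 20000, recall = 10000, interferer = 4000,
                              washout = 60000, distractor_scale = 1 / 3,
                              n_increments = 3L, n_switches = 1L),
                         durations)
  if (any(unlist(d[c("cue", "recall", "interferer", "washout")]) <= 0))
    stop("schedule_for_experiment: durations must be positive", call. = FALSE)
  add <- function(acc, dur, ev, sc = 1) {
    t0 <- if (nrow(acc)) acc$end[nrow(acc)] else 0
    rbind(acc, data.frame(start = t0, end = t0 + dur, ev = ev, sc = sc))
  }
  seg <- data.frame(start = numeric(), end = numeric(), ev = character(),
                    sc = numeric())
  seg <- switch(name,
    exp1 = {
      s <- add(seg, d$cue, "STIM_LEFT")
      add(s, d$recall, "STIM_OFF")
    },
    exp2 = {
      s <- seg
      for (k in seq_len(d$n_increments)) {
        s <- add(s, d$cue * k / d$n_increments, "STIM_LEFT")
        s <- add(s, d$recall, "STIM_OFF")
      }
      s
    },
    exp3 = {
      s <- seg
      sides <- rep(c("STIM_LEFT", "STIM_RIGHT"), length.out = d$n_switches + 1)
      for (ev in sides) {
        s <- add(s, d$cue, ev)
        s <- add(s, d$recall, "STIM_OFF")
      }
      s
    },
    exp4 = {
      s <- add(seg, d$cue, "STIM_LEFT")
      s <- add(s, d$recall, "STIM_OFF")
      s <- add(s, d$interferer, "STIM_RIGHT")
      add(s, d$recall, "STIM_OFF")
    },
    exp5 = {
      s <- add(seg, d$cue, "STIM_LEFT")
      s <- add(s, d$washout, "STIM_OFF")
      s <- add(s, d$interferer, "STIM_RIGHT")
      add(s, d$recall, "STIM_OFF")
    },
    exp6 = {
      s <- add(seg, d$cue, "STIM_LEFT")
      s <- add(s, d$recall, "STIM_OFF")
      s <- add(s, d$cue, "STIM_RIGHT", sc = d$distractor_scale)
      add(s, d$recall, "STIM_OFF")
    },
    stop("schedule_for_experiment: unknown experiment '", name, "'",
         call. = FALSE)
  )
  event_schedule(seg$start, seg$ev, horizon = seg$end[nrow(seg)],
                 intensity_scale = seg$sc)
}

## Expand a schedule into phase segments (start, end, event, scale).
schedule_phases <- function(sched) {
  horizon <- attr(sched, "horizon")
  n <- nrow(sched)
  data.frame(start = sched$time_ms,
             end = c(sched$time_ms[-1], horizon),
             event = sched$event,
             intensity_scale = sched$intensity_scale,
             stringsAsFactors = FALSE)
}
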