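## End-to-end protocol runs and their success criteria.
##
## Stimulus-to-subpopulation mapping: STIM_RIGHT centres the higher peak on
## unit 125, so the cued subpopulation for a RIGHT cue is the left-wheel
## subpopulation (units 1-250); STIM_LEFT cues the right-wheel subpopulation
## (units 251-500).

#' Subpopulation cued by a stimulus event
#'
#' @param event `"STIM_LEFT"` or `"STIM_RIGHT"`.
#' @return `"LEFT_SUBPOP"` or `"RIGHT_SUBPOP"`.
#' @export
cued_subpop <- function(event) {
  switch(event,
         STIM_RIGHT = "LEFT_SUBPOP",
         STIM_LEFT = "RIGHT_SUBPOP",
         stop("cued_subpop: not a cue event: ", event, call. = FALSE))
}

#' Run one working-memory protocol end to end
#'
#' Builds the protocol's schedule, simulates it, computes per-phase metrics
#' over the analysis window (the last `window_frac` of each phase, skipping
#' onset transients), and evaluates the protocol's success criterion.
#'
#' @param name `"exp1"` ... `"exp6"`.
#' @param seed Integer seed for the whole run.
#' @param durations Passed to [schedule_for_experiment()].
#' @param window_frac Fraction of each phase used as analysis window
#'   (default 0.25).
#' @param dp A [decoder_params()] object.
#' @param ... Further arguments to [run_simulation()] (parameter blocks,
#'   `dt`, feature switches, ...).
#' @return An object of class `wm_experiment`: the underlying `wm_run` plus
#'   `name`, `metrics` (per-phase data.frame), `verdict`
#'   (`"pass"`/`"fail"`/`"inconclusive"`), and `trajectory`.
#' @export
run_experiment <- function(name, seed = 42L, durations = list(),
                           window_frac = 0.25, dp = decoder_params(), ...) {
  sched <- schedule_for_experiment(name, durations)
  run <- run_simulation(sched, seed = seed, ...)
  metrics <- phase_metrics(run, window_frac = window_frac, dp = dp)
  speeds <- decode_wheel_speeds(run$spikes, dp,
                                horizon = run$phases$end[nrow(run$phases)])
  traj <- integrate_pose(speeds, dp)
  res <- c(run, list(name = name, metrics = metrics, trajectory = traj,
                     window_frac = window_frac, dp = dp))
  class(res) <- c("wm_experiment", "wm_run")
  res$verdict <- evaluate_experiment(res, name)
  res
}

#' Per-phase analysis metrics
#'
#' For each schedule phase: the analysis window (last `window_frac` of the
#' phase), mean firing rate of each subpopulation inside it (Hz), the mean
#' rate of the whole network over the entire phase, and the dominant
#' subpopulation in the window.
#'
#' @param run A `wm_run`.
#' @param window_frac Fraction of each phase analysed (from the end).
#' @param dp A [decoder_params()] object.
#' @return Data.frame with one row per phase.
#' @export
phase_metrics <- function(run, window_frac = 0.25, dp = decoder_params()) {
  ph <- run$phases
  N <- length(dp$left_units) + length(dp$right_units)
  out <- lapply(seq_len(nrow(ph)), function(k) {
    t0 <- ph$end[k] - window_frac * (ph$end[k] - ph$start[k])
    t1 <- ph$end[k]
    data.frame(
      phase = k, event = ph$event[k],
      start = ph$start[k], end = ph$end[k],
      win_start = t0, win_end = t1,
      rate_left = window_rate(run$spikes, dp$left_units, t0, t1),
      rate_right = window_rate(run$spikes, dp$right_units, t0, t1),
      rate_all_phase = window_rate(run$spikes, seq_len(N),
                                   ph$start[k], ph$end[k]),
      dominance = dominance(run$spikes, c(t0, t1), dp),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate a protocol's success criterion
#'
#' A pure function of the stored metrics, so verdicts can be recomputed
#' offline from a results directory:
#' \describe{
#'   \item{exp1}{recall dominance equals the cued side.}
#'   \item{exp2}{the cued-minus-uncued rate margin in successive recalls is
#'     non-decreasing in trend (Kendall tau >= 0) and the final recall is
#'     cue-dominant.}
#'   \item{exp3}{every recall's dominance equals the most recent cue.}
#'   \item{exp4}{the post-interference recall stays cue-dominant.}
#'   \item{exp5}{precondition: the washout ends in the tie band (otherwise
#'     `"inconclusive"`); then the post-interferer recall is dominated by the
#'     interferer side.}
#'   \item{exp6}{recalls before and after the weak distractor are both
#'     cue-dominant.}
#' }
#'
#' @param res A `wm_experiment` (or any list with `$metrics` laid out as in
#'   [phase_metrics()]).
#' @param name `"exp1"` ... `"exp6"`.
#' @return `"pass"`, `"fail"`, or `"inconclusive"`.
#' @export
evaluate_experiment <- function(res, name = res$name) {
  m <- res$metrics
  cue_events <- c("STIM_LEFT", "STIM_RIGHT")
  is_off <- m$event == "STIM_OFF"
  last_cue_before <- function(k) {
    prev <- which(m$event %in% cue_events & seq_len(nrow(m)) < k)
    if (!length(prev)) NA_character_ else m$event[max(prev)]
  }
  pass <- function(ok) if (isTRUE(ok)) "pass" else "fail"
  switch(name,
    exp1 = {
      k <- which(is_off)[1]
      pass(m$dominance[k] == cued_subpop(last_cue_before(k)))
    },
    exp2 = {
      offs <- which(is_off)
      side <- cued_subpop(last_cue_before(offs[1]))
      sgn <- if (side == "LEFT_SUBPOP") 1 else -1
      margin <- sgn * (m$rate_left[offs] - m$rate_right[offs])
      tau <- if (length(offs) < 2) 1 else
        suppressWarnings(stats::cor(seq_along(offs), margin,
                                    method = "kendall"))
      if (is.na(tau)) tau <- 0    # all margins equal: flat trend
      pass(tau >= 0 && m$dominance[offs[length(offs)]] == side)
    },
    exp3 = {
      offs <- which(is_off)
      ok <- vapply(offs, function(k)
        m$dominance[k] == cued_subpop(last_cue_before(k)), logical(1))
      pass(all(ok))
    },
    exp4 = {
      k <- max(which(is_off))
      cue <- m$event[which(m$event %in% cue_events)[1]]
      pass(m$dominance[k] == cued_subpop(cue))
    },
    exp5 = {
      offs <- which(is_off)
      washout <- offs[1]
      if (m$dominance[washout] != "NONE") return("inconclusive")
      interferer <- m$event[max(which(m$event %in% cue_events))]
      pass(m$dominance[offs[length(offs)]] == cued_subpop(interferer))
    },
    exp6 = {
      offs <- which(is_off)
      cue <- m$event[which(m$event %in% cue_events)[1]]
      pass(all(m$dominance[offs] == cued_subpop(cue)))
    },
    stop("evaluate_experiment: unknown experiment '", name, "'",
         call. = FALSE)
  )
}

#' Run a protocol over several seeds
#'
#' The published runs are single embodied sessions; running a small fixed
#' seed set quantifies robustness. The battery verdict is `"pass"` when the
#' criterion is met on at least `min_pass` of the seeds.
#'
#' @param name `"exp1"` ... `"exp6"`.
#' @param seeds Integer vector of seeds (default 41, 42, 43).
#' @param min_pass Minimum number of passing seeds (default 2).
#' @param ... Passed to [run_experiment()].
#' @return List with `verdict`, `per_seed` (named verdict vector), and the
#'   individual `wm_experiment` objects in `runs`.
#' @export
experiment_battery <- function(name, seeds = c(41L, 42L, 43L), min_pass = 2L,
                               ...) {
  runs <- lapply(seeds, function(s) run_experiment(name, seed = s, ...))
  per_seed <- vapply(runs, `[[`, character(1), "verdict")
  names(per_seed) <- as.character(seeds)
  list(verdict = if (sum(per_seed == "pass") >= min_pass) "pass" else "fail",
       per_seed = per_seed, runs = runs)
}

#' @export
print.wm_experiment <- function(x, ...) {
  cat("<wm_experiment> ", x$name, ", seed ", x$seed, ": ", x$verdict,
      "\n", sep = "")
  print(x$metrics[, c("event", "rate_left", "rate_right", "dominance")])
  invisible(x)
}
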