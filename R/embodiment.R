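## Spike-to-motor decoding and virtual differential-drive kinematics.
## Subpopulation 1 (units 1-250, higher peak at unit 125 under the clockwise
## configuration) drives the left wheel; subpopulation 2 (units 251-500,
## peak 375) drives the right wheel. A faster left wheel turns the agent
## clockwise, which is the unique wheel assignment consistent with "preferred
## unit 125 for clockwise rotations".

#' Decode per-bin wheel speeds from a spike record
#'
#' Spike counts of each wheel's subpopulation in consecutive non-overlapping
#' bins (default 40 ms, half-open `[t, t + bin)`, anchored at t = 0) are
#' multiplied by `gain`; the speed holds constant within each bin until the
#' next bin's count commands a new one.
#'
#' @param spikes Data.frame with columns `t_ms`, `unit` (sorted by time).
#' @param dp A [decoder_params()] object.
#' @param horizon End of the decoded interval (ms); defaults to the last
#'   spike's bin.
#' @return Data.frame with `t_ms` (bin start), `v_left`, `v_right` (mm/s).
#' @export
decode_wheel_speeds <- function(spikes, dp = decoder_params(),
                                horizon = NULL) {
  if (is.null(horizon))
    horizon <- if (nrow(spikes)) max(spikes$t_ms) + dp$bin_width else
      dp$bin_width
  n_bins <- ceiling(horizon / dp$bin_width)
  breaks <- seq(0, n_bins * dp$bin_width, by = dp$bin_width)
  count_in <- function(units) {
    sel <- spikes$unit %in% units
    ## right-open bins: a spike exactly on a boundary joins the later bin
    idx <- findInterval(spikes$t_ms[sel], breaks, left.open = FALSE,
                        rightmost.closed = FALSE)
    tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  }
  data.frame(t_ms = breaks[-length(breaks)],
             v_left = dp$gain * count_in(dp$left_units),
             v_right = dp$gain * count_in(dp$right_units))
}

#' Integrate the planar pose from per-bin wheel speeds
#'
#' Standard differential-drive kinematics with exact arc integration inside
#' each constant-speed bin: linear velocity `(v_l + v_r) / 2`, angular
#' velocity `(v_r - v_l) / wheelbase`. Positive heading change is
#' counter-clockwise; a dominant left wheel therefore decreases the heading
#' (clockwise turn).
#'
#' @param speeds Data.frame from [decode_wheel_speeds()].
#' @param dp A [decoder_params()] object.
#' @param x0,y0,heading0 Initial pose (mm, mm, radians).
#' @return Data.frame with `t_ms`, `v_left`, `v_right`, `x`, `y`, `heading`
#'   (pose at the *end* of each bin).
#' @export
integrate_pose <- function(speeds, dp = decoder_params(),
                           x0 = 0, y0 = 0, heading0 = 0) {
  n <- nrow(speeds)
  x <- y <- th <- numeric(n)
  dt_s <- dp$bin_width / 1000
  cx <- x0; cy <- y0; cth <- heading0
  for (k in seq_len(n)) {
    v <- (speeds$v_left[k] + speeds$v_right[k]) / 2
    om <- (speeds$v_right[k] - speeds$v_left[k]) / dp$wheelbase
    if (abs(om) < 1e-12) {
      cx <- cx + v * dt_s * cos(cth)
      cy <- cy + v * dt_s * sin(cth)
    } else {
      r <- v / om
      th_new <- cth + om * dt_s
      cx <- cx + r * (sin(th_new) - sin(cth))
      cy <- cy - r * (cos(th_new) - cos(cth))
      cth <- th_new
    }
    x[k] <- cx; y[k] <- cy; th[k] <- cth
  }
  cbind(speeds[, c("t_ms", "v_left", "v_right")],
        data.frame(x = x, y = y, heading = th))
}

#' Dominant subpopulation in a window
#'
#' The behavioural readout used by every protocol's success criterion: the
#' subpopulation with the strictly greater total spike count over
#' `(t0, t1]`. Returns `"NONE"` when the counts differ by less than
#' `margin` of their sum (tie band) or when fewer than `min_spikes` spikes
#' fell in the window at all.
#'
#' @param spikes Data.frame with `t_ms`, `unit`.
#' @param window Numeric `c(t0, t1)` in ms.
#' @param dp A [decoder_params()] object.
#' @return `"LEFT_SUBPOP"`, `"RIGHT_SUBPOP"`, or `"NONE"`.
#' @export
dominance <- function(spikes, window, dp = decoder_params()) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("dominance: window must be (t0, t1) with t1 > t0", call. = FALSE)
  sel <- spikes$t_ms > window[1] & spikes$t_ms <= window[2]
  nl <- sum(sel & spikes$unit %in% dp$left_units)
  nr <- sum(sel & spikes$unit %in% dp$right_units)
  if (nl + nr < dp$min_spikes ||
      abs(nl - nr) < dp$margin * (nl + nr)) return("NONE")
  if (nl > nr) "LEFT_SUBPOP" else "RIGHT_SUBPOP"
}

#' Circular mean bump position
#'
#' Count-weighted circular mean of spiking unit indices on the ring, over an
#' optional unit subset and window; quantifies where the activity bump sits.
#'
#' @param spikes Data.frame with `t_ms`, `unit`.
#' @param window Numeric `c(t0, t1)` in ms.
#' @param units Unit subset (default all of `1:N`).
#' @param N Ring size.
#' @return Unit index in `[1, N]` (real-valued).
#' @export
bump_center <- function(spikes, window, units = seq_len(N), N = 500L) {
  sel <- spikes$t_ms > window[1] & spikes$t_ms <= window[2] &
    spikes$unit %in% units
  if (!any(sel))
    stop("bump_center: no spikes in the window", call. = FALSE)
  counts <- table(spikes$unit[sel])
  idx <- as.integer(names(counts))
  ang <- 2 * pi * (idx - 1) / N
  m <- atan2(sum(counts * sin(ang)), sum(counts * cos(ang)))
  pos <- (m / (2 * pi)) %% 1 * N + 1
  if (pos > N + 0.5) pos <- pos - N
  pos
}
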