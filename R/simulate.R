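#' Stimulation protocol
#'
#' Either an explicit vector of stimulus times or a periodic train defined by
#' a frequency and a stimulus count (times `0, 1/f, 2/f, ...`).
#'
#' @param times Strictly increasing stimulus times (s), all >= 0.
#' @param frequency Stimulation frequency (Hz), used with `n`.
#' @param n Number of stimuli in the periodic train.
#' @return An object of class `"stimulus_protocol"` holding the times.
#' @examples
#' stimulus_protocol(frequency = 0.05, n = 3) # stimuli at 0, 20, 40 s
#' @export
stimulus_protocol <- function(times = NULL, frequency = NULL, n = NULL) {
  if (is.null(times)) {
    if (is.null(frequency) || is.null(n))
      stop("stimulus_protocol: give either 'times' or both 'frequency' and 'n'")
    if (frequency <= 0) stop("stimulus_protocol: 'frequency' must be > 0")
    if (n < 0 || n != round(n)) stop("stimulus_protocol: 'n' must be a count")
    times <- if (n == 0) numeric(0) else (seq_len(n) - 1) / frequency
  }
  if (length(times) > 0) {
    if (any(!is.finite(times)) || any(times < 0))
      stop("stimulus_protocol: times must be finite and >= 0")
    if (any(diff(times) <= 0))
      stop("stimulus_protocol: times must be strictly increasing")
  }
  structure(list(times = as.numeric(times)), class = "stimulus_protocol")
}

# Core explicit-Euler engine shared by simulate_ap() and recovery_time().
# Stimulus times are snapped to the nearest grid point. Returns the sampled
# trajectory matrix, the event table, and (optionally) stops early once the
# relative pressure has recovered past `stop_rel` with no excitation pending.
run_euler <- function(params, stim_times, t_end, stop_rel = NULL) {
  dt <- params$dt
  n_steps <- as.integer(round(t_end / dt))
  rtbar <- rt_bar_per_mM(params$rt_over_f)
  dp0 <- resting_pressure(params)
  press_factor <- 2 * rtbar * (params$alpha + 1) / params$alpha

  k_cell <- params$k_cell0; k_apo <- params$k_apo0
  a_cell <- params$a_cell0; a_apo <- params$a_apo0
  dp <- dp0
  excited_until <- -Inf

  stim_idx <- as.integer(round(stim_times / dt))
  if (any(stim_idx > n_steps))
    stop("run_euler: stimulus times must lie before 't_end'")
  ev_fired <- rep(NA, length(stim_idx))
  ev_rel <- rep(NA_real_, length(stim_idx))

  out <- matrix(NA_real_, n_steps + 1L, 7L)
  colnames(out) <- c("t", "k_cell", "k_apo", "a_cell", "a_apo", "dp", "trigger")
  out[1L, ] <- c(0, k_cell, k_apo, a_cell, a_apo, dp, 0)
  si <- 1L
  n_stim <- length(stim_idx)
  last_row <- n_steps + 1L

  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt
    # stimulus arriving at this grid point?
    while (si <= n_stim && stim_idx[si] == i - 1L) {
      rel <- dp / dp0
      ev_rel[si] <- rel
      if (t < excited_until) {
        # arrives during an ongoing excited phase: ignored non-event
        ev_fired[si] <- NA
      } else if (rel >= params$turgor_threshold) {
        excited_until <- t + params$excited_duration
        ev_fired[si] <- TRUE
      } else {
        ev_fired[si] <- FALSE
      }
      si <- si + 1L
    }
    trig <- as.numeric(t < excited_until)
    e_k <- params$rt_over_f * log(k_apo / k_cell)
    j <- params$k * (params$v_excited - e_k) * trig +
      min(0, params$k * params$beta * (params$v_rest - e_k + params$v0)) *
        (1 - trig)
    jdt <- j * dt
    k_cell <- k_cell - jdt; k_apo <- k_apo + jdt / params$alpha
    a_cell <- a_cell - jdt; a_apo <- a_apo + jdt / params$alpha
    if (min(k_cell, k_apo, a_cell, a_apo) < 0)
      stop("simulate: a concentration became negative at t = ", t + dt,
           " s; the time step 'dt' is too large for these parameters")
    dp <- dp - press_factor * jdt
    out[i + 1L, ] <- c(i * dt, k_cell, k_apo, a_cell, a_apo, dp,
                       as.numeric(i * dt < excited_until))
    if (!is.null(stop_rel) && si > n_stim && i * dt >= excited_until &&
        dp / dp0 >= stop_rel) {
      last_row <- i + 1L
      break
    }
  }
  list(states = out[seq_len(last_row), , drop = FALSE],
       events = data.frame(stimulus_time = stim_times,
                           fired = ev_fired,
                           rel_dp_at_stimulus = ev_rel),
       dp0 = dp0,
       recovered = !is.null(stop_rel) && last_row < n_steps + 1L)
}

#' Simulate trigger-hair action potentials
#'
#' Integrates the two-compartment ion/turgor model with explicit Euler steps
#' from the resting equilibrium. At each stimulus time the cell fires (the
#' membrane is held at `v_excited` for `excited_duration`) if and only if the
#' relative pressure difference is at or above the turgor threshold and the
#' cell is not already excited; sub-threshold stimuli are recorded as dropouts
#' (`fired = FALSE`), and stimuli arriving during an ongoing excited phase are
#' ignored non-events (`fired = NA`).
#'
#' @param params An [ap_params()] object.
#' @param protocol A [stimulus_protocol()], or a numeric vector of stimulus
#'   times (s).
#' @param t_end End time of the simulation (s); all stimuli must lie before
#'   it.
#' @return An object of class `"ap_trajectory"`: a list with `states` (a
#'   data frame with columns `t`, `k_cell`, `k_apo`, `a_cell`, `a_apo`, `dp`,
#'   `rel_dp`, `trigger`), `events` (one row per stimulus: `stimulus_time`,
#'   `fired`, `rel_dp_at_stimulus`), `params`, and the resting pressure
#'   `dp0` (bar).
#' @examples
#' traj <- simulate_ap(ap_params(), protocol = 0, t_end = 2)
#' tail(traj$states, 1)
#' @export
simulate_ap <- function(params, protocol = stimulus_protocol(times = numeric(0)),
                        t_end) {
  stopifnot(inherits(params, "ap_params"))
  if (is.numeric(protocol)) protocol <- stimulus_protocol(times = protocol)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (t_end <= 0) stop("simulate_ap: 't_end' must be > 0")
  if (length(protocol$times) > 0 && max(protocol$times) >= t_end)
    stop("simulate_ap: all stimulus times must lie before 't_end'")
  res <- run_euler(params, protocol$times, t_end)
  states <- as.data.frame(res$states)
  states$rel_dp <- states$dp / res$dp0
  states <- states[, c("t", "k_cell", "k_apo", "a_cell", "a_apo",
                       "dp", "rel_dp", "trigger")]
  structure(list(states = states, events = res$events,
                 params = params, dp0 = res$dp0),
            class = "ap_trajectory")
}

#' @export
print.ap_trajectory <- function(x, ...) {
  n_ev <- nrow(x$events)
  cat(sprintf(
    "Trigger-hair trajectory: %d samples over %.6g s, %d stimuli (%d fired)\n",
    nrow(x$states), max(x$states$t), n_ev, sum(x$events$fired %in% TRUE)))
  cat(sprintf("  resting dP0 = %.4g bar; final relative dP = %.3f\n",
              x$dp0, x$states$rel_dp[nrow(x$states)]))
  invisible(x)
}

#' Summary of a single simulated action potential
#'
#' Runs one stimulus from rest and reports the concentration and pressure
#' changes at the end of the excited phase: the percent decrease of cytosolic
#' K+, the apoplastic K+ both as percent of its initial value and as percent
#' increment, and the percent decrease of the pressure difference.
#'
#' @param params An [ap_params()] object.
#' @return A named numeric vector with elements `k_cell_decrease_pct`,
#'   `k_apo_final_pct_of_initial`, `k_apo_increment_pct`, and
#'   `dp_decrease_pct`.
#' @export
single_ap_summary <- function(params = ap_params()) {
  traj <- simulate_ap(params, protocol = 0,
                      t_end = params$excited_duration + params$dt)
  idx <- which.min(abs(traj$states$t - params$excited_duration))
  s <- traj$states[idx, ]
  c(k_cell_decrease_pct = 100 * (params$k_cell0 - s$k_cell) / params$k_cell0,
    k_apo_final_pct_of_initial = 100 * s$k_apo / params$k_apo0,
    k_apo_increment_pct = 100 * (s$k_apo - params$k_apo0) / params$k_apo0,
    dp_decrease_pct = 100 * (traj$dp0 - s$dp) / traj$dp0)
}

#' Time to full turgor recovery after one action potential
#'
#' Simulates a single stimulus from rest and returns the elapsed time from the
#' end of the excited phase until the relative pressure difference first
#' reaches `1 - tol`. Because the uptake flux scales linearly with `beta`,
#' reducing `beta` c-fold stretches the recovery c-fold (up to one Euler
#' step), which is how channel block slows the cell's reset.
#'
#' @param params An [ap_params()] object.
#' @param tol Recovery tolerance: recovery is declared at relative pressure
#'   `>= 1 - tol`. Default 0.01 (99% of resting).
#' @param t_cap Time cap (s); an error is raised if the trajectory has not
#'   recovered by then.
#' @return Recovery time in seconds.
#' @export
recovery_time <- function(params = ap_params(), tol = 0.01, t_cap = 50000) {
  stopifnot(inherits(params, "ap_params"))
  if (tol <= 0 || tol >= 1) stop("recovery_time: 'tol' must be in (0, 1)")
  res <- run_euler(params, stim_times = 0, t_end = t_cap, stop_rel = 1 - tol)
  if (!res$recovered)
    stop("recovery_time: relative pressure did not reach ", 1 - tol,
         " within ", t_cap, " s; increase 't_cap'")
  t_rec <- unname(res$states[nrow(res$states), "t"])
  t_rec - params$excited_duration
}

#' Steady operating range of relative turgor under periodic stimulation
#'
#' Runs a periodic stimulus train, discards the transient (the first
#' `max(10, floor(n_stimuli/2))` cycles), and returns the extrema of the
#' relative pressure difference (percent of resting) over the final complete
#' cycle. Convergence to a periodic regime is declared when the extrema of
#' the last two cycles differ by less than 0.1 percentage point; otherwise a
#' warning is raised. At the published defaults and 0.05 Hz the cell settles
#' into a band of roughly 51% to 61% of the resting pressure.
#'
#' @param params An [ap_params()] object.
#' @param frequency Stimulation frequency (Hz).
#' @param n_stimuli Number of stimuli (>= 2); enough to pass the transient.
#' @return A list with `range` (named vector `min`, `max`, percent of
#'   resting), `converged`, and `dropout_in_final_cycle`.
#' @export
operating_range <- function(params = ap_params(), frequency = 0.05,
                            n_stimuli = 60) {
  if (frequency <= 0) stop("operating_range: 'frequency' must be > 0")
  if (n_stimuli < 2) stop("operating_range: need at least 2 stimuli")
  period <- 1 / frequency
  prot <- stimulus_protocol(frequency = frequency, n = n_stimuli)
  t_end <- n_stimuli * period
  traj <- simulate_ap(params, prot, t_end)
  rel <- traj$states$rel_dp * 100
  t <- traj$states$t
  cyc_extrema <- function(i) { # extrema over cycle i (1-based)
    sel <- t >= (i - 1) * period & t < i * period
    c(min(rel[sel]), max(rel[sel]))
  }
  last <- cyc_extrema(n_stimuli)
  prev <- cyc_extrema(n_stimuli - 1)
  converged <- all(abs(last - prev) < 0.1)
  if (!converged)
    warning("operating_range: extrema of the last two cycles differ by ",
            ">= 0.1 percentage point; increase 'n_stimuli'")
  final_ev <- traj$events$fired[n_stimuli]
  list(range = c(min = last[1], max = last[2]),
       converged = converged,
       dropout_in_final_cycle = isTRUE(final_ev == FALSE))
}

#' Firing/dropout pattern under periodic stimulation
#'
#' Simulates a periodic stimulus train and returns, per stimulus, whether an
#' action potential fired, together with summary statistics. Stimuli that
#' find the turgor below the critical threshold fail (dropouts); high
#' stimulation frequencies and reduced uptake activity (small `beta`) both
#' lengthen the dropout runs.
#'
#' @inheritParams operating_range
#' @return A list with `events` (the per-stimulus table), `fired` (logical
#'   vector), `fraction_fired`, and `longest_failure_run`.
#' @export
dropout_pattern <- function(params = ap_params(), frequency = 0.05,
                            n_stimuli = 60) {
  if (frequency <= 0) stop("dropout_pattern: 'frequency' must be > 0")
  prot <- stimulus_protocol(frequency = frequency, n = n_stimuli)
  traj <- simulate_ap(params, prot, t_end = n_stimuli / frequency)
  fired <- traj$events$fired
  fails <- !fired %in% TRUE & !is.na(fired)
  runs <- rle(fails)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(events = traj$events,
       fired = fired,
       fraction_fired = mean(fired %in% TRUE),
       longest_failure_run = longest)
}
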