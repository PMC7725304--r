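#' Cell state of the trigger-hair model
#'
#' Bundles the time stamp, compartment concentrations, pressure difference and
#' excitation bookkeeping of one integration sample. `trigger` is the binary
#' excitation flag (1 while the membrane is held at `v_excited`, 0 during
#' recovery); `excited_until` is the absolute time at which the current
#' excited phase ends (`-Inf` when the cell is at rest).
#'
#' @param t Time (s).
#' @param k_cell,k_apo Cytosolic and apoplastic K+ concentrations (mM).
#' @param a_cell,a_apo Cytosolic and apoplastic anion concentrations (mM).
#' @param dp Hydrostatic/osmotic pressure difference (bar).
#' @param trigger Excitation flag, 0 or 1.
#' @param excited_until End time of the current excited phase (s).
#' @return An object of class `"cell_state"`.
#' @export
cell_state <- function(t, k_cell, k_apo, a_cell, a_apo, dp,
                       trigger = 0, excited_until = -Inf) {
  if (!trigger %in% c(0, 1)) stop("cell_state: 'trigger' must be 0 or 1")
  if (any(c(k_cell, k_apo, a_cell, a_apo) < 0))
    stop("cell_state: concentrations must be >= 0")
  structure(list(t = t, k_cell = k_cell, k_apo = k_apo,
                 a_cell = a_cell, a_apo = a_apo, dp = dp,
                 trigger = trigger, excited_until = excited_until),
            class = "cell_state")
}

#' Initial (resting) state for a parameter set
#'
#' @param params An [ap_params()] object.
#' @return A [cell_state()] at `t = 0` with the initial concentrations, the
#'   resting pressure difference, and `trigger = 0`.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  cell_state(t = 0, k_cell = params$k_cell0, k_apo = params$k_apo0,
             a_cell = params$a_cell0, a_apo = params$a_apo0,
             dp = resting_pressure(params))
}

#' K+/anion efflux rate through depolarization-activated channels
#'
#' Flux density out of the cell during the excited phase,
#' `k * (v_excited - E_K) * trigger`, in mM/s (positive = out of the cell).
#' The compensating anion efflux is defined identical to the K+ rate, so this
#' one function serves both ions.
#'
#' @param state A [cell_state()].
#' @param params An [ap_params()] object.
#' @return Flux density in mM/s.
#' @export
efflux_rate <- function(state, params) {
  e_k <- nernst_potential(state$k_apo, state$k_cell, params$rt_over_f)
  params$k * (params$v_excited - e_k) * state$trigger
}

#' Energized K+/anion uptake rate during recovery
#'
#' Flux density of the uptake pathway,
#' `min(0, k * beta * (v_rest - E_K + v0)) * (1 - trigger)`, in mM/s
#' (negative = into the cell). The clamp at zero encodes that uptake stops
#' once the concentration gradients are re-established (E_K = v_rest + v0);
#' the energized pathway never runs backwards as an efflux.
#'
#' @inheritParams efflux_rate
#' @return Flux density in mM/s, always <= 0.
#' @export
influx_rate <- function(state, params) {
  e_k <- nernst_potential(state$k_apo, state$k_cell, params$rt_over_f)
  min(0, params$k * params$beta * (params$v_rest - e_k + params$v0)) *
    (1 - state$trigger)
}

#' One explicit-Euler step of the ion/turgor model
#'
#' Advances a [cell_state()] by `params$dt`: the cytosolic concentrations are
#' decremented by the total flux times `dt`, the apoplastic ones incremented
#' by the same amount divided by `alpha`, and the pressure difference is
#' decremented by `2 RT (alpha + 1)/alpha * flux * dt`. K+ and the anion are
#' updated with the identical flux, and `k_cell + alpha * k_apo` is conserved
#' exactly. The trigger is switched off once the new time reaches
#' `excited_until`.
#'
#' @inheritParams efflux_rate
#' @return The advanced [cell_state()].
#' @export
euler_step <- function(state, params) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "ap_params"))
  j <- efflux_rate(state, params) + influx_rate(state, params)
  dt <- params$dt
  k_cell <- state$k_cell - j * dt
  k_apo <- state$k_apo + j * dt / params$alpha
  a_cell <- state$a_cell - j * dt
  a_apo <- state$a_apo + j * dt / params$alpha
  if (min(k_cell, k_apo, a_cell, a_apo) < 0)
    stop("euler_step: a concentration became negative; ",
         "the time step 'dt' is too large for these parameters")
  dp <- state$dp - 2 * rt_bar_per_mM(params$rt_over_f) *
    (params$alpha + 1) / params$alpha * j * dt
  t_new <- state$t + dt
  cell_state(t = t_new, k_cell = k_cell, k_apo = k_apo,
             a_cell = a_cell, a_apo = a_apo, dp = dp,
             trigger = as.numeric(t_new < state$excited_until),
             excited_until = state$excited_until)
}
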