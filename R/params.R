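# Physical constants. Concentrations are handled in mM, voltages in mV,
# time in s, pressure in bar throughout the model code.
.FARADAY <- 96485 # C/mol

#' Parameters of the trigger-hair ion-flux/turgor model
#'
#' Constructs the full parameter set of the two-compartment K+/anion/turgor
#' model of a trigger-hair sensory cell. Defaults are the published values:
#' an apoplast 15 times the cell volume, a two-level membrane voltage of
#' -60 mV (excited) / -170 mV (recovery), 100 mM K+ and 100 mM monovalent
#' anion inside versus 1 mM each outside, a flux rate constant
#' `k = a_K/Vol_cell = 1` M/(V s), an uptake efficiency `beta = 0.01`, and
#' explicit-Euler integration at `dt = 0.05` s with a 1-s excited phase.
#'
#' When `v0` is `NULL` (the default) the resting-offset voltage is recomputed
#' from the initial concentrations as `RT/F * ln(K_apo0/K_cell0) - v_rest`
#' (54.87 mV at defaults), which makes the resting state an exact fixed point
#' of the uptake pathway: the influx driving force `v_rest - E_K + v0`
#' vanishes at the initial gradient, so an unstimulated cell does not drift.
#' The rounded literal 55 mV can be supplied explicitly instead.
#'
#' @param alpha Apoplast-to-cell volume ratio (dimensionless, > 0).
#' @param v_excited Membrane voltage in the excited state (mV).
#' @param v_rest Membrane voltage in the recovery state (mV); must be below
#'   `v_excited`.
#' @param v0 Resting-offset voltage (mV) of the uptake pathway, or `NULL` to
#'   recompute the exact equilibrium value from the initial concentrations.
#' @param k Flux rate constant a_K/Vol_cell in mol/(l V s); with voltages in
#'   mV this gives fluxes directly in mM/s.
#' @param beta Uptake efficiency, 0 < beta <= 1. Channel block (e.g. by Cs+)
#'   is modelled as a reduction of `beta`.
#' @param rt_over_f Thermal voltage RT/F (mV).
#' @param dt Euler time step (s).
#' @param excited_duration Length of the depolarized phase per stimulus (s).
#' @param turgor_threshold Fraction of the resting pressure difference below
#'   which a mechanical stimulus fails to initiate an action potential.
#' @param k_cell0,k_apo0 Initial K+ concentrations in cell and apoplast (mM).
#' @param a_cell0,a_apo0 Initial anion concentrations (mM).
#' @return An object of class `"ap_params"` (a validated list).
#' @examples
#' p <- ap_params()
#' p$v0 # 54.87 mV, the exact resting fixed point
#' resting_pressure(p) # about 4.8 bar
#' @export
ap_params <- function(alpha = 15, v_excited = -60, v_rest = -170, v0 = NULL,
                      k = 1, beta = 0.01, rt_over_f = 25, dt = 0.05,
                      excited_duration = 1, turgor_threshold = 0.5,
                      k_cell0 = 100, k_apo0 = 1,
                      a_cell0 = 100, a_apo0 = 1) {
  p <- list(alpha = alpha, v_excited = v_excited, v_rest = v_rest,
            k = k, beta = beta, rt_over_f = rt_over_f, dt = dt,
            excited_duration = excited_duration,
            turgor_threshold = turgor_threshold,
            k_cell0 = k_cell0, k_apo0 = k_apo0,
            a_cell0 = a_cell0, a_apo0 = a_apo0)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("ap_params: '", nm, "' must be a single finite number")
  }
  if (alpha <= 0) stop("ap_params: 'alpha' must be > 0")
  if (beta <= 0 || beta > 1) stop("ap_params: 'beta' must satisfy 0 < beta <= 1")
  if (dt <= 0) stop("ap_params: 'dt' must be > 0")
  if (excited_duration <= 0) stop("ap_params: 'excited_duration' must be > 0")
  if (turgor_threshold <= 0 || turgor_threshold >= 1)
    stop("ap_params: 'turgor_threshold' must lie strictly between 0 and 1")
  if (v_excited <= v_rest) stop("ap_params: 'v_excited' must exceed 'v_rest'")
  if (rt_over_f <= 0) stop("ap_params: 'rt_over_f' must be > 0")
  conc <- c(k_cell0 = k_cell0, k_apo0 = k_apo0,
            a_cell0 = a_cell0, a_apo0 = a_apo0)
  if (any(conc <= 0))
    stop("ap_params: initial concentrations must all be > 0 (",
         paste(names(conc)[conc <= 0], collapse = ", "), ")")
  if (is.null(v0)) {
    v0 <- rt_over_f * log(k_apo0 / k_cell0) - v_rest
  } else if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0)) {
    stop("ap_params: 'v0' must be a single finite number or NULL")
  }
  p$v0 <- v0
  structure(p, class = "ap_params")
}

#' @export
print.ap_params <- function(x, ...) {
  cat("Trigger-hair ion-flux/turgor model parameters\n")
  cat(sprintf("  alpha = %g, V_excited = %g mV, V_rest = %g mV, V0 = %.4g mV\n",
              x$alpha, x$v_excited, x$v_rest, x$v0))
  cat(sprintf("  k = %g M/(V s), beta = %g, RT/F = %g mV\n",
              x$k, x$beta, x$rt_over_f))
  cat(sprintf("  dt = %g s, excited phase = %g s, turgor threshold = %g\n",
              x$dt, x$excited_duration, x$turgor_threshold))
  cat(sprintf("  initial mM: K_cell %g, K_apo %g, A_cell %g, A_apo %g\n",
              x$k_cell0, x$k_apo0, x$a_cell0, x$a_apo0))
  invisible(x)
}

# RT expressed in bar per mM, derived from the thermal voltage so that a
# single temperature parameter governs both the Nernst terms and the
# osmotic pressure (RT = (RT/F) * F; 1 mM = 1 mol/m^3; 1 bar = 1e5 Pa).
rt_bar_per_mM <- function(rt_over_f) (rt_over_f / 1000) * .FARADAY / 1e5

#' Potassium Nernst (equilibrium) potential
#'
#' @param k_apo Apoplastic (external) K+ concentration (mM), > 0.
#' @param k_cell Cytosolic K+ concentration (mM), > 0.
#' @param rt_over_f Thermal voltage RT/F (mV).
#' @return Equilibrium voltage `RT/F * ln(k_apo/k_cell)` in mV.
#' @examples
#' nernst_potential(1, 100, 25) # -115.13 mV
#' @export
nernst_potential <- function(k_apo, k_cell, rt_over_f = 25) {
  if (any(!is.finite(k_apo)) || any(!is.finite(k_cell)) ||
      any(k_apo <= 0) || any(k_cell <= 0))
    stop("nernst_potential: concentrations must be finite and > 0")
  rt_over_f * log(k_apo / k_cell)
}

#' Resting trans-membrane pressure difference
#'
#' Evaluates the osmotic/hydrostatic pressure difference of the resting state,
#' `dP0 = RT * ((K_cell0 + A_cell0) - (K_apo0 + A_apo0))`, converted to bar.
#' With the default 200 mM inside versus 2 mM outside this is about 4.8 bar.
#'
#' @param params An [ap_params()] object.
#' @return Pressure difference in bar.
#' @export
resting_pressure <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  rt_bar_per_mM(params$rt_over_f) *
    ((params$k_cell0 + params$a_cell0) - (params$k_apo0 + params$a_apo0))
}

#' Whole-cell current implied by the flux rate constant
#'
#' Converts the volumetric flux rate constant into the macroscopic K+ current
#' a voltage-clamped cell would carry: `I = F * k * vol_cytosol * delta_v`.
#' At `k = 1` M/(V s), a 50-fl cytosol and a 50-mV driving force this is
#' about 241 pA.
#'
#' @param k Flux rate constant a_K/Vol_cell in mol/(l V s).
#' @param vol_cytosol Cytosolic volume in litres (> 0).
#' @param delta_v Driving force V - E_K in mV.
#' @return Current in ampere.
#' @examples
#' whole_cell_current(1, 50e-15, 50) * 1e12 # about 241 pA
#' @export
whole_cell_current <- function(k, vol_cytosol, delta_v) {
  if (vol_cytosol <= 0) stop("whole_cell_current: 'vol_cytosol' must be > 0")
  .FARADAY * k * vol_cytosol * (delta_v / 1000)
}
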