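#' Boltzmann gating parameters
#'
#' Parameters of the voltage-dependent open-probability model of a
#' hyperpolarization-activated channel:
#' `po = 1 / (1 + exp(a/(RT/F) * (V - V_half)))`.
#'
#' @param a Apparent gating-charge factor (dimensionless, > 0 for a
#'   hyperpolarization-activated channel).
#' @param v_half Half-activation voltage (mV).
#' @param rt_over_f Thermal voltage RT/F (mV). The default 25.2 mV is the
#'   value used in the oocyte recordings.
#' @return An object of class `"boltzmann_params"`.
#' @export
boltzmann_params <- function(a, v_half, rt_over_f = 25.2) {
  if (!is.finite(a) || !is.finite(v_half)) stop("boltzmann_params: non-finite")
  if (rt_over_f <= 0) stop("boltzmann_params: 'rt_over_f' must be > 0")
  structure(list(a = a, v_half = v_half, rt_over_f = rt_over_f),
            class = "boltzmann_params")
}

#' Voltage-dependent open probability
#'
#' @param v Membrane voltage(s) in mV.
#' @param params A [boltzmann_params()] object.
#' @return Open probability in (0, 1), strictly decreasing in `v` for
#'   `a > 0` (hyperpolarization activation).
#' @examples
#' p <- boltzmann_params(a = 0.6, v_half = -95.7)
#' open_probability(-150, p) # about 0.78
#' @export
open_probability <- function(v, params) {
  stopifnot(inherits(params, "boltzmann_params"))
  1 / (1 + exp((params$a / params$rt_over_f) * (v - params$v_half)))
}

#' pH-dependence parameters of the half-activation voltage
#'
#' Combined Boltzmann / law-of-mass-action model in which external protons
#' shift the half-activation voltage:
#' `V_half(pH) = V_half_inf - Vs * ln((10^pH + 10^pK_C)/(10^pH + 10^pK_O))`
#' with `Vs = RT/(aF)`. For an acid-activated channel `pK_O > pK_C`, so
#' acidification shifts `V_half` positive (more open channels at
#' physiological voltages); at high pH the curve saturates at `V_half_inf`.
#'
#' @param v_half_inf Asymptotic half-activation voltage at high pH (mV).
#' @param pk_o,pk_c Apparent pK of the open and closed state (pH units).
#' @param a Apparent gating-charge factor.
#' @param rt_over_f Thermal voltage (mV); `vs = rt_over_f / a`.
#' @return An object of class `"ph_model_params"` (includes derived `vs`).
#' @seealso [kdm1_wt_gating()], [kdm1_h147s_gating()] for the published
#'   fitted values.
#' @export
ph_model_params <- function(v_half_inf, pk_o, pk_c, a = 0.6, rt_over_f = 25.2) {
  if (a <= 0 || rt_over_f <= 0)
    stop("ph_model_params: 'a' and 'rt_over_f' must be > 0")
  structure(list(v_half_inf = v_half_inf, pk_o = pk_o, pk_c = pk_c,
                 a = a, rt_over_f = rt_over_f, vs = rt_over_f / a),
            class = "ph_model_params")
}

#' Published pH-gating parameters of KDM1
#'
#' Convenience constructors for the fitted wild-type and H147S-mutant
#' parameter sets of the KDM1 trigger-hair K+ channel
#' (`a = 0.6`, `RT/F = 25.2` mV, hence `Vs = 42` mV).
#'
#' @return A [ph_model_params()] object.
#' @export
kdm1_wt_gating <- function() {
  ph_model_params(v_half_inf = -177.048, pk_o = 5.1328, pk_c = 4.04)
}

#' @rdname kdm1_wt_gating
#' @export
kdm1_h147s_gating <- function() {
  ph_model_params(v_half_inf = -153.632, pk_o = 4.6285, pk_c = 4.1914)
}

#' Half-activation voltage at a given external pH
#'
#' @param ph External pH value(s).
#' @param params A [ph_model_params()] object.
#' @return Half-activation voltage(s) in mV.
#' @examples
#' v_half_at_ph(4, kdm1_wt_gating()) # about -95.6 mV
#' v_half_at_ph(7, kdm1_wt_gating()) # about -176.5 mV
#' @export
v_half_at_ph <- function(ph, params) {
  stopifnot(inherits(params, "ph_model_params"))
  params$v_half_inf -
    params$vs * log((10^ph + 10^params$pk_c) / (10^ph + 10^params$pk_o))
}

#' Convert tail currents to a relative open-probability curve
#'
#' Tail currents measured at a fixed post-pulse voltage are proportional to
#' the open probability reached at the end of each test pulse; dividing by
#' the largest magnitude maps them onto a relative activation curve in
#' [0, 1] (sign handled so saturation maps to 1).
#'
#' @param v Test voltages (mV), >= 3 distinct values.
#' @param i_tail Tail currents, one per test voltage, sharing one sign
#'   convention (zeros allowed).
#' @return A data frame with columns `v_mv` and `rel_po`.
#' @export
tail_to_open_probability <- function(v, i_tail) {
  if (length(v) != length(i_tail)) stop("tail_to_open_probability: lengths differ")
  if (length(unique(v)) < 3)
    stop("tail_to_open_probability: need >= 3 distinct test voltages")
  nz <- i_tail[i_tail != 0]
  if (length(nz) == 0) stop("tail_to_open_probability: all tail currents are zero")
  if (length(unique(sign(nz))) > 1)
    stop("tail_to_open_probability: tail currents must share one sign")
  data.frame(v_mv = v, rel_po = i_tail / nz[which.max(abs(nz))])
}

# Multi-start bounded Levenberg-Marquardt helper: returns the converged fit
# with the smallest residual norm, or NULL if every start fails.
best_nls_fit <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::residuals(fit)^2))
      if (is.null(best) || rn < best$resid_norm)
        best <- list(fit = fit, resid_norm = rn)
    }
  }
  best
}

#' Fit a Boltzmann activation curve
#'
#' Nonlinear least squares of relative open probability against voltage with
#' the model `rel_po = 1/(1 + exp(a/(RT/F) (V - V_half)))`, estimating
#' `(a, v_half)` or `v_half` alone when `fixed_a` is given. Five starts are
#' used (the `v_half` start is the voltage whose response is nearest 0.5,
#' combined with a grid of gating-charge starts of both signs) so that a
#' monotone-increasing curve converges to a negative `a`, which is flagged as
#' inconsistent with hyperpolarization activation rather than silently
#' mirrored. Values slightly above 1 from measurement noise are used as-is;
#' clipping them would bias `v_half`.
#'
#' @param curve A data frame with columns `v_mv` and `rel_po` (>= 5 distinct
#'   voltages spanning the transition).
#' @param fixed_a Optional fixed gating-charge factor.
#' @param rt_over_f Thermal voltage (mV).
#' @return A list with `params` (a [boltzmann_params()]), `se` (approximate
#'   standard errors), `resid_norm`, and `hyperpolarization_activated`
#'   (`a > 0`).
#' @export
fit_boltzmann <- function(curve, fixed_a = NULL, rt_over_f = 25.2) {
  stopifnot(is.data.frame(curve), all(c("v_mv", "rel_po") %in% names(curve)))
  curve <- curve[is.finite(curve$v_mv) & is.finite(curve$rel_po), ]
  if (length(unique(curve$v_mv)) < 5)
    stop("fit_boltzmann: need >= 5 distinct voltages")
  if (diff(range(curve$rel_po)) < 0.2)
    stop("fit_boltzmann: dynamic range of the curve is < 0.2; ",
         "the data do not span the activation transition")
  vh0 <- curve$v_mv[which.min(abs(curve$rel_po - 0.5))]
  if (is.null(fixed_a)) {
    starts <- lapply(c(0.3, 0.6, 1.2, -0.6, 2),
                     function(a) list(a = a, v_half = vh0))
    best <- best_nls_fit(
      rel_po ~ 1 / (1 + exp((a / rt_over_f) * (v_mv - v_half))), curve,
      starts, lower = c(a = -20, v_half = min(curve$v_mv) - 300),
      upper = c(a = 20, v_half = max(curve$v_mv) + 300))
  } else {
    starts <- lapply(vh0 + c(0, -30, 30, -60, 60),
                     function(v) list(v_half = v))
    a <- fixed_a
    best <- best_nls_fit(
      rel_po ~ 1 / (1 + exp((a / rt_over_f) * (v_mv - v_half))), curve,
      starts, lower = c(v_half = min(curve$v_mv) - 300),
      upper = c(v_half = max(curve$v_mv) + 300))
  }
  if (is.null(best)) stop("fit_boltzmann: nonlinear least squares did not converge")
  est <- stats::coef(best$fit)
  a_hat <- if (is.null(fixed_a)) unname(est["a"]) else fixed_a
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) NULL)
  list(params = boltzmann_params(a = a_hat, v_half = unname(est["v_half"]),
                                 rt_over_f = rt_over_f),
       se = se, resid_norm = best$resid_norm,
       hyperpolarization_activated = a_hat > 0)
}

#' Fit the pH-dependence of the half-activation voltage
#'
#' Least-squares fit of `(v_half_inf, pk_o, pk_c)` in the combined
#' Boltzmann / mass-action model, with the gating-charge factor and thermal
#' voltage held fixed (so `vs = rt_over_f/a` is fixed, as in the published
#' analysis). Multi-start initialisation places the pK starts at the data's
#' pH extremes to guard against the open/closed-pK degeneracy; a fit with
#' `|pk_o - pk_c| < 1e-3` is flagged as degenerate.
#'
#' @param ph,v_half Paired observations (>= 4 pH points).
#' @param a Fixed gating-charge factor.
#' @param rt_over_f Thermal voltage (mV).
#' @param weights Optional per-point weights for weighted least squares;
#'   unweighted by default.
#' @return A list with `params` (a [ph_model_params()]), `se`, `resid_norm`,
#'   `acid_activated` (`pk_o > pk_c`), and `degenerate`.
#' @export
fit_ph_model <- function(ph, v_half, a = 0.6, rt_over_f = 25.2,
                         weights = NULL) {
  if (length(ph) != length(v_half)) stop("fit_ph_model: lengths differ")
  if (length(unique(ph)) < 4)
    stop("fit_ph_model: need >= 4 distinct pH points (3 parameters + 1)")
  vs <- rt_over_f / a
  dat <- data.frame(ph = ph, v_half = v_half)
  vinf0 <- v_half[which.max(ph)]
  lo <- min(ph) - 2; hi <- max(ph) + 2
  starts <- list(
    list(v_half_inf = vinf0, pk_o = hi - 1, pk_c = lo + 0.5),
    list(v_half_inf = vinf0, pk_o = mean(ph), pk_c = lo),
    list(v_half_inf = vinf0, pk_o = hi, pk_c = mean(ph)),
    list(v_half_inf = vinf0 - 20, pk_o = hi - 1, pk_c = lo + 1),
    list(v_half_inf = vinf0 + 20, pk_o = mean(ph) + 0.5, pk_c = mean(ph) - 0.5))
  form <- v_half ~ v_half_inf -
    vs * log((10^ph + 10^pk_c) / (10^ph + 10^pk_o))
  best <- NULL
  for (st in starts) {
    args <- list(form, data = dat, start = st,
                 lower = c(v_half_inf = -500, pk_o = lo - 4, pk_c = lo - 4),
                 upper = c(v_half_inf = 200, pk_o = hi + 4, pk_c = hi + 4),
                 control = minpack.lm::nls.lm.control(maxiter = 300))
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::residuals(fit)^2))
      if (is.null(best) || rn < best$resid_norm)
        best <- list(fit = fit, resid_norm = rn)
    }
  }
  if (is.null(best)) stop("fit_ph_model: nonlinear least squares did not converge")
  est <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) NULL)
  degenerate <- abs(est["pk_o"] - est["pk_c"]) < 1e-3
  if (degenerate)
    warning("fit_ph_model: pk_o and pk_c are degenerate (difference < 1e-3)")
  list(params = ph_model_params(unname(est["v_half_inf"]),
                                unname(est["pk_o"]), unname(est["pk_c"]),
                                a = a, rt_over_f = rt_over_f),
       se = se, resid_norm = best$resid_norm,
       acid_activated = unname(est["pk_o"] > est["pk_c"]),
       degenerate = unname(degenerate))
}

#' Nernst slope of the reversal potential
#'
#' Linear-regression slope of the reversal potential on log10 of the external
#' K+ concentration, in mV per decade. An ideally K+-selective channel at a
#' thermal voltage of 25 mV gives `25 ln(10) = 57.6` mV/decade.
#'
#' @param e_rev Reversal potentials (mV).
#' @param k_ext External K+ concentrations (mM), > 0, >= 2 distinct values.
#' @return A list with `slope` (mV/decade), `se`, and the `fit` object.
#' @export
nernst_shift_per_decade <- function(e_rev, k_ext) {
  if (length(e_rev) != length(k_ext)) stop("nernst_shift_per_decade: lengths differ")
  if (any(k_ext <= 0)) stop("nernst_shift_per_decade: concentrations must be > 0")
  if (length(unique(k_ext)) < 2)
    stop("nernst_shift_per_decade: need >= 2 distinct concentrations")
  fit <- stats::lm(e_rev ~ log10(k_ext))
  # noiseless calibration data fit exactly; the SE is then just 0
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(stats::coef(fit)[2]),
       se = if (nrow(sm) >= 2 && ncol(sm) >= 2) sm[2, 2] else NA_real_,
       fit = fit)
}

#' Fractional current block
#'
#' `1 - i_blocked/i_control`: 0.9 means the blocker removed 90% of the
#' current (the Cs+ magnitude on KDM1), 0.6 the TEA+/Ba2+ magnitude. Values
#' outside [0, 1] (from noise or run-up) are clipped and flagged via the
#' `"out_of_range"` attribute.
#'
#' @param i_control Current without blocker (non-zero).
#' @param i_blocked Current with blocker, same sign convention.
#' @return Fraction blocked in [0, 1], with attribute `out_of_range`.
#' @examples
#' fractional_block(-10, -1) # 0.9
#' @export
fractional_block <- function(i_control, i_blocked) {
  if (any(i_control == 0)) stop("fractional_block: control current is zero")
  f <- 1 - i_blocked / i_control
  oor <- f < 0 | f > 1
  f <- pmin(1, pmax(0, f))
  attr(f, "out_of_range") <- oor
  f
}

#' Per-cell normalization of current-voltage data
#'
#' Oocyte current amplitudes vary strongly between cells, so each cell's
#' currents are divided by the magnitude of its own measurement at a
#' reference condition and voltage (sign preserved: inward currents stay
#' negative). Across-cell means and standard deviations are then computed
#' per condition and voltage; the reference mean has magnitude 1.
#'
#' @param data A data frame with columns `cell_id`, `condition`, `v_mv`, `i`.
#' @param ref_condition,ref_v The reference condition label and voltage (mV);
#'   every cell must have a measurement there.
#' @return A list with `normalized` (per-record data frame with `i_norm`) and
#'   `summary` (per condition/voltage mean, sd, n).
#' @export
normalize_currents <- function(data, ref_condition, ref_v) {
  need <- c("cell_id", "condition", "v_mv", "i")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  cells <- unique(data$cell_id)
  ref_mag <- vapply(cells, function(cid) {
    sel <- data$cell_id == cid & data$condition == ref_condition &
      data$v_mv == ref_v
    if (!any(sel)) NA_real_ else abs(data$i[sel][1])
  }, numeric(1))
  missing <- cells[is.na(ref_mag) | ref_mag == 0]
  if (length(missing) > 0)
    stop("normalize_currents: no usable reference measurement for cell(s): ",
         paste(missing, collapse = ", "))
  data$i_norm <- data$i / ref_mag[match(data$cell_id, cells)]
  agg <- stats::aggregate(i_norm ~ condition + v_mv, data = data,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  summary <- data.frame(condition = agg$condition, v_mv = agg$v_mv,
                        mean = agg$i_norm[, "mean"],
                        sd = agg$i_norm[, "sd"],
                        n = agg$i_norm[, "n"])
  list(normalized = data, summary = summary)
}
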