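#' Kinetic parameterization of a Cav1.3 channel variant
#'
#' Bundles every parameter of the gating model for one channel construct:
#' Boltzmann activation (`v_half_act`, `slope_act`) with a bell-shaped
#' activation time constant, linear-ohmic driving force (`g_max`, `v_rev`),
#' voltage-dependent inactivation as a fast plus a slow gate plus a
#' persistent (non-inactivating) pathway whose fractions sum to one,
#' a steady-state inactivation Boltzmann (`v_half_inact`, `slope_inact`)
#' shared by the VDI gates, a calcium-dependent inactivation gate driven by
#' the instantaneous inward Ca2+ flux, a slow deactivation pathway that
#' shapes tail currents, an ON gating-charge parameterization, and
#' dihydropyridine block (Hill slope fixed at 1) with a linear run-down rate
#' for pharmacology runs.
#'
#' All voltages are on the junction-corrected (true membrane) scale.
#'
#' @param variant variant label (free text).
#' @param v_half_act,slope_act activation Boltzmann midpoint and slope (mV).
#' @param g_max maximal conductance (nS).
#' @param v_rev reversal potential (mV).
#' @param tau_act_min,tau_act_max,tau_act_v,tau_act_k activation time
#'   constant tau_m(V) = `tau_act_min` + `tau_act_max`/cosh((V -
#'   `tau_act_v`)/`tau_act_k`), in ms and mV.
#' @param frac_fast,frac_slow,frac_persistent VDI pathway fractions (sum 1).
#' @param tau_fast_0,tau_slow_0 VDI time constants at the inactivation
#'   midpoint (ms); the voltage dependence is
#'   tau(V) = tau0 / cosh((V - `v_half_inact`)/`tau_v_dep`).
#' @param tau_v_dep width of the VDI time-constant bell (mV).
#' @param v_half_inact,slope_inact steady-state inactivation Boltzmann (mV).
#' @param cdi_coupling CDI rate per unit inward Ca2+ charge (1/pC).
#' @param tau_cdi_recovery CDI recovery time constant (ms).
#' @param tail_slow_frac fraction of channels deactivating through the slow
#'   pathway.
#' @param tau_tail_slow slow deactivation time constant (ms).
#' @param q_on_total integrated ON gating charge (pA*ms).
#' @param tau_q gating-current decay time constant (ms).
#' @param ic50 dihydropyridine IC50 (nM).
#' @param hill_slope Hill slope (fixed at 1).
#' @param rundown_rate linear run-down of peak current (%/min).
#' @return an object of class `cav_variant` (a validated list).
#' @export
variant_params <- function(variant,
                           v_half_act, slope_act, g_max, v_rev,
                           tau_act_min = 0.1, tau_act_max = 1.2,
                           tau_act_v = v_half_act, tau_act_k = 16,
                           frac_fast, frac_slow, frac_persistent,
                           tau_fast_0, tau_slow_0, tau_v_dep = 23,
                           v_half_inact, slope_inact,
                           cdi_coupling = 0, tau_cdi_recovery = 2000,
                           tail_slow_frac = 0.25, tau_tail_slow = 1.2,
                           q_on_total = 150, tau_q = 0.4,
                           ic50 = 60, hill_slope = 1, rundown_rate = 3) {
  p <- list(variant = variant,
            v_half_act = v_half_act, slope_act = slope_act,
            g_max = g_max, v_rev = v_rev,
            tau_act_min = tau_act_min, tau_act_max = tau_act_max,
            tau_act_v = tau_act_v, tau_act_k = tau_act_k,
            frac_fast = frac_fast, frac_slow = frac_slow,
            frac_persistent = frac_persistent,
            tau_fast_0 = tau_fast_0, tau_slow_0 = tau_slow_0,
            tau_v_dep = tau_v_dep,
            v_half_inact = v_half_inact, slope_inact = slope_inact,
            cdi_coupling = cdi_coupling, tau_cdi_recovery = tau_cdi_recovery,
            tail_slow_frac = tail_slow_frac, tau_tail_slow = tau_tail_slow,
            q_on_total = q_on_total, tau_q = tau_q,
            ic50 = ic50, hill_slope = hill_slope, rundown_rate = rundown_rate)
  validate_variant(p)
  structure(p, class = "cav_variant")
}

validate_variant <- function(p) {
  if (abs(p$frac_fast + p$frac_slow + p$frac_persistent - 1) > 1e-9)
    stop("invalid argument: VDI pathway fractions must sum to 1")
  taus <- c(p$tau_act_min, p$tau_act_max, p$tau_fast_0, p$tau_slow_0,
            p$tau_tail_slow, p$tau_cdi_recovery, p$tau_q)
  if (any(taus <= 0)) stop("invalid argument: all time constants must be > 0")
  if (p$slope_act <= 0 || p$slope_inact <= 0 || p$tau_act_k <= 0 ||
      p$tau_v_dep <= 0)
    stop("invalid argument: slope parameters must be > 0")
  if (p$ic50 <= 0) stop("invalid argument: ic50 must be > 0")
  if (p$cdi_coupling < 0) stop("invalid argument: cdi_coupling must be >= 0")
  invisible(p)
}

#' @export
print.cav_variant <- function(x, ...) {
  cat(sprintf("<cav_variant '%s'> V0.5,act %.2f mV (k %.2f), Vrev %.1f mV, Gmax %.2f nS\n",
              x$variant, x$v_half_act, x$slope_act, x$v_rev, x$g_max))
  cat(sprintf("  SSI: V0.5 %.2f mV (k %.2f), persistent %.1f%%; CDI coupling %.3g /pC\n",
              x$v_half_inact, x$slope_inact, 100 * x$frac_persistent,
              x$cdi_coupling))
  invisible(x)
}

#' Steady-state activation
#'
#' Boltzmann open probability m_inf(V) = 1 / (1 + exp(-(V - V0.5)/k)), the
#' same relationship used to fit normalized conductance-voltage curves.
#'
#' @param v membrane voltage(s), mV.
#' @param p a [variant_params()] object.
#' @return values in (0, 1); exactly 0.5 at `v = p$v_half_act`.
#' @export
steady_state_activation <- function(v, p) {
  plogis((v - p$v_half_act) / p$slope_act)
}

steady_state_inactivation_gate <- function(v, p) {
  plogis(-(v - p$v_half_inact) / p$slope_inact)
}

#' Exact first-order gate update
#'
#' Advances a Hodgkin-Huxley-style gate by `dt` at constant voltage using the
#' closed-form solution of dx/dt = (x_inf - x)/tau.
#'
#' @param x0 gate value at the start of the interval (in \[0, 1\]).
#' @param x_inf steady-state value at the current voltage.
#' @param tau time constant (ms, > 0).
#' @param dt interval (ms, >= 0).
#' @return `x_inf + (x0 - x_inf) * exp(-dt/tau)`.
#' @export
gate_update_exact <- function(x0, x_inf, tau, dt) {
  if (any(tau <= 0)) stop("invalid argument: tau must be > 0")
  x_inf + (x0 - x_inf) * exp(-dt / tau)
}

#' Steady-state dihydropyridine block
#'
#' Fraction of current blocked at a drug concentration, c / (c + IC50), a
#' Hill relationship with slope 1 and full block at saturation.
#'
#' @param p a [variant_params()] object.
#' @param concentration drug concentration (nM, >= 0).
#' @return blocked fraction in \[0, 1).
#' @export
apply_block <- function(p, concentration) {
  if (any(concentration < 0))
    stop("invalid argument: concentration must be >= 0")
  concentration / (concentration + p$ic50)
}

#' Packaged Cav1.3 variant parameter sets
#'
#' Returns the calibrated parameter set for one of the packaged constructs:
#' the C-terminally long and short wild-type Cav1.3 splice variants (`WT_L`,
#' `WT_S`), the gain-of-function mutant in both backbones (`S652L_L`,
#' `S652L_S`) and the loss-of-function mutant (`S652W_L`). Boltzmann and
#' reversal parameters are the published construct values; kinetic and CDI
#' parameters were calibrated (scripts/calibrate.R) so that the simulated
#' recordings, analyzed with this package's pipeline, reproduce the
#' published activation/inactivation parameters and inactivation time
#' courses. IC50 values for constructs without published dose-response data
#' are synthetic stand-ins equal to the corresponding backbone measurement.
#'
#' @param variant one of `"WT_L"`, `"WT_S"`, `"S652L_L"`, `"S652L_S"`,
#'   `"S652W_L"`.
#' @return a [variant_params()] object.
#' @export
cav13_variant <- function(variant = c("WT_L", "WT_S", "S652L_L", "S652L_S",
                                      "S652W_L")) {
  variant <- match.arg(variant)
  do.call(variant_params, .cav13_presets[[variant]])
}

#' @rdname cav13_variant
#' @return for `cav13_variants()`: named list of all packaged sets.
#' @export
cav13_variants <- function() {
  sets <- names(.cav13_presets)
  stats::setNames(lapply(sets, cav13_variant), sets)
}

#' Read or write variant parameters as JSON
#'
#' @param p a [variant_params()] object.
#' @param path file path.
#' @return `variant_to_json` invisibly returns the JSON string;
#'   `variant_from_json` returns a validated [variant_params()] object.
#' @export
variant_to_json <- function(p, path = NULL) {
  js <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname variant_to_json
#' @param json JSON string or file path.
#' @export
variant_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(variant_params, x)
}
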