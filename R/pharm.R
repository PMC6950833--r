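# Run-down-corrected concentration-response analysis of steady-state
# current inhibition.

#' Run-down correction of a drug peak series
#'
#' Divides the drug cell's relative peak current by the linear decay fitted
#' to a control cell recorded with bath solution only, then reads the
#' steady-state inhibition from the mean of the last `n_steady` corrected
#' sweeps. Both series are normalized to the mean of their pre-drug
#' baseline sweeps; cells whose baseline drifts faster than
#' `baseline_slope_tol` (fractional change per sweep) are rejected.
#'
#' @param drug_peaks data frame with `sweep` (index) and `peak` (pA) of the
#'   drug cell; the `n_baseline` sweeps immediately before `drug_start` are
#'   the control baseline (drug application starts only after the baseline
#'   has become constant).
#' @param control_peaks data frame with `sweep` and `peak` of a control
#'   (no-drug) cell over matching sweep indices.
#' @param drug_start first sweep index with drug present (>= 4 so that at
#'   least three baseline sweeps exist).
#' @param n_baseline number of pre-drug baseline sweeps (>= 3).
#' @param n_steady number of final sweeps averaged for the steady state.
#' @param baseline_slope_tol maximal fractional baseline slope per sweep.
#' @return list with `corrected` (data frame `sweep`, `relative`,
#'   `corrected`), `inhibition` (0-1) and `rundown_slope` (per sweep).
#' @export
rundown_correct <- function(drug_peaks, control_peaks, drug_start,
                            n_baseline = 3, n_steady = 3,
                            baseline_slope_tol = 0.01) {
  stopifnot(all(c("sweep", "peak") %in% names(drug_peaks)),
            all(c("sweep", "peak") %in% names(control_peaks)))
  if (drug_start < 4 || n_baseline < 3)
    stop("invalid argument: need at least three baseline sweeps before drug")
  base_idx <- drug_peaks$sweep < drug_start &
    drug_peaks$sweep >= drug_start - n_baseline
  if (sum(base_idx) < 3)
    stop("invalid argument: need at least three baseline sweeps before drug")
  base <- drug_peaks[base_idx, ]
  rel_base <- base$peak / mean(base$peak)
  slope_base <- stats::coef(stats::lm(rel_base ~ base$sweep))[2L]
  if (abs(slope_base) > baseline_slope_tol)
    stop("cell rejected: unstable baseline (|slope| = ",
         signif(abs(slope_base), 3), " per sweep)")
  rel <- drug_peaks$peak / mean(base$peak)
  ctrl_base <- control_peaks$peak[control_peaks$sweep < drug_start &
                                    control_peaks$sweep >= drug_start - n_baseline]
  ctrl_rel <- control_peaks$peak / mean(ctrl_base)
  dec_fit <- stats::lm(ctrl_rel ~ control_peaks$sweep)
  decay <- stats::predict(dec_fit,
                          newdata = data.frame(`control_peaks$sweep` = drug_peaks$sweep,
                                               check.names = FALSE))
  decay <- pmax(decay, 0.05)
  corrected <- rel / decay
  steady_idx <- utils::tail(order(drug_peaks$sweep), n_steady)
  inhibition <- 1 - mean(corrected[steady_idx])
  list(corrected = data.frame(sweep = drug_peaks$sweep, relative = rel,
                              corrected = corrected),
       inhibition = inhibition,
       rundown_slope = unname(stats::coef(dec_fit)[2L]))
}

hill_inhibition <- function(conc, ic50) 100 * conc / (conc + ic50)

#' Constrained Hill fit of a concentration-inhibition relationship
#'
#' One-parameter least-squares fit of percent inhibition to
#' `100 c / (c + IC50)` — Hill slope fixed at 1, bottom fixed at 0, top at
#' 100. The IC50 is fitted on the log scale; the 95% confidence interval is
#' the asymptotic interval on log(IC50), exponentiated (asymmetric, as
#' conventionally reported).
#'
#' @param concentrations drug concentrations (nM), >= 4 values spanning at
#'   least 1.5 log units.
#' @param inhibition percent inhibition at each concentration.
#' @param monotone_tol tolerated non-monotonicity (percentage points) before
#'   a warning is raised.
#' @return an object of class `cav_hill_fit`: `ic50` (nM), `ci95`,
#'   `hill_slope` (1), `top` (100), `bottom` (0), per-concentration data.
#' @export
fit_hill <- function(concentrations, inhibition, monotone_tol = 5) {
  if (length(concentrations) < 4)
    stop("invalid argument: need >= 4 concentrations")
  if (diff(range(log10(concentrations))) < 1.5)
    stop("invalid argument: concentrations must span >= 1.5 log units")
  ord <- order(concentrations)
  if (any(diff(inhibition[ord]) < -monotone_tol))
    warning("inhibition decreases with concentration beyond tolerance")
  d <- data.frame(conc = concentrations, inh = inhibition)
  l0 <- log(concentrations[which.min(abs(inhibition - 50))])
  fit <- safe_nlsLM(inh ~ 100 * conc / (conc + exp(lic)), d,
                    start = list(lic = l0))
  if (inherits(fit, "error")) fit_failure(conditionMessage(fit))
  cf <- summary(fit)$coefficients
  lic <- cf["lic", "Estimate"]; se <- cf["lic", "Std. Error"]
  structure(list(ic50 = exp(lic),
                 ci95 = exp(lic + c(-1, 1) * stats::qnorm(0.975) * se),
                 log_ic50 = lic, log_ic50_se = se,
                 hill_slope = 1, top = 100, bottom = 0,
                 data = d, residual_sse = sum(stats::resid(fit)^2)),
            class = "cav_hill_fit")
}

#' @export
print.cav_hill_fit <- function(x, ...) {
  cat(sprintf("<cav_hill_fit> IC50 %.3g nM (95%% CI %.3g - %.3g), Hill slope 1\n",
              x$ic50, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Compare two concentration-response curves
#'
#' Extra-sum-of-squares F test of separate IC50s against a shared IC50
#' (both fits constrained to Hill slope 1, bottom 0, top 100).
#'
#' @param conc_a,inh_a,conc_b,inh_b the two datasets.
#' @return list with both [fit_hill()] objects, the shared-IC50 SSE, `f`
#'   and `p`.
#' @export
compare_hill <- function(conc_a, inh_a, conc_b, inh_b) {
  fa <- fit_hill(conc_a, inh_a)
  fb <- fit_hill(conc_b, inh_b)
  conc <- c(conc_a, conc_b); inh <- c(inh_a, inh_b)
  shared <- safe_nlsLM(inh ~ 100 * conc / (conc + exp(lic)),
                       data.frame(conc = conc, inh = inh),
                       start = list(lic = log(sqrt(fa$ic50 * fb$ic50))))
  if (inherits(shared, "error")) fit_failure(conditionMessage(shared))
  sse_shared <- sum(stats::resid(shared)^2)
  sse_sep <- fa$residual_sse + fb$residual_sse
  df1 <- 1
  df2 <- length(conc) - 2
  f <- ((sse_shared - sse_sep) / df1) / (sse_sep / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(fit_a = fa, fit_b = fb, sse_shared = sse_shared, f = f, p = p)
}

#' Simulate a run-down-corrected dose-response experiment
#'
#' For each concentration, simulates a pharmacology run (square pulses at
#' 0.1 Hz with linear run-down; drug applied after the baseline sweeps) and
#' a matched no-drug control cell, extracts per-sweep peaks, applies
#' [rundown_correct()] and returns the percent inhibition per
#' concentration.
#'
#' @param p a [variant_params()] object.
#' @param cfg a [sim_config()].
#' @param concentrations tested concentrations (nM).
#' @param n_stabilize initial sweeps discarded while the cell's inactivation
#'   equilibrates at the pulsing cadence (drug application starts only after
#'   constant control sweeps).
#' @param n_baseline pre-drug baseline sweeps.
#' @param n_drug sweeps with drug present.
#' @param vmax_cmd command voltage of the test pulse (mV).
#' @return data frame with `conc` and `inhibition` (percent).
#' @export
simulate_dose_response <- function(p, cfg,
                                   concentrations = c(1, 3, 10, 30, 100, 300, 1000),
                                   n_stabilize = 4, n_baseline = 3,
                                   n_drug = 7, vmax_cmd = 0) {
  n_sweeps <- n_stabilize + n_baseline + n_drug
  drug_start <- n_stabilize + n_baseline + 1
  prot <- build_pharm_protocol(vmax_cmd, n_sweeps, hp = -79.7)
  peaks_of <- function(recs) {
    data.frame(sweep = seq_along(recs),
               peak = vapply(recs, function(r)
                 window_peak(as_processed(r), "test", skip_ms = 2), numeric(1)))
  }
  ctrl <- simulate_protocol(p, prot, cfg, conc = 0, rundown = TRUE)
  ctrl_peaks <- peaks_of(ctrl)
  inh <- vapply(concentrations, function(cc) {
    conc_vec <- c(rep(0, drug_start - 1), rep(cc, n_drug))
    recs <- simulate_protocol(p, prot, cfg, conc = conc_vec, rundown = TRUE)
    rc <- rundown_correct(peaks_of(recs), ctrl_peaks, drug_start = drug_start)
    100 * rc$inhibition
  }, numeric(1))
  data.frame(conc = concentrations, inhibition = inh)
}
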