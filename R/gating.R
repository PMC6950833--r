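# Derived gating statistics: I-V extraction, SSI extraction, window
# currents, inactivation time course, CDI decomposition, persistent
# currents and the open-probability proxy.

#' Extract peak currents from an I-V protocol
#'
#' Signed peak current (and current density) per test potential; the peak is
#' the extremum of a 3-sample median-smoothed trace within the test window,
#' skipping the first `skip_ms` to avoid onset transients.
#'
#' @param recs list of processed sweeps from [build_iv_protocol()].
#' @param skip_ms onset skip within the test window (ms).
#' @param smooth apply 3-sample median smoothing before peak picking.
#' @return data frame of class `cav_iv_points` with `v` (corrected mV), `i`
#'   (pA), `i_density` (pA/pF); attribute `v_max` is the voltage of maximal
#'   inward current (ties broken toward the more hyperpolarized voltage).
#' @export
extract_iv <- function(recs, skip_ms = 3, smooth = TRUE) {
  if (length(recs) < 5) stop("insufficient data: need >= 5 I-V sweeps")
  rows <- lapply(recs, function(r) {
    r <- as_processed(r)
    j <- which(r$segments$role == "test")[1L]
    idx1 <- which(r$segment_index == j)[1L]
    data.frame(v = r$v_corrected[idx1],
               i = window_peak(r, "test", skip_ms = skip_ms, smooth = smooth),
               capacitance = r$capacitance)
  })
  pts <- do.call(rbind, rows)
  pts$i_density <- pts$i / pts$capacitance
  pts <- pts[order(pts$v), c("v", "i", "i_density")]
  if (all(abs(pts$i) < 1e-9))
    stop("insufficient data: no measurable currents (all-zero I-V)")
  v_max <- min(pts$v[pts$i == min(pts$i)])
  attr(pts, "v_max") <- v_max
  class(pts) <- c("cav_iv_points", class(pts))
  pts
}

#' Full I-V / activation analysis of an I-V protocol
#'
#' Convenience pipeline: [extract_iv()], [fit_iv()], conductance transform
#' at the fitted reversal potential and the normalized G-V Boltzmann fit.
#' `exclude_mv` widens the singularity guard around the reversal potential;
#' points with a small driving force amplify any error in the fitted
#' reversal and can corrupt the G-V normalization.
#'
#' @param recs list of processed I-V sweeps.
#' @param exclude_mv reversal guard for [conductance_transform()].
#' @param skip_ms forwarded to [extract_iv()].
#' @return list with `points`, `v_max`, `iv` (a `cav_iv_fit`) and
#'   `activation` (a `cav_act_fit`).
#' @export
analyze_iv <- function(recs, exclude_mv = 2, skip_ms = 3) {
  pts <- extract_iv(recs, skip_ms = skip_ms)
  ivf <- fit_iv(pts)
  gv <- conductance_transform(pts, ivf$v_rev, exclude_mv = exclude_mv)
  act <- fit_boltzmann(gv)
  list(points = pts, v_max = attr(pts, "v_max"), iv = ivf, activation = act)
}

#' Extract steady-state inactivation points
#'
#' Availability per conditioning voltage as the ratio of the test-pulse to
#' the control-pulse peak current (both pulses to the voltage of maximal
#' inward current).
#'
#' @param recs list of processed sweeps from [build_ssi_protocol()].
#' @param min_control_pA cells whose control peak is below this magnitude
#'   are rejected (noise floor).
#' @param skip_ms onset skip within each 20-ms pulse (ms).
#' @return data frame with `v` (corrected conditioning voltage, mV) and
#'   `availability`.
#' @export
extract_ssi <- function(recs, min_control_pA = 10, skip_ms = 1) {
  rows <- lapply(recs, function(r) {
    r <- as_processed(r)
    if (!has_role(r, "control") || !has_role(r, "test"))
      stop("protocol mismatch: SSI sweep needs control and test pulses",
           call. = FALSE)
    ctrl <- window_peak(r, "control", skip_ms = skip_ms)
    if (abs(ctrl) < min_control_pA)
      stop("insufficient data: control peak below noise floor", call. = FALSE)
    test <- window_peak(r, "test", skip_ms = skip_ms)
    j <- which(r$segments$role == "conditioning")[1L]
    vc <- r$segments$v_start[j] +
      (if (is.null(r$junction_offset_applied)) 0 else r$junction_offset_applied)
    data.frame(v = vc, availability = test / ctrl)
  })
  pts <- do.call(rbind, rows)
  pts[order(pts$v), ]
}

#' Window current
#'
#' Product of steady-state availability and peak current density per
#' voltage: the sustained inward current expected at a maintained potential.
#' Availability is interpolated linearly onto the I-V voltage grid;
#' extrapolation is not performed.
#'
#' @param ssi data frame with `v` and `availability` (points or a fitted
#'   curve evaluated on a grid) or a `cav_ssi_fit`.
#' @param iv_points data frame with `v` and `i_density` from [extract_iv()].
#' @return data frame with `v`, `availability`, `i_density` and `window`
#'   (pA/pF) on the overlapping voltage grid.
#' @export
window_current <- function(ssi, iv_points) {
  if (inherits(ssi, "cav_ssi_fit")) {
    grid <- seq(min(ssi$points$v), max(ssi$points$v), by = 1)
    ssi <- data.frame(v = grid,
                      availability = ssi$plateau + (1 - ssi$plateau) /
                        (1 + exp((grid - ssi$v_half_inact) / ssi$slope_inact)))
  }
  keep <- iv_points$v >= min(ssi$v) & iv_points$v <= max(ssi$v)
  if (!any(keep)) stop("insufficient overlap: disjoint voltage ranges")
  v <- iv_points$v[keep]
  avail <- stats::approx(ssi$v, ssi$availability, xout = v, rule = 1)$y
  data.frame(v = v, availability = avail, i_density = iv_points$i_density[keep],
             window = avail * iv_points$i_density[keep])
}

#' Remaining current fractions during a sustained depolarization
#'
#' Percentage of the peak current remaining at fixed offsets after the peak
#' of a prolonged (typically 5-s) depolarization: r_t = 100 I(t_peak + t) /
#' I_peak. Offsets extending past the end of the pulse are evaluated at the
#' final sample.
#'
#' @param rec processed sweep containing a `"test"` segment with the
#'   sustained depolarization.
#' @param times offsets in ms (default 50, 100, 250, 500, 1000, 5000).
#' @param peak_within_ms the peak is expected within this window; a later
#'   peak raises a warning and is used as found.
#' @return named numeric vector of r values (percent).
#' @export
remaining_fractions <- function(rec, times = c(50, 100, 250, 500, 1000, 5000),
                                peak_within_ms = 50) {
  rec <- as_processed(rec)
  idx <- segment_samples(rec, "test")
  dt <- rec$meta$dt
  y <- rec$i_corr[idx]
  if (length(y) >= 3) y <- stats::runmed(y, 3)
  j_peak <- which.min(y)
  if ((j_peak - 1) * dt > peak_within_ms) {
    warning("peak current later than ", peak_within_ms,
            " ms into the depolarization; proceeding")
  }
  i_peak <- y[j_peak]
  j_t <- pmin(j_peak + round(times / dt), length(y))
  r <- 100 * y[j_t] / i_peak
  stats::setNames(r, paste0("r", times))
}

#' CDI strength parameter f
#'
#' Difference between the Ba2+ and Ca2+ remaining fractions at a matched
#' voltage and time (conventionally 250 ms), on the 0-1 scale:
#' f = (r_Ba - r_Ca) / 100. Negative values (more remaining current with
#' Ca2+ than Ba2+) are permitted but flagged with a warning.
#'
#' @param r_ba,r_ca remaining fractions in percent.
#' @return f value(s).
#' @export
cdi_f <- function(r_ba, r_ca) {
  f <- (r_ba - r_ca) / 100
  if (any(f < 0)) warning("negative f value: r_Ba < r_Ca")
  f
}

#' Fractional Ca2+-dependent component of inactivation
#'
#' CDI = 1 - r_Ca / r_Ba, the fraction of the inactivation attributable to
#' calcium at a given time point, assuming CDI and VDI act independently.
#'
#' @param r_ca,r_ba remaining fractions (percent or fraction, consistently).
#' @return CDI fraction(s).
#' @export
cdi_fraction <- function(r_ca, r_ba) {
  if (any(r_ba == 0)) stop("undefined result: r_Ba is zero")
  1 - r_ca / r_ba
}

#' Persistent current after a prolonged depolarization
#'
#' Current at the end of a 5-s depolarization as a percentage of the peak
#' current elicited by the 20-ms pre-pulse to the voltage of maximal inward
#' current in the same sweep.
#'
#' @param rec processed sweep from
#'   `build_inactivation_protocol(..., prepulse = TRUE)`.
#' @param tail_ms averaging window at the end of the test step (ms).
#' @return persistent current in percent.
#' @export
persistent_current <- function(rec, tail_ms = 5) {
  rec <- as_processed(rec)
  if (!has_role(rec, "prepulse"))
    stop("protocol mismatch: sweep has no 20-ms pre-pulse", call. = FALSE)
  peak <- window_peak(rec, "prepulse", skip_ms = 1)
  idx <- segment_samples(rec, "test")
  n_end <- max(1L, round(tail_ms / rec$meta$dt))
  i_end <- mean(rec$i_corr[utils::tail(idx, n_end)])
  100 * i_end / peak
}

#' Open-probability proxy from gating charge and tail currents
#'
#' Per-group linear regression of the peak ionic tail current on the
#' integrated ON gating charge measured at the reversal potential; the
#' slope (1/ms) is proportional to channel open probability. With two
#' groups the slopes are compared by the extra-sum-of-squares F test on the
#' interaction term.
#'
#' @param data data frame with columns `q_on` (pA*ms, > 0), `i_tail` (pA)
#'   and optionally `group` (up to two levels).
#' @param min_n minimal cells per group.
#' @return an object of class `cav_po_proxy`: per-group `slope`,
#'   `slope_se`, `r2`, and `f_statistic`/`p_value` for the two-group slope
#'   comparison.
#' @export
po_proxy <- function(data, min_n = 5) {
  stopifnot(all(c("q_on", "i_tail") %in% names(data)))
  if (any(data$q_on <= 0))
    stop("invalid argument: q_on must be > 0 for included cells")
  if (is.null(data$group)) data$group <- "all"
  data$group <- factor(data$group)
  tab <- table(data$group)
  if (any(tab < min_n))
    stop("insufficient data: need >= ", min_n, " cells per group")
  per_group <- lapply(split(data, data$group), function(d) {
    m <- stats::lm(i_tail ~ q_on, data = d)
    s <- summary(m)
    list(slope = unname(stats::coef(m)["q_on"]),
         slope_se = s$coefficients["q_on", "Std. Error"],
         r2 = s$r.squared, n = nrow(d))
  })
  fstat <- p <- NA_real_
  if (nlevels(data$group) == 2L) {
    m_full <- stats::lm(i_tail ~ q_on * group, data = data)
    m_null <- stats::lm(i_tail ~ q_on + group, data = data)
    a <- stats::anova(m_null, m_full)
    fstat <- a$F[2L]; p <- a$`Pr(>F)`[2L]
  }
  structure(list(groups = per_group, f_statistic = fstat, p_value = p),
            class = "cav_po_proxy")
}

#' Measure Q_ON and peak tail current from a gating-current sweep
#'
#' Integrates the outward ON gating transient over the onset of the
#' depolarizing pre-pulse (recorded at the reversal potential, where no
#' ionic current flows) and measures the peak ionic tail current after
#' repolarization.
#'
#' @param rec processed sweep from [build_tail_protocol()] simulated with
#'   `include_gating = TRUE` and `pre_v` at the reversal potential.
#' @param integrate_ms integration window for the ON charge (ms).
#' @return named vector `c(q_on = pA*ms, i_tail = pA)`.
#' @export
measure_qon_itail <- function(rec, integrate_ms = 5) {
  rec <- as_processed(rec)
  idx_pre <- segment_samples(rec, "pre")
  dt <- rec$meta$dt
  idx_pre <- idx_pre[seq_len(min(length(idx_pre), round(integrate_ms / dt)))]
  q_on <- sum(pmax(rec$i_corr[idx_pre], 0)) * dt
  i_tail <- window_peak(rec, "tail", skip_ms = 0)
  c(q_on = q_on, i_tail = i_tail)
}

#' Conductance-scaled plateau current at a subthreshold voltage
#'
#' Rescales a sustained-depolarization trace (normalized to the peak current
#' at the voltage of maximal inward current, measured by the pre-pulse in
#' the same sweep) by the steady-state conductance at the test voltage,
#' making currents comparable across constructs with different activation
#' midpoints. Reports the scaled value at the trace peak and at 300 ms.
#'
#' @param rec processed sweep from
#'   `build_inactivation_protocol(..., prepulse = TRUE)` with the test step
#'   at the subthreshold voltage (e.g. -20 mV).
#' @param conductance_at_v normalized conductance at the test voltage (from
#'   the activation curve).
#' @return list with `trace` (data frame `t`, `y`), `value_at_peak`,
#'   `value_at_300ms`.
#' @export
normalized_plateau_current <- function(rec, conductance_at_v) {
  rec <- as_processed(rec)
  if (!has_role(rec, "prepulse"))
    stop("protocol mismatch: sweep has no normalizing pre-pulse", call. = FALSE)
  ref <- window_peak(rec, "prepulse", skip_ms = 1)
  idx <- segment_samples(rec, "test")
  dt <- rec$meta$dt
  y <- rec$i_corr[idx] / abs(ref) * conductance_at_v
  t <- (seq_along(idx) - 0.5) * dt
  j300 <- min(length(y), round(300 / dt))
  sm <- if (length(y) >= 3) stats::runmed(y, 3) else y
  list(trace = data.frame(t = t, y = y),
       value_at_peak = sm[which.max(abs(sm))],
       value_at_300ms = y[j300])
}
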