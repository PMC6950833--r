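# Nonlinear fits of the standard voltage-clamp relationships. All fits use
# Levenberg-Marquardt least squares (minpack.lm::nlsLM) with data-driven
# starting values and physically bounded slopes.

fit_failure <- function(msg) stop(paste("fit failure:", msg), call. = FALSE)

safe_nlsLM <- function(formula, data, start, lower = NULL, upper = NULL) {
  args <- list(formula, data = data, start = start,
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
}

#' Fit the current-voltage relationship
#'
#' Least-squares fit of peak currents to
#' `I = G_max (V - V_rev) / (1 + exp(-(V - V_0.5)/k))`, the product of a
#' linear-ohmic driving force and a Boltzmann activation term.
#'
#' @param points data frame with columns `v` (mV) and `i` (peak current, pA
#'   or pA/pF) — e.g. from [extract_iv()].
#' @return an object of class `cav_iv_fit`: `g_max`, `v_rev`, `v_half`,
#'   `slope` with standard errors, `residual_sse`, an `identifiable` flag
#'   and the input points.
#' @export
fit_iv <- function(points) {
  stopifnot(all(c("v", "i") %in% names(points)))
  points <- points[order(points$v), ]
  v <- points$v; i <- points$i
  if (length(v) < 6) fit_failure("need >= 6 I-V points")
  j_min <- which.min(i)
  if (all(abs(i) < 1e-12)) stop("insufficient data: all currents are zero")
  # a (near-)perfect line carries no activation signature: V0.5 runs off to
  # minus infinity and the Boltzmann term is unidentifiable
  lin <- stats::lm(i ~ v)
  r2_lin <- suppressWarnings(summary(lin)$r.squared)
  if (r2_lin > 0.9999) {
    cf_lin <- stats::coef(lin)
    return(structure(list(g_max = unname(cf_lin[2]),
                          v_rev = unname(-cf_lin[1] / cf_lin[2]),
                          v_half = -Inf, slope = NA_real_,
                          se = c(g_max = NA_real_, v_rev = NA_real_,
                                 v_half = NA_real_, slope = NA_real_),
                          residual_sse = sum(stats::resid(lin)^2),
                          identifiable = FALSE, points = points),
                     class = "cav_iv_fit"))
  }
  # reversal guess: zero crossing depolarized of the minimum
  vrev0 <- {
    up <- j_min:length(v)
    cross <- which(i[up] >= 0)[1L]
    if (!is.na(cross) && cross > 1) {
      k2 <- up[cross]; k1 <- k2 - 1L
      v[k1] + (0 - i[k1]) * (v[k2] - v[k1]) / (i[k2] - i[k1])
    } else max(v) + 10
  }
  gmax0 <- max(abs(i[j_min]) / abs(v[j_min] - vrev0), 1e-4)
  half <- which(i[1:j_min] <= i[j_min] / 2)[1L]
  vhalf0 <- if (!is.na(half)) v[half] else v[j_min] - 10
  fit <- safe_nlsLM(i ~ gmax * (v - vrev) / (1 + exp(-(v - vhalf) / k)),
                    data.frame(v = v, i = i),
                    start = list(gmax = gmax0, vrev = vrev0,
                                 vhalf = vhalf0, k = 8),
                    lower = c(1e-6, min(v), min(v) - 150, 0.5),
                    upper = c(Inf, max(v) + 150, max(v), 30))
  if (inherits(fit, "error")) fit_failure(conditionMessage(fit))
  cf <- summary(fit)$coefficients
  identifiable <- cf["vhalf", "Estimate"] > min(v) - 100 &&
    is.finite(cf["vhalf", "Std. Error"]) && cf["vhalf", "Std. Error"] < 50
  structure(list(g_max = cf["gmax", "Estimate"], v_rev = cf["vrev", "Estimate"],
                 v_half = cf["vhalf", "Estimate"], slope = cf["k", "Estimate"],
                 se = c(g_max = cf["gmax", "Std. Error"],
                        v_rev = cf["vrev", "Std. Error"],
                        v_half = cf["vhalf", "Std. Error"],
                        slope = cf["k", "Std. Error"]),
                 residual_sse = sum(stats::resid(fit)^2),
                 identifiable = identifiable, points = points, fit = fit),
            class = "cav_iv_fit")
}

#' Conductance transform of an I-V relationship
#'
#' G(V) = I / (V - V_rev), normalized to its maximum. Voltages within
#' `exclude_mv` of the reversal potential are excluded (singularity guard).
#'
#' @param points data frame with `v` and `i` columns.
#' @param v_rev reversal potential (mV), typically from [fit_iv()].
#' @param exclude_mv exclusion radius around `v_rev` (mV).
#' @return data frame with `v` and normalized conductance `g`.
#' @export
conductance_transform <- function(points, v_rev, exclude_mv = 2) {
  keep <- abs(points$v - v_rev) >= exclude_mv
  if (!any(keep)) stop("insufficient data: all points within reversal guard")
  g <- points$i[keep] / (points$v[keep] - v_rev)
  gmax <- max(g)
  if (gmax <= 0) stop("insufficient data: non-positive conductances")
  data.frame(v = points$v[keep], g = g / gmax)
}

#' Fit a Boltzmann activation curve
#'
#' Fits normalized conductance to `G = 1 / (1 + exp(-(V - V_0.5)/k))`.
#'
#' @param gv_points data frame with `v` and normalized `g` columns.
#' @return an object of class `cav_act_fit`: `v_half_act`, `slope_act`,
#'   standard errors, `identifiable` flag and the points.
#' @export
fit_boltzmann <- function(gv_points) {
  stopifnot(all(c("v", "g") %in% names(gv_points)))
  v <- gv_points$v; g <- gv_points$g
  if (length(v) < 6) fit_failure("need >= 6 G-V points")
  if (diff(range(g)) < 0.1) {
    return(structure(list(v_half_act = NA_real_, slope_act = NA_real_,
                          se = c(v_half_act = NA_real_, slope_act = NA_real_),
                          identifiable = FALSE, points = gv_points),
                     class = "cav_act_fit"))
  }
  vhalf0 <- v[which.min(abs(g - 0.5))]
  fit <- safe_nlsLM(g ~ 1 / (1 + exp(-(v - vhalf) / k)),
                    data.frame(v = v, g = g),
                    start = list(vhalf = vhalf0, k = 8),
                    lower = c(min(v) - 100, 0.5), upper = c(max(v) + 100, 30))
  if (inherits(fit, "error")) fit_failure(conditionMessage(fit))
  cf <- summary(fit)$coefficients
  structure(list(v_half_act = cf["vhalf", "Estimate"],
                 slope_act = cf["k", "Estimate"],
                 se = c(v_half_act = cf["vhalf", "Std. Error"],
                        slope_act = cf["k", "Std. Error"]),
                 residual_sse = sum(stats::resid(fit)^2),
                 identifiable = TRUE, points = gv_points, fit = fit),
            class = "cav_act_fit")
}

#' Fit a steady-state inactivation curve
#'
#' Fits availability to the modified Boltzmann
#' `G = (1 - plateau) / (1 + exp((V - V_0.5,inact)/k_inact)) + plateau`,
#' where the plateau is the non-inactivating fraction.
#'
#' @param ssi_points data frame with `v` (conditioning voltage, mV) and
#'   `availability` (test/control ratio) columns.
#' @return an object of class `cav_ssi_fit`: `v_half_inact`, `slope_inact`,
#'   `plateau` with standard errors.
#' @export
fit_ssi <- function(ssi_points) {
  stopifnot(all(c("v", "availability") %in% names(ssi_points)))
  v <- ssi_points$v; y <- ssi_points$availability
  if (length(v) < 6) fit_failure("need >= 6 conditioning voltages")
  vhalf0 <- v[which.min(abs(y - (max(y) + min(y)) / 2))]
  fit <- safe_nlsLM(y ~ plateau + (1 - plateau) / (1 + exp((v - vhalf) / k)),
                    data.frame(v = v, y = y),
                    start = list(plateau = max(min(y), 0), vhalf = vhalf0, k = 5),
                    lower = c(0, min(v) - 100, 0.5),
                    upper = c(0.9, max(v) + 100, 30))
  if (inherits(fit, "error")) fit_failure(conditionMessage(fit))
  cf <- summary(fit)$coefficients
  structure(list(v_half_inact = cf["vhalf", "Estimate"],
                 slope_inact = cf["k", "Estimate"],
                 plateau = cf["plateau", "Estimate"],
                 se = c(v_half_inact = cf["vhalf", "Std. Error"],
                        slope_inact = cf["k", "Std. Error"],
                        plateau = cf["plateau", "Std. Error"]),
                 residual_sse = sum(stats::resid(fit)^2),
                 points = ssi_points, fit = fit),
            class = "cav_ssi_fit")
}

tail_curve <- function(t, a_fast, tau_fast, a_slow, tau_slow, c0) {
  slow <- if (is.na(tau_slow)) 0 else a_slow * exp(-t / tau_slow)
  a_fast * exp(-t / tau_fast) + slow + c0
}

#' Bi-exponential tail-current fit
#'
#' Fits a normalized deactivating tail transient to
#' `y(t) = A_fast exp(-t/tau_fast) + A_slow exp(-t/tau_slow) + C`.
#' The input is either a processed sweep from a tail protocol (the segment
#' with role `"tail"` is used) or a data frame with columns `t` (ms from
#' repolarization) and `y`. Sweep input is normalized to the extremum of the
#' first `norm_within_ms` after repolarization. If the two time constants do
#' not separate by at least `min_tau_ratio` (or the bi-exponential fit fails
#' to converge), a single-exponential fallback is fitted and flagged in
#' `model`.
#'
#' The half width is the full width at half-extremum of the fitted
#' transient; with an instantaneous rising phase the left crossing is 0, so
#' it equals the time at which the fitted curve decays through half its
#' initial value. `norm_area` is the analytic integral of the fitted curve
#' over the fit window.
#'
#' @param x processed `cav_sweep` or data frame with `t`, `y`.
#' @param window_ms fit window after repolarization (ms).
#' @param norm_within_ms window used to locate the normalizing extremum.
#' @param min_tau_ratio minimal tau_slow/tau_fast separation.
#' @return an object of class `cav_tail_fit`: `tau_fast`, `tau_slow`,
#'   `a_fast`, `a_slow`, `c`, `half_width`, `norm_area`, `model`
#'   (`"biexp"` or `"single"`).
#' @export
fit_tail <- function(x, window_ms = 20, norm_within_ms = 0.5,
                     min_tau_ratio = 1.5) {
  if (is.data.frame(x)) {
    t <- x$t; y <- x$y
  } else {
    rec <- as_processed(x)
    idx <- segment_samples(rec, "tail")
    dt <- rec$meta$dt
    t <- (seq_along(idx) - 1) * dt
    keep <- t <= window_ms
    t <- t[keep]
    yraw <- rec$i_corr[idx][keep]
    norm_idx <- which(t <= norm_within_ms)
    ext <- yraw[norm_idx][which.max(abs(yraw[norm_idx]))]
    y <- yraw / abs(ext)
  }
  c0 <- mean(y[t >= max(t) * 0.9])
  y0 <- y[1L]
  amp <- y0 - c0
  start <- list(af = 0.65 * amp, tf = 0.2, as = 0.35 * amp, ts = 2, c0 = c0)
  lo <- c(-2, 0.01, -2, 0.02, -1)
  hi <- c(2, 50, 2, 200, 1)
  fit <- safe_nlsLM(y ~ af * exp(-t / tf) + as * exp(-t / ts) + c0,
                    data.frame(t = t, y = y), start, lo, hi)
  single <- FALSE
  if (!inherits(fit, "error")) {
    cf <- stats::coef(fit)
    # order components: fast first
    if (cf[["tf"]] > cf[["ts"]]) {
      cf <- c(af = cf[["as"]], tf = cf[["ts"]], as = cf[["af"]],
              ts = cf[["tf"]], c0 = cf[["c0"]])
    }
    if (cf[["ts"]] / cf[["tf"]] < min_tau_ratio) single <- TRUE
  } else single <- TRUE
  if (single) {
    fit1 <- safe_nlsLM(y ~ a * exp(-t / tau) + c0, data.frame(t = t, y = y),
                       list(a = amp, tau = 0.5, c0 = c0),
                       c(-2, 0.01, -1), c(2, 200, 1))
    if (inherits(fit1, "error")) fit_failure(conditionMessage(fit1))
    cf1 <- stats::coef(fit1)
    cf <- c(af = cf1[["a"]], tf = cf1[["tau"]], as = 0, ts = NA_real_,
            c0 = cf1[["c0"]])
    fit <- fit1
  }
  pars <- list(a_fast = unname(cf[["af"]]), tau_fast = unname(cf[["tf"]]),
               a_slow = unname(cf[["as"]]), tau_slow = unname(cf[["ts"]]),
               c = unname(cf[["c0"]]))
  Tw <- max(t)
  yfit0 <- tail_curve(0, pars$a_fast, pars$tau_fast, pars$a_slow,
                      pars$tau_slow, pars$c)
  tgrid <- seq(0, Tw, length.out = 4000)
  yg <- tail_curve(tgrid, pars$a_fast, pars$tau_fast, pars$a_slow,
                   pars$tau_slow, pars$c)
  cross <- which(abs(yg) <= abs(yfit0) / 2)[1L]
  half_width <- if (is.na(cross)) NA_real_ else tgrid[cross]
  area_slow <- if (is.na(pars$tau_slow)) 0 else
    pars$a_slow * pars$tau_slow * (1 - exp(-Tw / pars$tau_slow))
  norm_area <- pars$a_fast * pars$tau_fast * (1 - exp(-Tw / pars$tau_fast)) +
    area_slow + pars$c * Tw
  structure(c(pars, list(half_width = half_width, norm_area = norm_area,
                         model = if (single) "single" else "biexp",
                         residual_sse = sum(stats::resid(fit)^2),
                         t = t, y = y)),
            class = "cav_tail_fit")
}
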