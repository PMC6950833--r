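#!/usr/bin/env Rscript
# Calibrates the packaged variant parameter sets against the published
# construct tables and regenerates R/presets-data.R.
#
# Boltzmann activation/SSI midpoints, slopes and reversal potentials enter
# the model directly but are nudged (fixed-point style, via an objective
# that evaluates the analysis pipeline's fitted values) so that the
# *measured* parameters -- G-V Boltzmann fit, SSI fit (Ba configuration),
# 5-s inactivation r values (Ba and Ca) and tail time constants -- match
# the published numbers. Run from the repository root with the package
# installed:
#   Rscript scripts/calibrate.R

suppressMessages(library(cavclamp))

## ---- published targets (junction-corrected mV; r values in percent) ----
targets <- list(
  WT_L = list(act = c(v = -0.18, k = 9.63), vrev = 71.1,
              ssi = c(v = -25.7, k = 5.64), plateau = 0.225,
              rba = c(92.55, 88.74, 79.10, 68.4, 57.37, 30.26),
              rca = c(65.6, 54.5, 36.9, 24.9, 16.9, 8.60),
              tail = list(tau_fast = c(`-60` = 0.16, `-40` = 0.19),
                          tau_slow_40 = 1.12, slow_frac_40 = 0.24 / (0.65 + 0.24)),
              g_max = 8.6, q_on = 158.9, ic50 = 60.3),
  S652L_L = list(act = c(v = -16.3, k = 8.27), vrev = 59.9,
                 ssi = c(v = -43.3, k = 4.99), plateau = 0.128,
                 rba = c(86.78, 76.91, 59.05, 47.17, 36.33, 17.24),
                 rca = c(52.8, 35.2, 17.1, 10.8, 8.04, 5.33),
                 tail = list(tau_fast = c(`-60` = 0.20, `-40` = 0.39),
                             tau_slow_40 = 1.95, slow_frac_40 = 0.54 / (0.29 + 0.54)),
                 g_max = 5.5, q_on = 140.3, ic50 = 18.1),
  WT_S = list(act = c(v = -10.6, k = 7.65), vrev = 64.7,
              ssi = c(v = -31.2, k = 4.78), plateau = 0.121,
              rba = c(93.57, 88.24, 76.96, 64.48, 50.89, 25.67),
              rca = c(29.3, 23.3, 17.1, 12.9, 10.1, 6.21),
              tail = list(tau_fast = c(`-60` = 0.16, `-40` = 0.19),
                          tau_slow_40 = 1.12, slow_frac_40 = 0.27),
              g_max = 8, q_on = 30, ic50 = 60.3),
  S652L_S = list(act = c(v = -23.5, k = 7.32), vrev = 58.4,
                 ssi = c(v = -47.2, k = 4.24), plateau = 0.0914,
                 rba = c(84.74, 72.67, 53.91, 40.74, 29.98, 15.27),
                 rca = c(26.4, 17.6, 10.5, 7.11, 6.15, 3.34),
                 tail = list(tau_fast = c(`-60` = 0.20, `-40` = 0.39),
                             tau_slow_40 = 1.95, slow_frac_40 = 0.65),
                 g_max = 6, q_on = 30, ic50 = 18.1),
  # loss-of-function variant: activation/SSI from its own table; kinetics
  # shared with the wild-type long backbone (no published Ba series); the
  # Ca time course is its own published series.
  S652W_L = list(act = c(v = 4.23, k = 8.73), vrev = 64.6,
                 ssi = c(v = -13.1, k = 5.73), plateau = 0.151,
                 rba = c(92.55, 88.74, 79.10, 68.4, 57.37, 30.26),
                 rca = c(62.86, 49.49, 31.35, 20.61, 13.85, 6.35),
                 tail = list(tau_fast = c(`-60` = 0.16, `-40` = 0.19),
                             tau_slow_40 = 1.12, slow_frac_40 = 0.27),
                 g_max = 8.6, q_on = 150, ic50 = 60.3)
)
r_times <- c(50, 100, 250, 500, 1000, 5000)

noiseless <- function(carrier = "Ca", dt = 0.02)
  sim_config(dt = dt, noise_sd = 0, leak_conductance = 0, junction_offset = 0,
             carrier = carrier)

make_variant <- function(tg, th) {
  variant_params("tmp",
    v_half_act = th[["vha"]], slope_act = th[["ka"]],
    g_max = tg$g_max, v_rev = tg$vrev,
    tau_act_min = th[["tact_min"]], tau_act_max = 1.2,
    tau_act_v = th[["vha"]], tau_act_k = th[["tact_k"]],
    frac_fast = th[["ff"]], frac_slow = 1 - th[["ff"]] - th[["fp"]],
    frac_persistent = th[["fp"]],
    tau_fast_0 = th[["tf0"]], tau_slow_0 = th[["ts0"]], tau_v_dep = th[["tvd"]],
    v_half_inact = th[["vhi"]], slope_inact = th[["ki"]],
    cdi_coupling = th[["cdi_c"]], tau_cdi_recovery = th[["cdi_tr"]],
    tail_slow_frac = tg$tail$slow_frac_40, tau_tail_slow = tg$tail$tau_slow_40,
    q_on_total = tg$q_on, ic50 = tg$ic50)
}

## ---- step 1: activation time constants from the tail tau_fast targets ----
solve_tact <- function(tg) {
  vh <- tg$act[["v"]]
  f <- function(par) {
    b <- exp(par[1]); k <- exp(par[2])
    tt <- b + 1.2 / cosh((c(-60, -40) - vh) / k)
    sum((tt - tg$tail$tau_fast)^2)
  }
  o <- optim(c(log(0.15), log(12)), f)
  c(tact_min = exp(o$par[1]), tact_k = exp(o$par[2]))
}

## ---- step 2: analytic Ba-side model for the VDI/SSI joint fit ----
hinf <- function(v, vhi, ki) plogis(-(v - vhi) / ki)
tau_vdi <- function(v, tau0, vhi, tvd) tau0 / cosh((v - vhi) / tvd)

vmax_true <- function(tg) {
  grid <- seq(-89, 65, by = 5)
  m <- plogis((grid - tg$act[["v"]]) / tg$act[["k"]])
  grid[which.min(m * (grid - tg$vrev))]
}

ba_r_model <- function(th, vmax, t_peak = 2) {
  h0 <- hinf(-89, th[["vhi"]], th[["ki"]])
  hv <- hinf(vmax, th[["vhi"]], th[["ki"]])
  tf <- tau_vdi(vmax, th[["tf0"]], th[["vhi"]], th[["tvd"]])
  ts <- tau_vdi(vmax, th[["ts0"]], th[["vhi"]], th[["tvd"]])
  hvdi <- function(t) th[["ff"]] * (hv + (h0 - hv) * exp(-t / tf)) +
    (1 - th[["ff"]] - th[["fp"]]) * (hv + (h0 - hv) * exp(-t / ts)) +
    th[["fp"]]
  100 * hvdi(t_peak + r_times) / hvdi(t_peak)
}

ssi_fit_model <- function(th, cond_ms = 5000) {
  vc <- seq(-109, 41, by = 10)
  h0 <- hinf(-89, th[["vhi"]], th[["ki"]])
  hv <- hinf(vc, th[["vhi"]], th[["ki"]])
  tf <- tau_vdi(vc, th[["tf0"]], th[["vhi"]], th[["tvd"]])
  ts <- tau_vdi(vc, th[["ts0"]], th[["vhi"]], th[["tvd"]])
  A <- th[["ff"]] * (hv + (h0 - hv) * exp(-cond_ms / tf)) +
    (1 - th[["ff"]] - th[["fp"]]) * (hv + (h0 - hv) * exp(-cond_ms / ts)) +
    th[["fp"]]
  fit_ssi(data.frame(v = vc, availability = A))
}

calibrate_vdi <- function(tg) {
  vmax <- vmax_true(tg)
  obj <- function(par) {
    th <- c(ff = plogis(par[1]), fp = 0.5 * plogis(par[2]),
            tf0 = exp(par[3]), ts0 = exp(par[4]), tvd = exp(par[5]),
            vhi = par[6], ki = exp(par[7]))
    if (th[["ff"]] + th[["fp"]] > 0.98) return(1e6)
    if (th[["ki"]] < 0.5 * tg$ssi[["k"]] || th[["ki"]] > 2 * tg$ssi[["k"]])
      return(1e6)
    r <- ba_r_model(th, vmax)
    s <- tryCatch(ssi_fit_model(th), error = function(e) NULL)
    if (is.null(s)) return(1e6)
    w_r <- c(2, 2, 2, 2, 2, 6)
    sum(w_r * (r - tg$rba)^2) +
      6 * (100 * (s$plateau - tg$plateau))^2 +
      16 * (s$v_half_inact - tg$ssi[["v"]])^2 +
      16 * (s$slope_inact - tg$ssi[["k"]])^2 +
      0.5 * (100 * (th[["fp"]] - tg$plateau))^2
  }
  p0 <- c(qlogis(0.4), qlogis(2 * 0.2), log(120), log(2500), log(23),
          tg$ssi[["v"]], log(tg$ssi[["k"]]))
  o <- optim(p0, obj, control = list(maxit = 4000, reltol = 1e-10))
  o <- optim(o$par, obj, control = list(maxit = 4000, reltol = 1e-10))
  par <- o$par
  list(th = c(ff = plogis(par[1]), fp = 0.5 * plogis(par[2]),
              tf0 = exp(par[3]), ts0 = exp(par[4]), tvd = exp(par[5]),
              vhi = par[6], ki = exp(par[7])),
       value = o$value, vmax = vmax)
}

## ---- step 3: CDI coupling/recovery against the Ca r values (kernel sim) --
sim_r <- function(p, vmax, carrier, dt = 0.02) {
  prot <- build_inactivation_protocol(-89, vmax, leak_step = FALSE)
  rec <- simulate_protocol(p, prot, noiseless(carrier, dt))[[1]]
  remaining_fractions(correct_junction(rec, 0))
}

calibrate_cdi <- function(tg, th, w250 = 4) {
  vmax <- vmax_true(tg)
  obj <- function(par) {
    th2 <- th
    th2[["cdi_c"]] <- exp(par[1]); th2[["cdi_tr"]] <- exp(par[2])
    p <- make_variant(tg, th2)
    r <- sim_r(p, vmax, "Ca", dt = 0.05)
    w <- c(1, 1, w250, 1, 1, 1)
    sum(w * (r - tg$rca)^2)
  }
  o <- optim(c(log(2e-5), log(2000)), obj,
             control = list(maxit = 200, reltol = 1e-8))
  c(cdi_c = exp(o$par[1]), cdi_tr = exp(o$par[2]))
}

## ---- step 4: nudge activation so the pipeline G-V fit lands on target ----
# Activation is calibrated in the Ba (CDI-free) configuration, like the
# SSI curve: the instantaneous-flux CDI gate already bites at the peak of
# large mid-voltage currents and would otherwise distort the G-V transform.
measure_act <- function(p, dt = 0.02) {
  prot <- build_iv_protocol(-89, -89, 65, 5, 50)
  recs <- simulate_protocol(p, prot, noiseless("Ba", dt))
  a <- analyze_iv(preprocess_sweeps(recs, offset = 0, leak = "none"),
                  exclude_mv = 8)
  c(v = a$activation$v_half_act, k = a$activation$slope_act, vmax = a$v_max)
}

nudge_act <- function(tg, th, iters = 6, damp = 0.7) {
  th[["vha"]] <- tg$act[["v"]]; th[["ka"]] <- tg$act[["k"]]
  best <- th; best_err <- Inf
  for (i in seq_len(iters)) {
    m <- measure_act(make_variant(tg, th), dt = 0.05)
    err <- abs(tg$act[["v"]] - m[["v"]]) + abs(tg$act[["k"]] - m[["k"]])
    if (err < best_err) { best <- th; best_err <- err }
    if (err < 0.02) break
    th[["vha"]] <- th[["vha"]] + damp * (tg$act[["v"]] - m[["v"]])
    th[["ka"]] <- th[["ka"]] * (tg$act[["k"]] / m[["k"]])^damp
    th[["ka"]] <- min(max(th[["ka"]], 0.5 * tg$act[["k"]]), 2 * tg$act[["k"]])
  }
  best
}

## ---- step 5: verify SSI through the full pipeline and nudge once --------
measure_ssi <- function(p, vmax, dt = 0.02) {
  prot <- build_ssi_protocol(-89, vmax, -109, 41, 10)
  recs <- simulate_protocol(p, prot, noiseless("Ba", dt))
  fit_ssi(extract_ssi(preprocess_sweeps(recs, offset = 0, leak = "none")))
}

# One-shot midpoint correction for the (small) pipeline-vs-analytic offset;
# slope and plateau are owned by the joint optimizer above.
nudge_ssi <- function(tg, th, iters = 2) {
  vmax <- vmax_true(tg)
  for (i in seq_len(iters)) {
    s <- measure_ssi(make_variant(tg, th), vmax, dt = 0.05)
    th[["vhi"]] <- th[["vhi"]] + (tg$ssi[["v"]] - s$v_half_inact)
  }
  th
}

## ---- run ---------------------------------------------------------------
out <- list()
for (nm in names(targets)) {
  tg <- targets[[nm]]
  cat("==", nm, "==\n")
  tact <- solve_tact(tg)
  vdi <- calibrate_vdi(tg)
  th <- c(vha = tg$act[["v"]], ka = tg$act[["k"]], tact, vdi$th,
          cdi_c = 2e-5, cdi_tr = 2000)
  th <- nudge_ssi(tg, th)
  th <- nudge_act(tg, th)
  cdi <- calibrate_cdi(tg, th)
  th[["cdi_c"]] <- cdi[["cdi_c"]]; th[["cdi_tr"]] <- cdi[["cdi_tr"]]
  p <- make_variant(tg, th)
  # report
  m <- measure_act(p)
  s <- measure_ssi(p, vdi$vmax)
  rba <- sim_r(p, vdi$vmax, "Ba")
  rca <- sim_r(p, vdi$vmax, "Ca")
  cat(sprintf("  act: v %.2f (tgt %.2f)  k %.2f (tgt %.2f)\n",
              m[["v"]], tg$act[["v"]], m[["k"]], tg$act[["k"]]))
  cat(sprintf("  ssi: v %.2f (tgt %.2f)  k %.2f (tgt %.2f)  plat %.3f (tgt %.3f)\n",
              s$v_half_inact, tg$ssi[["v"]], s$slope_inact, tg$ssi[["k"]],
              s$plateau, tg$plateau))
  cat("  rBa:", paste(sprintf("%.1f/%.1f", rba, tg$rba), collapse = " "), "\n")
  cat("  rCa:", paste(sprintf("%.1f/%.1f", rca, tg$rca), collapse = " "), "\n")
  out[[nm]] <- list(tg = tg, th = th)
}

## ---- emit R/presets-data.R ----------------------------------------------
fmt <- function(x) formatC(x, digits = 10, format = "g")
lines <- c(
"# Packaged Cav1.3 variant parameter sets. Boltzmann/reversal values are the",
"# published construct parameters (junction-corrected voltage scale);",
"# kinetic, CDI and tail parameters were calibrated with scripts/calibrate.R",
"# so that the simulated recordings, analyzed through this package's",
"# pipeline, reproduce the published activation/inactivation parameters and",
"# 5-s inactivation time courses. Regenerated by scripts/calibrate.R.", "",
".cav13_presets <- list(")
for (nm in names(out)) {
  tg <- out[[nm]]$tg; th <- out[[nm]]$th
  lines <- c(lines, sprintf("  %s = list(variant = \"%s\",", nm, nm),
    sprintf("    v_half_act = %s, slope_act = %s, g_max = %s, v_rev = %s,",
            fmt(th[["vha"]]), fmt(th[["ka"]]), fmt(tg$g_max), fmt(tg$vrev)),
    sprintf("    tau_act_min = %s, tau_act_max = 1.2, tau_act_v = %s, tau_act_k = %s,",
            fmt(th[["tact_min"]]), fmt(th[["vha"]]), fmt(th[["tact_k"]])),
    sprintf("    frac_fast = %s, frac_slow = %s, frac_persistent = %s,",
            fmt(th[["ff"]]), fmt(1 - th[["ff"]] - th[["fp"]]), fmt(th[["fp"]])),
    sprintf("    tau_fast_0 = %s, tau_slow_0 = %s, tau_v_dep = %s,",
            fmt(th[["tf0"]]), fmt(th[["ts0"]]), fmt(th[["tvd"]])),
    sprintf("    v_half_inact = %s, slope_inact = %s,",
            fmt(th[["vhi"]]), fmt(th[["ki"]])),
    sprintf("    cdi_coupling = %s, tau_cdi_recovery = %s,",
            fmt(th[["cdi_c"]]), fmt(th[["cdi_tr"]])),
    sprintf("    tail_slow_frac = %s, tau_tail_slow = %s,",
            fmt(tg$tail$slow_frac_40), fmt(tg$tail$tau_slow_40)),
    sprintf("    q_on_total = %s, tau_q = 0.4,", fmt(tg$q_on)),
    sprintf("    ic50 = %s, rundown_rate = 3),", fmt(tg$ic50)))
}
lines[length(lines)] <- sub("\\),$", ")", lines[length(lines)])
lines <- c(lines, ")")
writeLines(lines, "R/presets-data.R")
cat("wrote R/presets-data.R\n")
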