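#' Simulator configuration
#'
#' Acquisition- and cell-level settings for the synthetic whole-cell
#' recordings: integration/sampling step, current noise, linear leak, cell
#' capacitance, charge carrier, the liquid-junction offset the "amplifier"
#' does not correct for, and the random seed.
#'
#' The simulated membrane voltage is `command + junction_offset`, mirroring
#' acquisition reality: protocols hold command voltages, the analysis side
#' corrects them with [correct_junction()].
#'
#' @param dt sample interval in ms (0 < dt <= 0.1; 0.02 ms = 50 kHz).
#' @param noise_sd Gaussian current-noise SD (pA, >= 0).
#' @param leak_conductance linear leak conductance (nS).
#' @param leak_reversal leak reversal potential (mV).
#' @param capacitance cell capacitance (pF, > 0).
#' @param carrier charge carrier, `"Ca"` (enables CDI) or `"Ba"`.
#' @param junction_offset liquid-junction offset (mV), -9.3 by default.
#' @param seed integer seed for the noise generator (`NULL` = leave RNG).
#' @param include_gating add the ON gating-current transient at step onsets
#'   (used for gating-charge measurements; off by default).
#' @param enable_p4 generate P/4 leak subpulse recordings alongside each
#'   sweep.
#' @return an object of class `cav_sim_config`.
#' @export
sim_config <- function(dt = 0.02, noise_sd = 2, leak_conductance = 0.5,
                       leak_reversal = 0, capacitance = 15,
                       carrier = c("Ca", "Ba"), junction_offset = -9.3,
                       seed = NULL, include_gating = FALSE,
                       enable_p4 = FALSE) {
  carrier <- match.arg(carrier)
  if (dt <= 0 || dt > 0.1) stop("invalid argument: dt must be in (0, 0.1]")
  if (capacitance <= 0) stop("invalid argument: capacitance must be > 0")
  if (noise_sd < 0) stop("invalid argument: noise_sd must be >= 0")
  structure(list(dt = dt, noise_sd = noise_sd,
                 leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal,
                 capacitance = capacitance, carrier = carrier,
                 junction_offset = junction_offset, seed = seed,
                 include_gating = include_gating, enable_p4 = enable_p4),
            class = "cav_sim_config")
}

kernel_pars <- function(p) {
  p[c("g_max", "v_rev", "v_half_act", "slope_act", "tau_act_min",
      "tau_act_max", "tau_act_v", "tau_act_k", "tail_slow_frac",
      "tau_tail_slow", "frac_fast", "frac_slow", "frac_persistent",
      "tau_fast_0", "tau_slow_0", "tau_v_dep", "v_half_inact",
      "slope_inact", "cdi_coupling", "tau_cdi_recovery")]
}

# Equilibrium gating state at a constant (true) voltage.
equilibrium_state <- function(p, v) {
  m <- steady_state_activation(v, p)
  h <- steady_state_inactivation_gate(v, p)
  c(m1 = m, m2 = m, hf = h, hs = h, hcdi = 1)
}

# Relax the gating state analytically for `ms` at constant voltage v
# (no current-driven CDI: used for inter-sweep gaps at holding).
relax_state <- function(state, p, v, ms) {
  m_inf <- steady_state_activation(v, p)
  tau_m <- p$tau_act_min + p$tau_act_max / cosh((v - p$tau_act_v) / p$tau_act_k)
  h_inf <- steady_state_inactivation_gate(v, p)
  sech <- 1 / cosh((v - p$v_half_inact) / p$tau_v_dep)
  tau2 <- if (state[["m2"]] > m_inf) p$tau_tail_slow else tau_m
  c(m1 = gate_update_exact(state[["m1"]], m_inf, tau_m, ms),
    m2 = gate_update_exact(state[["m2"]], m_inf, tau2, ms),
    hf = gate_update_exact(state[["hf"]], h_inf, p$tau_fast_0 * sech, ms),
    hs = gate_update_exact(state[["hs"]], h_inf, p$tau_slow_0 * sech, ms),
    hcdi = gate_update_exact(state[["hcdi"]], 1, p$tau_cdi_recovery, ms))
}

# Exponential ON gating-current transient injected at depolarizing step
# onsets; total injected charge scales with the steady-state activation jump.
gating_current <- function(p, sweep, samp, dt) {
  ig <- numeric(length(samp$v))
  bounds <- c(0, cumsum(round(sweep$duration / dt)))
  v_prev <- sweep$v_start[1L]
  for (j in seq_len(nrow(sweep))) {
    if (sweep$kind[j] == "step" && sweep$v_start[j] > v_prev) {
      dm <- steady_state_activation(sweep$v_start[j], p) -
        steady_state_activation(v_prev, p)
      if (dm > 0) {
        q <- p$q_on_total * dm
        idx <- (bounds[j] + 1L):length(ig)
        trel <- (seq_along(idx) - 0.5) * dt
        ig[idx] <- ig[idx] + q / p$tau_q * exp(-trel / p$tau_q)
      }
    }
    v_prev <- sweep$v_end[j]
  }
  ig
}

#' Simulate a single voltage-clamp sweep
#'
#' Integrates the gating model along the sampled command voltage and returns
#' a synthetic recording. The ionic current is
#' `g_max * m * h_vdi * h_cdi * (1 - block) * (V - v_rev)` with inward
#' current negative; the CDI gate is active only with the Ca carrier.
#' Linear leak, the optional ON gating transient and Gaussian noise are
#' added on top.
#'
#' @param p a [variant_params()] object.
#' @param sweep a segment data frame (one element of `protocol$sweeps`).
#' @param cfg a [sim_config()].
#' @param block steady-state blocked fraction (see [apply_block()]).
#' @param state0 initial gating state; defaults to equilibrium at holding.
#' @param hp command holding potential used for initial equilibrium.
#' @param g_scale multiplicative conductance scale (used for run-down).
#' @param sweep_index,protocol_name provenance metadata.
#' @return an object of class `cav_sweep` with fields `time` (ms),
#'   `command_v` (mV), `current` (pA), `capacitance`, `carrier`,
#'   `segments`, `segment_index`, `state_end` and `meta`.
#' @export
simulate_sweep <- function(p, sweep, cfg, block = 0, state0 = NULL,
                           hp = sweep$v_start[1L], g_scale = 1,
                           sweep_index = 1L, protocol_name = "sweep") {
  samp <- sample_sweep(sweep, cfg$dt)
  v_true <- samp$v + cfg$junction_offset
  if (is.null(state0))
    state0 <- equilibrium_state(p, hp + cfg$junction_offset)
  pk <- kernel_pars(p)
  pk$g_max <- pk$g_max * g_scale
  out <- sim_sweep_kernel(samp$v + cfg$junction_offset, cfg$dt, pk,
                          cfg$carrier == "Ca", block,
                          as.numeric(state0), FALSE)
  i <- out$i_ion +
    cfg$leak_conductance * (v_true - cfg$leak_reversal)
  if (cfg$include_gating)
    i <- i + gating_current(p, sweep, samp, cfg$dt)
  if (cfg$noise_sd > 0)
    i <- i + stats::rnorm(length(i), 0, cfg$noise_sd)
  structure(list(time = samp$time, command_v = samp$v, current = i,
                 capacitance = cfg$capacitance, carrier = cfg$carrier,
                 protocol_name = protocol_name, sweep_index = sweep_index,
                 segments = sweep, segment_index = samp$seg_index,
                 state_end = stats::setNames(out$state,
                                             c("m1", "m2", "hf", "hs", "hcdi")),
                 meta = list(dt = cfg$dt, hp = hp,
                             junction_offset = cfg$junction_offset,
                             variant = p$variant, g_scale = g_scale,
                             block = block)),
            class = "cav_sweep")
}

#' @export
print.cav_sweep <- function(x, ...) {
  cat(sprintf("<cav_sweep %s #%d> %s, %d samples (%.1f ms), %s carrier, %g pF\n",
              x$protocol_name, x$sweep_index, x$meta$variant,
              length(x$time), max(x$time) + x$meta$dt / 2, x$carrier,
              x$capacitance))
  invisible(x)
}

#' Simulate every sweep of a protocol
#'
#' Runs [simulate_sweep()] over a protocol, carrying the gating state across
#' sweeps and relaxing it analytically at the holding potential during the
#' inter-sweep gap (cadence minus sweep duration). With `rundown = TRUE` the
#' conductance declines linearly with elapsed time at the variant's
#' `rundown_rate` (%/min), emulating whole-cell run-down during pharmacology
#' recordings. `conc` may be a scalar or per-sweep vector of drug
#' concentrations (nM), applied as steady-state block.
#'
#' @param p a [variant_params()] object.
#' @param prot a [cav_protocol()].
#' @param cfg a [sim_config()]; `cfg$seed` (if non-`NULL`) seeds the noise
#'   generator so identical inputs give bit-identical recordings.
#' @param conc drug concentration(s), nM.
#' @param rundown apply linear run-down across sweeps.
#' @return list of [simulate_sweep()] recordings, one per sweep.
#' @export
simulate_protocol <- function(p, prot, cfg, conc = 0, rundown = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(prot$sweeps)
  conc <- rep_len(conc, n)
  hp <- prot$holding_potential
  state <- equilibrium_state(p, hp + cfg$junction_offset)
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    sw <- prot$sweeps[[k]]
    elapsed_min <- (k - 1) * prot$inter_sweep_interval / 60
    g_scale <- if (rundown) max(0, 1 - p$rundown_rate / 100 * elapsed_min) else 1
    recs[[k]] <- simulate_sweep(p, sw, cfg,
                                block = apply_block(p, conc[k]),
                                state0 = state, hp = hp, g_scale = g_scale,
                                sweep_index = k, protocol_name = prot$name)
    state <- recs[[k]]$state_end
    gap_ms <- prot$inter_sweep_interval * 1000 - sweep_duration(sw)
    if (gap_ms < -1e-9)
      stop("inter_sweep_interval shorter than sweep duration")
    if (gap_ms > 0)
      state <- relax_state(state, p, hp + cfg$junction_offset, gap_ms)
  }
  recs
}

#' Simulate a cytosolic Ca2+ fluorescence signal from an AP train
#'
#' First-order indicator model driven by the inward Ca2+ current of a
#' simulated action-potential train:
#' dF/dt = kappa * |I_Ca,inward| - (F - F0)/extrusion_tau, reported as F/F0.
#' With `extrusion_tau = Inf` the signal is proportional to cumulative
#' inward charge (pure integrator).
#'
#' @param train list of [simulate_sweep()] recordings (Ca carrier).
#' @param kappa fluorescence gain per unit inward charge (1/pC).
#' @param extrusion_tau extrusion/clearance time constant (ms); may be `Inf`.
#' @param f0 baseline fluorescence.
#' @return data frame with columns `time` (ms, across the whole train) and
#'   `f_over_f0`.
#' @export
simulate_fluorescence <- function(train, kappa, extrusion_tau = 5000,
                                  f0 = 1) {
  if (!length(train)) stop("invalid argument: empty train")
  if (train[[1L]]$carrier == "Ba")
    stop("invalid argument: fluorescence requires the Ca carrier")
  dt <- train[[1L]]$meta$dt
  i_all <- unlist(lapply(train, function(r) r$current))
  drive <- kappa * pmax(0, -i_all) * dt         # pA*ms = 1e-3 pC steps
  if (is.finite(extrusion_tau)) {
    a <- exp(-dt / extrusion_tau)
    dev <- stats::filter(drive, a, method = "recursive")
  } else {
    dev <- cumsum(drive)
  }
  f <- f0 + as.numeric(dev)
  data.frame(time = (seq_along(f) - 0.5) * dt, f_over_f0 = f / f0)
}
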