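# Shared fixtures: noiseless simulator configurations, published table
# values used as generator inputs, and hand-built sweep objects for
# analyzer unit tests.

noiseless_cfg <- function(carrier = "Ca", dt = 0.05, ...) {
  sim_config(dt = dt, noise_sd = 0, leak_conductance = 0,
             junction_offset = 0, carrier = carrier, ...)
}

# Construct a minimal sweep object with a given current trace inside a
# single "test" segment (plus holding pads), bypassing the simulator.
fake_step_sweep <- function(current, v_test = 0, dt = 1, hp = -89,
                            pad_ms = 10, capacitance = 15, extra_roles = NULL) {
  segs <- rbind(seg_step(hp, pad_ms, role = "hold"),
                if (!is.null(extra_roles)) extra_roles,
                seg_step(v_test, length(current) * dt, role = "test"),
                seg_step(hp, pad_ms, role = "hold"))
  n_per <- round(segs$duration / dt)
  idx <- rep(seq_len(nrow(segs)), n_per)
  i_full <- numeric(sum(n_per))
  i_full[idx == which(segs$role == "test")] <- current
  structure(list(time = (seq_along(i_full) - 0.5) * dt,
                 command_v = rep(segs$v_start, n_per),
                 current = i_full, capacitance = capacitance,
                 carrier = "Ca", protocol_name = "fake", sweep_index = 1L,
                 segments = segs, segment_index = idx,
                 state_end = NULL,
                 meta = list(dt = dt, hp = hp, junction_offset = 0,
                             variant = "fake")),
            class = "cav_sweep")
}

# Published Boltzmann parameters used as generators in round-trip tests.
tab_s652l_l <- list(g_max = 5, v_rev = 59.9, v_half = -16.3, k = 8.27,
                    v_half_inact = -43.3, k_inact = 4.99, plateau = 0.128)
tab_s652w_l <- list(v_half = 4.23, k = 8.73)
tab_tail_s652l_l_40 <- list(tau_fast = 0.39, tau_slow = 1.95,
                            a_fast = -0.29, a_slow = -0.54, c = -0.047)

# Pipeline measurement of activation/SSI used for packaged-set checks
# (Ba configuration; see the methods vignette for why).
pipeline_activation <- function(p, dt = 0.05) {
  recs <- simulate_protocol(p, build_iv_protocol(-89, -89, 65, 5, 50),
                            noiseless_cfg("Ba", dt))
  analyze_iv(preprocess_sweeps(recs, offset = 0, leak = "none"),
             exclude_mv = 8)
}

pipeline_ssi <- function(p, vmax, dt = 0.05) {
  recs <- simulate_protocol(p, build_ssi_protocol(-89, vmax, -109, 41, 10),
                            noiseless_cfg("Ba", dt))
  fit_ssi(extract_ssi(preprocess_sweeps(recs, offset = 0, leak = "none")))
}

pipeline_r_values <- function(p, vmax, carrier, dt = 0.05) {
  prot <- build_inactivation_protocol(-89, vmax, leak_step = FALSE)
  rec <- simulate_protocol(p, prot, noiseless_cfg(carrier, dt))[[1]]
  remaining_fractions(correct_junction(rec, 0))
}
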