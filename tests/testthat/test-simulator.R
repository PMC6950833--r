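test_that("exact gate update matches the closed-form relaxation", {
  expect_equal(gate_update_exact(0, 1, 2, 2), 1 - exp(-1))
  expect_equal(gate_update_exact(0.2, 0.2, 5, 3), 0.2)
  expect_equal(gate_update_exact(0, 1, 1, 1e6), 1)
  expect_error(gate_update_exact(0, 1, -1, 1), "tau")
})

test_that("steady-state activation is the published Boltzmann", {
  p <- cav13_variant("WT_L")
  expect_equal(steady_state_activation(p$v_half_act, p), 0.5)
  expect_equal(steady_state_activation(1e4, p), 1)
  # evaluated at the published WT_L parameters (not the calibrated set)
  ptab <- p; ptab$v_half_act <- -0.18; ptab$slope_act <- 9.63
  expect_equal(steady_state_activation(-20, ptab), 0.113, tolerance = 5e-3)
})

test_that("steady-state dihydropyridine block follows Hill with slope 1", {
  p <- cav13_variant("S652L_L")
  expect_equal(apply_block(p, p$ic50), 0.5)
  expect_equal(apply_block(p, 0), 0)
  expect_equal(apply_block(p, 9 * p$ic50), 0.9)
  expect_error(apply_block(p, -1), "concentration")
})

test_that("variant parameter validation enforces the model invariants", {
  args <- unclass(cav13_variant("WT_L"))
  args$frac_fast <- args$frac_fast + 0.1
  expect_error(do.call(variant_params, args), "sum to 1")
  args <- unclass(cav13_variant("WT_L")); args$tau_fast_0 <- -1
  expect_error(do.call(variant_params, args), "time constants")
  args <- unclass(cav13_variant("WT_L")); args$ic50 <- 0
  expect_error(do.call(variant_params, args), "ic50")
  expect_equal(variant_from_json(variant_to_json(cav13_variant("WT_S"))),
               cav13_variant("WT_S"))
})

test_that("piecewise-exact gate integration matches dense stepping on steps", {
  p <- cav13_variant("WT_L")
  pars <- cavclamp:::kernel_pars(p)
  dt <- 0.05
  v_coarse <- rep(c(-89, 10, -89), times = round(c(5, 20, 5) / dt))
  v_dense <- rep(v_coarse, each = 100)
  s0 <- cavclamp:::equilibrium_state(p, -89)
  coarse <- cavclamp:::sim_sweep_kernel(v_coarse, dt, pars, FALSE, 0,
                                        as.numeric(s0), TRUE)
  dense <- cavclamp:::sim_sweep_kernel(v_dense, dt / 100, pars, FALSE, 0,
                                       as.numeric(s0), TRUE)
  idx <- seq(100, length(v_dense), by = 100)
  expect_lt(max(abs(coarse$states - dense$states[idx, ])), 1e-6)
})

test_that("Ca and Ba runs are bit-identical when CDI coupling is zero", {
  args <- unclass(cav13_variant("S652L_L"))
  args$cdi_coupling <- 0
  p0 <- do.call(variant_params, args)
  prot <- build_iv_protocol(-89, -30, -10, 10, 50)
  ca <- simulate_protocol(p0, prot, sim_config(dt = 0.05, noise_sd = 2,
                                               carrier = "Ca", seed = 42))
  ba <- simulate_protocol(p0, prot, sim_config(dt = 0.05, noise_sd = 2,
                                               carrier = "Ba", seed = 42))
  for (k in seq_along(ca)) expect_identical(ca[[k]]$current, ba[[k]]$current)
})

test_that("zero conductance leaves leak plus noise only", {
  args <- unclass(cav13_variant("WT_L")); args$g_max <- 0
  p0 <- do.call(variant_params, args)
  cfg <- sim_config(dt = 0.05, noise_sd = 0, leak_conductance = 0.5,
                    leak_reversal = 0, junction_offset = 0)
  rec <- simulate_protocol(p0, build_iv_protocol(-89, -20, -20, 5, 50), cfg)[[1]]
  expect_equal(rec$current, 0.5 * (rec$command_v - 0), tolerance = 1e-12)
})

test_that("identical parameters, protocol, config and seed reproduce bits", {
  p <- cav13_variant("WT_L")
  cfg <- sim_config(dt = 0.05, noise_sd = 2, seed = 7)
  prot <- build_iv_protocol(-89, -40, -20, 10, 50)
  a <- simulate_protocol(p, prot, cfg)
  b <- simulate_protocol(p, prot, cfg)
  expect_identical(lapply(a, `[[`, "current"), lapply(b, `[[`, "current"))
})

test_that("open probability and availability stay inside [0, 1]", {
  p <- cav13_variant("S652L_L")
  rec <- simulate_protocol(p, build_apw_train(3, 10),
                           noiseless_cfg("Ca", 0.05))[[3]]
  po <- rec$current / (p$g_max * (rec$command_v - p$v_rev))
  expect_true(all(po >= -1e-12 & po <= 1 + 1e-12))
})

test_that("simulated fluorescence integrates inward calcium flux", {
  args <- unclass(cav13_variant("WT_L")); args$g_max <- 0
  p0 <- do.call(variant_params, args)
  cfg <- noiseless_cfg("Ca", 0.05)
  silent <- simulate_protocol(p0, build_apw_train(3, 10), cfg)
  f <- simulate_fluorescence(silent, kappa = 1e-3)
  expect_equal(unique(f$f_over_f0), 1)

  p <- cav13_variant("WT_L")
  train <- simulate_protocol(p, build_apw_train(3, 10), cfg)
  f_int <- simulate_fluorescence(train, kappa = 1e-3, extrusion_tau = Inf)
  expect_true(all(diff(f_int$f_over_f0) >= 0))
  charge <- cumsum(pmax(0, -unlist(lapply(train, `[[`, "current")))) * 0.05
  expect_equal(f_int$f_over_f0, 1 + 1e-3 * charge, tolerance = 1e-9)

  ba <- simulate_protocol(p, build_apw_train(1, 10), noiseless_cfg("Ba", 0.05))
  expect_error(simulate_fluorescence(ba, 1e-3), "Ca carrier")
})

test_that("simulator configuration rejects out-of-range settings", {
  expect_error(sim_config(dt = 0.2), "dt")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(capacitance = -1), "capacitance")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})
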