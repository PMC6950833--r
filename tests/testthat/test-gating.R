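test_that("I-V extraction picks signed peaks and breaks V_max ties low", {
  recs <- lapply(seq(-60, -20, 10), function(v)
    fake_step_sweep(rep(ifelse(v %in% c(-40, -30), -200, -100), 50),
                    v_test = v))
  pts <- extract_iv(recs, skip_ms = 0)
  expect_equal(attr(pts, "v_max"), -40)   # tie at -40/-30 broken low
  expect_equal(pts$i_density, pts$i / 15)

  expect_error(extract_iv(recs[1:3]), ">= 5")
  zero <- lapply(seq(-60, -20, 10), function(v)
    fake_step_sweep(rep(0, 50), v_test = v))
  expect_error(extract_iv(zero, skip_ms = 0), "all-zero")
})

test_that("SSI extraction returns test/control ratios per conditioning voltage", {
  p <- cav13_variant("WT_L")
  prot <- build_ssi_protocol(-89, 16, -89, -69, 10)
  recs <- simulate_protocol(p, prot, noiseless_cfg("Ba", 0.05))
  pts <- extract_ssi(preprocess_sweeps(recs, offset = 0, leak = "none"))
  # conditioning at/near holding leaves the channel fully available
  expect_equal(pts$availability[pts$v == -89], 1, tolerance = 0.01)
  expect_true(all(diff(pts$availability) <= 0.01))

  no_ctrl <- simulate_protocol(p, build_inactivation_protocol(-89, 0,
                                                              leak_step = FALSE),
                               noiseless_cfg("Ba", 0.05))
  expect_error(extract_ssi(lapply(no_ctrl, correct_junction, 0)),
               "control")
})

test_that("window current is the product of availability and density", {
  ssi <- data.frame(v = seq(-60, 0, 10),
                    availability = c(1, 0.8, 0.5, 0.2, 0, 0, 0))
  iv <- data.frame(v = seq(-60, 0, 10), i_density = rep(-3, 7))
  w <- window_current(ssi, iv)
  expect_equal(w$window[w$v == -60], -3)          # availability 1: identity
  expect_true(all(w$window[w$availability == 0] == 0))  # zero where SSI = 0
  # linear in current density
  w2 <- window_current(ssi, transform(iv, i_density = 2 * i_density))
  expect_equal(w2$window, 2 * w$window)
  expect_error(window_current(ssi, data.frame(v = 50, i_density = 1)),
               "overlap")
})

test_that("remaining fractions follow the trace relative to its peak", {
  const <- fake_step_sweep(rep(-300, 6000), dt = 1)
  r <- remaining_fractions(correct_junction(const, 0))
  expect_true(all(r == 100))

  expo <- fake_step_sweep(-300 * exp(-(seq_len(6000) - 0.5) / 250), dt = 1)
  r2 <- remaining_fractions(correct_junction(expo, 0))
  expect_equal(unname(r2[["r250"]]), 100 * exp(-1), tolerance = 1)
  expect_true(all(diff(r2) < 0))

  late <- fake_step_sweep(c(seq(-100, -300, length.out = 100),
                            rep(-300, 500)), dt = 1)
  expect_warning(remaining_fractions(correct_junction(late, 0)), "peak")
})

test_that("CDI statistics reproduce the published worked examples", {
  expect_equal(cdi_f(79.10, 36.9), 0.422, tolerance = 1e-9)
  expect_equal(cdi_f(50, 50), 0)
  expect_warning(f_neg <- cdi_f(30, 40), "negative")
  expect_lt(f_neg, 0)

  expect_equal(round(cdi_fraction(17.1, 76.96), 3), 0.778)
  expect_equal(round(cdi_fraction(10.5, 53.91), 3), 0.805)
  expect_equal(cdi_fraction(42, 42), 0)
  expect_error(cdi_fraction(10, 0), "undefined")
})

test_that("persistent current matches the end of the 5-s depolarization", {
  p <- cav13_variant("WT_L")
  vmax <- 16
  prot <- build_inactivation_protocol(-89, vmax, leak_step = FALSE,
                                      prepulse = TRUE, v_ref = vmax)
  rec <- correct_junction(simulate_protocol(p, prot,
                                            noiseless_cfg("Ba", 0.05))[[1]], 0)
  pc <- persistent_current(rec)
  r <- pipeline_r_values(p, vmax, "Ba")
  expect_equal(pc, unname(r[["r5000"]]), tolerance = 2)

  # a non-inactivating channel keeps ~100% of its pre-pulse peak
  args <- unclass(p)
  args[c("frac_fast", "frac_slow", "frac_persistent")] <- list(1e-9, 1e-9, 1 - 2e-9)
  pni <- do.call(variant_params, args)
  rec2 <- correct_junction(simulate_protocol(pni, prot,
                                             noiseless_cfg("Ba", 0.05))[[1]], 0)
  expect_equal(persistent_current(rec2), 100, tolerance = 1)

  no_pre <- correct_junction(simulate_protocol(
    p, build_inactivation_protocol(-89, vmax, leak_step = FALSE),
    noiseless_cfg("Ba", 0.05))[[1]], 0)
  expect_error(persistent_current(no_pre), "pre-pulse")
})

test_that("ON gating charge integrates to the parameterized total", {
  p <- cav13_variant("WT_L")
  cfg <- sim_config(dt = 0.02, noise_sd = 0, leak_conductance = 0,
                    junction_offset = 0, include_gating = TRUE)
  rec <- simulate_protocol(p, build_tail_protocol(p$v_rev, -60, hp = -89),
                           cfg)[[1]]
  m <- measure_qon_itail(correct_junction(rec, 0))
  dm <- steady_state_activation(p$v_rev, p) - steady_state_activation(-89, p)
  expect_equal(unname(m[["q_on"]]), p$q_on_total * dm, tolerance = 0.02)
  expect_lt(m[["i_tail"]], 0)
})

test_that("tail-slope open-probability proxy separates planted groups", {
  gen <- function(slope, n, seed) {
    set.seed(seed)
    q <- runif(n, 40, 300)
    sigma <- abs(slope) * sd(q) * sqrt(0.28 / 0.72)
    data.frame(q_on = q, i_tail = slope * q + rnorm(n, 0, sigma))
  }
  d <- rbind(cbind(gen(-7.22, 26, 1), group = "WT"),
             cbind(gen(-4.24, 25, 2), group = "mut"))
  pp <- po_proxy(d)
  expect_equal(pp$groups$WT$slope, -7.22, tolerance = 0.5)
  expect_true(pp$groups$WT$r2 > 0.5 && pp$groups$WT$r2 < 0.9)
  expect_lt(pp$p_value, 0.05)

  # power: with the published slopes, group sizes and r2, the analytic
  # (noncentral-t) power of the slope-comparison F test is ~0.80; the
  # simulated rejection rate must match it within binomial error, and
  # identical slopes must be rejected only at ~the alpha level
  n_seed <- 400
  rej_diff <- rej_same <- logical(n_seed)
  for (s in seq_len(n_seed)) {
    da <- rbind(cbind(gen(-7.22, 26, 1000 + s), group = "a"),
                cbind(gen(-4.24, 25, 2000 + s), group = "b"))
    rej_diff[s] <- po_proxy(da)$p_value < 0.05
    ds <- rbind(cbind(gen(-7.22, 26, 3000 + s), group = "a"),
                cbind(gen(-7.22, 25, 4000 + s), group = "b"))
    rej_same[s] <- po_proxy(ds)$p_value < 0.05
  }
  noise_frac <- sqrt(0.28 / 0.72)
  se_diff <- sqrt((7.22 * noise_frac)^2 / 25 + (4.24 * noise_frac)^2 / 24)
  ncp <- (7.22 - 4.24) / se_diff
  crit <- stats::qt(0.975, 47)
  predicted <- stats::pt(crit, 47, ncp, lower.tail = FALSE) +
    stats::pt(-crit, 47, ncp)
  expect_lt(abs(mean(rej_diff) - predicted),
            3 * sqrt(predicted * (1 - predicted) / n_seed) + 0.02)
  expect_gt(mean(rej_diff), 0.7)
  expect_lte(mean(rej_same), 0.1)

  expect_error(po_proxy(d[1:4, ]), "insufficient")
  expect_error(po_proxy(transform(d, q_on = -q_on)), "q_on")
})

test_that("conductance scaling of plateau currents behaves linearly", {
  p <- cav13_variant("WT_L")
  prot <- build_inactivation_protocol(-89, -20, duration = 1000,
                                      leak_step = FALSE, prepulse = TRUE,
                                      v_ref = 16)
  rec <- correct_junction(simulate_protocol(p, prot,
                                            noiseless_cfg("Ca", 0.05))[[1]], 0)
  z <- normalized_plateau_current(rec, 0)
  expect_true(all(z$trace$y == 0))
  one <- normalized_plateau_current(rec, 1)
  half <- normalized_plateau_current(rec, 0.5)
  expect_equal(half$value_at_peak, one$value_at_peak / 2)
  expect_equal(half$value_at_300ms, one$value_at_300ms / 2)
})
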