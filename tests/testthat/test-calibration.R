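# Packaged parameter sets, measured through the full analysis pipeline on
# noiseless simulations, against the published construct parameters.
#
# Tolerances: activation (0.5 mV midpoint, 0.3 mV slope) and Ca r250
# (2 percentage points) at the idealized calibration tolerances; SSI slope,
# plateau and the 5-s endpoints carry the documented structural tolerances
# of the two-gate VDI model (the published SSI plateau, Ba r_5000 and SSI
# slope are not jointly representable; see the methods vignette).

published <- list(
  WT_L    = list(act = c(-0.18, 9.63),  ssi = c(-25.7, 5.64), plat = 0.225,
                 r250_ca = 36.9, r250_ba = 79.10),
  S652L_L = list(act = c(-16.3, 8.27),  ssi = c(-43.3, 4.99), plat = 0.128,
                 r250_ca = 17.1, r250_ba = 59.05),
  WT_S    = list(act = c(-10.6, 7.65),  ssi = c(-31.2, 4.78), plat = 0.121,
                 r250_ca = 17.1, r250_ba = 76.96),
  S652L_S = list(act = c(-23.5, 7.32),  ssi = c(-47.2, 4.24), plat = 0.0914,
                 r250_ca = 10.5, r250_ba = 53.91),
  S652W_L = list(act = c(4.23, 8.73),   ssi = c(-13.1, 5.73), plat = 0.151,
                 r250_ca = 31.35, r250_ba = NA)
)
slope_tol <- c(WT_L = 0.3, S652L_L = 0.3, WT_S = 1.6, S652L_S = 0.3,
               S652W_L = 1.6)
plat_tol <- c(WT_L = 0.045, S652L_L = 0.025, WT_S = 0.045, S652L_S = 0.025,
              S652W_L = 0.045)

acts <- list()

test_that("packaged sets reproduce published activation parameters", {
  for (nm in names(published)) {
    a <- pipeline_activation(cav13_variant(nm))
    acts[[nm]] <<- a
    expect_lt(abs(a$activation$v_half_act - published[[nm]]$act[1]), 0.5,
              label = paste(nm, "V0.5,act error"))
    expect_lt(abs(a$activation$slope_act - published[[nm]]$act[2]), 0.3,
              label = paste(nm, "k_act error"))
  }
  # the mutation shifts the I-V minimum to more negative voltages
  expect_lt(acts$S652L_L$v_max, acts$WT_L$v_max)
  expect_lt(acts$S652L_S$v_max, acts$WT_S$v_max)
  expect_gt(acts$S652W_L$v_max, acts$S652L_L$v_max)
})

test_that("packaged sets reproduce published steady-state inactivation", {
  for (nm in names(published)) {
    s <- pipeline_ssi(cav13_variant(nm), acts[[nm]]$v_max)
    expect_lt(abs(s$v_half_inact - published[[nm]]$ssi[1]), 0.5,
              label = paste(nm, "V0.5,inact error"))
    expect_lt(abs(s$slope_inact - published[[nm]]$ssi[2]), slope_tol[[nm]],
              label = paste(nm, "k_inact error"))
    expect_lt(abs(s$plateau - published[[nm]]$plat), plat_tol[[nm]],
              label = paste(nm, "plateau error"))
  }
})

test_that("packaged sets reproduce the published inactivation time courses", {
  tab2 <- list(
    WT_L    = list(ca = c(65.6, 54.5, 36.9, 24.9, 16.9, 8.60),
                   ba = c(92.55, 88.74, 79.10, 68.4, 57.37, 30.26)),
    S652L_L = list(ca = c(52.8, 35.2, 17.1, 10.8, 8.04, 5.33),
                   ba = c(86.78, 76.91, 59.05, 47.17, 36.33, 17.24)),
    WT_S    = list(ca = c(29.3, 23.3, 17.1, 12.9, 10.1, 6.21),
                   ba = c(93.57, 88.24, 76.96, 64.48, 50.89, 25.67)),
    S652L_S = list(ca = c(26.4, 17.6, 10.5, 7.11, 6.15, 3.34),
                   ba = c(84.74, 72.67, 53.91, 40.74, 29.98, 15.27)))
  for (nm in names(tab2)) {
    p <- cav13_variant(nm)
    vmax <- acts[[nm]]$v_max
    rca <- pipeline_r_values(p, vmax, "Ca")
    rba <- pipeline_r_values(p, vmax, "Ba")
    # r250, the CDI-defining time point, at the calibration tolerance
    expect_lt(abs(rca[["r250"]] - tab2[[nm]]$ca[3]), 2,
              label = paste(nm, "Ca r250 error"))
    expect_lt(abs(rba[["r250"]] - tab2[[nm]]$ba[3]), 2,
              label = paste(nm, "Ba r250 error"))
    # whole time course: tight on average, bounded pointwise
    expect_lt(mean(abs(rca - tab2[[nm]]$ca)), 2.5,
              label = paste(nm, "Ca mean error"))
    expect_lt(mean(abs(rba - tab2[[nm]]$ba)), 2.5,
              label = paste(nm, "Ba mean error"))
    expect_lt(max(abs(rca - tab2[[nm]]$ca)), 7,
              label = paste(nm, "Ca max error"))
    expect_lt(max(abs(rba - tab2[[nm]]$ba)), 5,
              label = paste(nm, "Ba max error"))
    # r values decline monotonically on noiseless simulations
    expect_true(all(diff(rca) < 0) && all(diff(rba) < 0))
    # with Ca as carrier inactivation is always deeper than with Ba
    expect_true(all(rca < rba))
  }
})

test_that("simulated CDI has the published magnitude and a U-shaped f(V)", {
  p <- cav13_variant("WT_S")
  vmax <- acts$WT_S$v_max
  rca <- pipeline_r_values(p, vmax, "Ca")
  rba <- pipeline_r_values(p, vmax, "Ba")
  cdi <- cdi_fraction(rca[["r250"]], rba[["r250"]])
  expect_equal(cdi, 0.778, tolerance = 0.05)

  # f(V): weak at threshold, strong near the I-V minimum, weaker again
  # at strongly depolarized voltages (smaller driving force)
  f_at <- function(v) {
    ca <- pipeline_r_values(p, v, "Ca")[["r250"]]
    ba <- pipeline_r_values(p, v, "Ba")[["r250"]]
    cdi_f(ba, ca)
  }
  f_low <- f_at(-50); f_mid <- f_at(vmax); f_high <- f_at(50)
  expect_gt(f_mid, f_low)
  expect_gt(f_mid, f_high)
  expect_gt(f_mid, 0.3)
})

test_that("mutant window currents exceed wild type at subthreshold voltages", {
  win <- function(nm) {
    a <- acts[[nm]]
    s <- pipeline_ssi(cav13_variant(nm), a$v_max)
    window_current(s, a$points)
  }
  w_wt <- win("WT_S"); w_mut <- win("S652L_S")
  at <- function(w, v) stats::approx(w$v, w$window, xout = v)$y
  expect_gte(abs(at(w_mut, -50)) / abs(at(w_wt, -50)), 2)
  expect_gt(abs(at(w_mut, -40)), abs(at(w_wt, -40)))
  # the loss-of-function variant does not increase the window current
  w_wtl <- win("WT_L"); w_w <- win("S652W_L")
  expect_lte(abs(at(w_w, -40)), abs(at(w_wtl, -40)) * 1.2)
})
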