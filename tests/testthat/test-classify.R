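fits_from <- function(variant, v_act, v_inact, plateau, window = NULL) {
  gating_fits(variant,
              activation = list(v_half_act = v_act, slope_act = 8),
              ssi = list(v_half_inact = v_inact, slope_inact = 5,
                         plateau = plateau),
              window = window)
}

test_that("published parameter shifts classify as gain or loss of function", {
  wt <- fits_from("WT_L", -0.18, -25.7, 0.225)
  mut <- fits_from("S652L_L", -16.3, -43.3, 0.128)
  v <- classify_variant(wt, mut)
  expect_identical(v$verdict, "GOF")
  expect_equal(v$delta_v_act, -16.12)
  expect_true(v$evidence[["activation_negative_shift"]])

  lof <- classify_variant(fits_from("WT_L", -0.50, -17.5, 0.174),
                          fits_from("S652W_L", 4.23, -13.1, 0.151))
  expect_identical(lof$verdict, "LOF")
  expect_equal(lof$delta_v_act, 4.73)
  expect_false(any(lof$evidence[c("activation_negative_shift",
                                  "plateau_increase", "window_increase")]))

  same <- classify_variant(wt, fits_from("twin", -0.18, -25.7, 0.225))
  expect_identical(same$verdict, "indeterminate")
})

test_that("activation-shift rule is antisymmetric and thresholds configurable", {
  a <- fits_from("a", -5, -30, 0.2)
  b <- fits_from("b", -12, -38, 0.2)
  expect_equal(classify_variant(a, b)$delta_v_act,
               -classify_variant(b, a)$delta_v_act)
  expect_identical(classify_variant(a, b)$verdict, "GOF")
  strict <- classify_variant(a, b, thresholds = list(gof_act_shift = -10))
  expect_identical(strict$verdict, "indeterminate")
  lax <- classify_variant(a, b, thresholds = list(gof_act_shift = -20,
                                                  lof_act_shift = 30))
  expect_identical(lax$verdict, "indeterminate")
})

test_that("plateau and window rules can each carry a GOF verdict", {
  wt <- fits_from("wt", 0, -30, 0.10,
                  window = data.frame(v = c(-50, -40), window = c(-0.1, -0.5)))
  m_plat <- fits_from("m1", -1, -30, 0.25)
  expect_identical(classify_variant(wt, m_plat)$verdict, "GOF")
  m_win <- fits_from("m2", -1, -30, 0.10,
                     window = data.frame(v = c(-50, -40),
                                         window = c(-0.4, -1.2)))
  v <- classify_variant(wt, m_win)
  expect_identical(v$verdict, "GOF")
  expect_gte(v$window_ratio, 2)
})

test_that("classification requires complete activation and SSI fits", {
  wt <- fits_from("wt", 0, -30, 0.2)
  broken <- gating_fits("m", activation = list(v_half_act = NA_real_),
                        ssi = list(v_half_inact = -30, plateau = 0.2))
  expect_error(classify_variant(wt, broken), "incomplete")
})

test_that("group comparisons run the standard tests with Bonferroni", {
  set.seed(5)
  x <- rnorm(20)
  same <- compare_groups(x, x, test = "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(compare_groups(1:2, 1:5), "n >= 3")

  # power for a 1-SD shift matches the noncentral-t prediction
  n_seed <- 400
  rej <- vapply(seq_len(n_seed), function(s) {
    set.seed(s)
    compare_groups(rnorm(20), rnorm(20, 1), test = "t")$p < 0.05
  }, logical(1))
  predicted <- stats::power.t.test(n = 20, delta = 1, sd = 1)$power
  expect_lt(abs(mean(rej) - predicted),
            3 * sqrt(predicted * (1 - predicted) / n_seed))

  # multi-voltage input: Bonferroni adjustment across columns
  a <- matrix(rnorm(60), ncol = 3)
  b <- matrix(rnorm(60), ncol = 3)
  res <- compare_groups(a, b, test = "mannwhitney")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  expect_equal(nrow(compare_groups(rnorm(10), rnorm(10), "anova")), 1)
})

test_that("report rendering is deterministic and schema-complete", {
  out1 <- file.path(tempdir(), "rep1")
  out2 <- file.path(tempdir(), "rep2")
  wt <- fits_from("WT_L", -0.18, -25.7, 0.225)
  wt$r250 <- 36.9
  mut <- fits_from("S652L_L", -16.3, -43.3, 0.128)
  mut$r250 <- 17.1
  v <- classify_variant(wt, mut)
  render_report(list(WT_L = wt, S652L_L = mut), list(v), out1, seed = 1)
  render_report(list(WT_L = wt, S652L_L = mut), list(v), out2, seed = 1)
  tab <- utils::read.csv(file.path(out1, "gating_parameters.csv"))
  expect_setequal(names(tab), c("variant", "v_half_act", "slope_act", "v_rev",
                                "v_half_inact", "slope_inact",
                                "non_inactivating_pct", "r250"))
  expect_equal(tab$variant, c("WT_L", "S652L_L"))
  vj <- jsonlite::fromJSON(file.path(out1, "verdicts.json"),
                           simplifyDataFrame = FALSE)
  expect_identical(vj[[1]]$verdict, "GOF")
  expect_identical(readLines(file.path(out1, "verdicts.json")),
                   readLines(file.path(out2, "verdicts.json")))
  expect_warning(render_report(list(), list(), file.path(tempdir(), "rep0")),
                 "empty")
})

test_that("sweep CSV + JSON serialization round-trips recordings", {
  recs <- simulate_protocol(cav13_variant("WT_L"),
                            build_iv_protocol(-89, -50, -10, 10, 50),
                            sim_config(dt = 0.05, noise_sd = 2, seed = 9))
  path <- file.path(tempdir(), "sweeps.csv")
  write_sweeps(recs, path)
  back <- read_sweeps(path)
  expect_length(back, 5)
  for (k in 1:5) {
    expect_equal(back[[k]]$current, recs[[k]]$current)
    expect_equal(back[[k]]$command_v, recs[[k]]$command_v)
    expect_equal(back[[k]]$segments$role, recs[[k]]$segments$role)
  }
  # analyses agree on original and round-tripped recordings
  p1 <- extract_iv(preprocess_sweeps(recs, offset = 0, leak = "none"),
                   skip_ms = 2)
  p2 <- extract_iv(preprocess_sweeps(back, offset = 0, leak = "none"),
                   skip_ms = 2)
  expect_equal(p1$i, p2$i)
})
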