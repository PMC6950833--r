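# Gain-/loss-of-function classification and report generation.

#' Collect the gating statistics of one construct
#'
#' Light container pairing the fitted activation, SSI, window-current and
#' kinetic summaries of one construct for [classify_variant()].
#'
#' @param variant construct label.
#' @param activation a `cav_act_fit` (or list with `v_half_act`).
#' @param ssi a `cav_ssi_fit` (or list with `v_half_inact`, `plateau`).
#' @param window data frame from [window_current()] (optional).
#' @param r250 remaining fraction at 250 ms, percent (optional).
#' @param tail a `cav_tail_fit` (optional).
#' @return an object of class `cav_gating_fits`.
#' @export
gating_fits <- function(variant, activation, ssi, window = NULL, r250 = NULL,
                        tail = NULL) {
  structure(list(variant = variant, activation = activation, ssi = ssi,
                 window = window, r250 = r250, tail = tail),
            class = "cav_gating_fits")
}

window_at <- function(window, v) {
  if (is.null(window)) return(NA_real_)
  stats::approx(window$v, window$window, xout = v, rule = 1)$y
}

#' Classify a variant as gain- or loss-of-function
#'
#' Rule-based verdict from the comparison of a mutant construct with its
#' wild-type backbone, distilled from the diagnostic picture of pathogenic
#' Cav1.3 variants: enhancement (gain of function) is called when the
#' activation midpoint is shifted to more negative voltages by at least
#' `gof_act_shift`, when the non-inactivating fraction grows by at least
#' `gof_plateau_points` percentage points, or when the subthreshold window
#' current grows at least `gof_window_ratio`-fold; loss of function is
#' called when activation shifts positive by at least `lof_act_shift` with
#' no enhancement rule firing; anything else is indeterminate. Slowed
#' inactivation (r250) and slowed tail deactivation are reported as
#' supporting flags.
#'
#' @param wt,mut [gating_fits()] of the wild-type and mutant construct.
#' @param thresholds named list overriding the defaults
#'   `gof_act_shift = -5`, `lof_act_shift = 3`, `gof_plateau_points = 10`,
#'   `gof_window_ratio = 2`, `subthreshold_v = c(-50, -40)`.
#' @return an object of class `cav_verdict` with the deltas, rule-by-rule
#'   evidence and the verdict (`"GOF"`, `"LOF"` or `"indeterminate"`).
#' @export
classify_variant <- function(wt, mut, thresholds = list()) {
  th <- utils::modifyList(list(gof_act_shift = -5, lof_act_shift = 3,
                               gof_plateau_points = 10, gof_window_ratio = 2,
                               subthreshold_v = c(-50, -40)), thresholds)
  need <- function(x, f) if (is.null(x[[f]]) || is.na(x[[f]]))
    stop("incomplete input: missing ", f, " for ", x$variant %||% "construct")
  for (g in list(wt$activation, mut$activation)) need(g, "v_half_act")
  for (g in list(wt$ssi, mut$ssi)) need(g, "v_half_inact")
  delta_v_act <- mut$activation$v_half_act - wt$activation$v_half_act
  delta_v_inact <- mut$ssi$v_half_inact - wt$ssi$v_half_inact
  plateau_delta <- 100 * ((mut$ssi$plateau %||% NA_real_) -
                          (wt$ssi$plateau %||% NA_real_))
  wr <- vapply(th$subthreshold_v, function(v) {
    w_wt <- window_at(wt$window, v); w_mut <- window_at(mut$window, v)
    if (is.na(w_wt) || is.na(w_mut) || abs(w_wt) < 1e-12) NA_real_
    else abs(w_mut) / abs(w_wt)
  }, numeric(1))
  window_ratio <- if (all(is.na(wr))) NA_real_ else max(wr, na.rm = TRUE)
  inact_slowing <- !is.null(wt$r250) && !is.null(mut$r250) &&
    (mut$r250 - wt$r250) > 10
  tail_slowing <- !is.null(wt$tail) && !is.null(mut$tail) &&
    is.finite(wt$tail$tau_slow %||% NA) && is.finite(mut$tail$tau_slow %||% NA) &&
    mut$tail$tau_slow > 1.2 * wt$tail$tau_slow
  evidence <- c(activation_negative_shift = delta_v_act <= th$gof_act_shift,
                plateau_increase = isTRUE(plateau_delta >= th$gof_plateau_points),
                window_increase = isTRUE(window_ratio >= th$gof_window_ratio),
                inactivation_slowing = inact_slowing,
                tail_slowing = tail_slowing)
  enhancement <- any(evidence[c("activation_negative_shift",
                                "plateau_increase", "window_increase")])
  verdict <- if (enhancement) "GOF"
             else if (delta_v_act >= th$lof_act_shift) "LOF"
             else "indeterminate"
  structure(list(variant = mut$variant, wt = wt$variant,
                 delta_v_act = delta_v_act, delta_v_inact = delta_v_inact,
                 plateau_delta = plateau_delta, window_ratio = window_ratio,
                 inactivation_slowing = inact_slowing,
                 tail_slowing = tail_slowing,
                 evidence = evidence, verdict = verdict, thresholds = th),
            class = "cav_verdict")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cav_verdict <- function(x, ...) {
  cat(sprintf("<cav_verdict> %s vs %s: %s (dV0.5,act %+.1f mV, dV0.5,inact %+.1f mV)\n",
              x$variant, x$wt, x$verdict, x$delta_v_act, x$delta_v_inact))
  invisible(x)
}

#' Compare two groups of per-cell values
#'
#' Thin wrapper over the standard tests used for per-cell gating
#' statistics: unpaired t test, Mann-Whitney U test, or one-way ANOVA.
#' When a matrix of per-voltage values is supplied the comparison is run per
#' voltage with Bonferroni adjustment.
#'
#' @param a,b numeric vectors (or matrices with one column per voltage) of
#'   per-cell values.
#' @param test `"t"`, `"mannwhitney"` or `"anova"`.
#' @return data frame with `statistic`, `p`, and `p_adj` (Bonferroni, for
#'   multi-voltage input).
#' @export
compare_groups <- function(a, b, test = c("t", "mannwhitney", "anova")) {
  test <- match.arg(test)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("insufficient data: need n >= 3 per group")
  ncols <- max(ncol(a), ncol(b))
  res <- lapply(seq_len(ncols), function(j) {
    x <- a[, min(j, ncol(a))]; y <- b[, min(j, ncol(b))]
    out <- switch(test,
      t = { h <- stats::t.test(x, y); c(h$statistic, h$p.value) },
      mannwhitney = { h <- stats::wilcox.test(x, y, exact = FALSE)
                      c(h$statistic, h$p.value) },
      anova = { d <- data.frame(v = c(x, y),
                                g = factor(rep(1:2, c(length(x), length(y)))))
                h <- summary(stats::aov(v ~ g, data = d))[[1L]]
                c(h$`F value`[1L], h$`Pr(>F)`[1L]) })
    data.frame(statistic = out[1L], p = out[2L])
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}

#' Write analysis reports
#'
#' Writes tidy CSV tables of the fitted parameters (activation/inactivation
#' layout), per-voltage series, JSON verdicts and a run log (configuration
#' hash and seed) into a directory. Output is deterministic given the same
#' inputs and seed.
#'
#' @param fits named list of [gating_fits()] per construct (may be empty).
#' @param verdicts list of [classify_variant()] results (may be empty).
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the run log.
#' @return invisibly, the paths written.
#' @export
render_report <- function(fits, verdicts, out_dir, seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  paths <- character()
  if (!length(fits)) warning("empty analysis set: writing empty report")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(variant = f$variant,
               v_half_act = f$activation$v_half_act %||% NA_real_,
               slope_act = f$activation$slope_act %||% NA_real_,
               v_rev = f$activation$v_rev %||% NA_real_,
               v_half_inact = f$ssi$v_half_inact %||% NA_real_,
               slope_inact = f$ssi$slope_inact %||% NA_real_,
               non_inactivating_pct = 100 * (f$ssi$plateau %||% NA_real_),
               r250 = f$r250 %||% NA_real_)
  }))
  if (is.null(tab))
    tab <- data.frame(variant = character(), v_half_act = numeric(),
                      slope_act = numeric(), v_rev = numeric(),
                      v_half_inact = numeric(), slope_inact = numeric(),
                      non_inactivating_pct = numeric(), r250 = numeric())
  p1 <- file.path(out_dir, "gating_parameters.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  paths <- c(paths, p1)
  for (f in fits) {
    if (!is.null(f$window)) {
      pw <- file.path(out_dir, paste0("window_", f$variant, ".csv"))
      utils::write.csv(f$window, pw, row.names = FALSE)
      paths <- c(paths, pw)
    }
  }
  vj <- lapply(verdicts, function(v)
    v[c("variant", "wt", "delta_v_act", "delta_v_inact", "plateau_delta",
        "window_ratio", "inactivation_slowing", "tail_slowing", "evidence",
        "verdict")])
  p2 <- file.path(out_dir, "verdicts.json")
  jsonlite::write_json(vj, p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p3 <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(seed = seed, n_fits = length(fits),
                            n_verdicts = length(verdicts)),
                       p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, p2, p3))
}
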