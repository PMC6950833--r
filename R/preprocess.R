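#' Liquid-junction potential correction
#'
#' Shifts the recorded command voltages by the liquid-junction offset
#' (-9.3 mV for the standard solution pair) so that downstream fits report
#' true membrane voltages. Currents are untouched. Marks the sweep as processed and
#' initializes the leak-subtracted trace and the current density.
#'
#' @param rec a `cav_sweep`.
#' @param offset junction offset in mV.
#' @return a `cav_processed` sweep with `v_corrected`, `i_corr` and
#'   `i_density` fields.
#' @export
correct_junction <- function(rec, offset = -9.3) {
  rec$v_corrected <- rec$command_v + offset
  rec$junction_offset_applied <- offset
  if (is.null(rec$i_corr)) rec$i_corr <- rec$current
  rec$i_density <- rec$i_corr / rec$capacitance
  rec$qc_pass <- NA
  rec$qc_reason <- NA_character_
  class(rec) <- unique(c("cav_processed", class(rec)))
  rec
}

as_processed <- function(rec, offset = 0) {
  if (inherits(rec, "cav_processed")) rec else correct_junction(rec, offset)
}

segment_samples <- function(rec, role) {
  j <- which(rec$segments$role %in% role)
  if (!length(j))
    stop(sprintf("protocol mismatch: no segment with role '%s' in sweep",
                 paste(role, collapse = "/")),
         call. = FALSE)
  which(rec$segment_index %in% j)
}

has_role <- function(rec, role) any(rec$segments$role %in% role)

#' Offline linear leak subtraction
#'
#' Estimates the linear leak conductance from a hyperpolarizing voltage step
#' (default role `"leakstep"`, the 50-ms step 10 mV below holding): the
#' steady current during the final part of the step, relative to the holding
#' baseline, divided by the step size. The leak current at every sample's
#' command voltage (plus the holding baseline) is then subtracted.
#' Alternatively a pre-estimated conductance/baseline pair can be supplied,
#' e.g. for sweeps of a protocol without their own leak step.
#'
#' @param rec a processed sweep (see [correct_junction()]).
#' @param leak_role segment role holding the hyperpolarizing step.
#' @param steady_frac fraction of the step (from its end) averaged as the
#'   steady-state current.
#' @param g_leak,baseline optional pre-estimated leak conductance (nS) and
#'   holding-baseline current (pA); both must be given together.
#' @return the sweep with `i_corr`/`i_density` leak-subtracted and
#'   `meta$leak_g`, `meta$leak_baseline` recorded.
#' @export
leak_subtract_offline <- function(rec, leak_role = "leakstep",
                                  steady_frac = 0.6, g_leak = NULL,
                                  baseline = NULL) {
  rec <- as_processed(rec)
  hp <- rec$meta$hp
  if (is.null(g_leak)) {
    if (!has_role(rec, leak_role))
      stop("protocol mismatch: recording has no hyperpolarizing leak step",
           call. = FALSE)
    idx_step <- segment_samples(rec, leak_role)
    idx_hold <- which(rec$segment_index == 1L)   # leading hold at hp
    n_st <- length(idx_step)
    steady <- idx_step[seq.int(from = ceiling(n_st * (1 - steady_frac)) + 1L,
                               to = n_st)]
    baseline <- mean(rec$current[idx_hold])
    v_step <- rec$segments$v_start[rec$segment_index[idx_step[1L]]]
    dv <- v_step - hp
    if (abs(dv) < 1e-9) stop("leak step has zero amplitude")
    g_leak <- (mean(rec$current[steady]) - baseline) / dv
  } else if (is.null(baseline)) {
    stop("supply baseline together with g_leak")
  }
  leak <- baseline + g_leak * (rec$command_v - hp)
  rec$i_corr <- rec$current - leak
  rec$i_density <- rec$i_corr / rec$capacitance
  rec$meta$leak_g <- g_leak
  rec$meta$leak_baseline <- baseline
  rec
}

#' P/4 online leak subtraction
#'
#' Subtracts the summed, baseline-aligned responses to four subpulses scaled
#' to 1/4 of the main-sweep amplitude. Each sweep (main and subpulses) is
#' first referenced to its own holding-baseline current; for a linear leak
#' the subpulse sum then equals the leak response to the full command.
#'
#' @param rec_main the main `cav_sweep`.
#' @param rec_subpulses list of exactly four subpulse recordings with the
#'   same sample count as the main sweep.
#' @param polarity +1 when subpulses have the same polarity as the main
#'   command, -1 for inverted subpulses.
#' @return processed main sweep with leak-subtracted `i_corr`/`i_density`.
#' @export
leak_subtract_p4 <- function(rec_main, rec_subpulses, polarity = 1) {
  if (length(rec_subpulses) != 4L)
    stop("invalid argument: P/4 requires exactly 4 subpulse recordings")
  rec <- as_processed(rec_main)
  idx_hold <- which(rec$segment_index == 1L)
  main0 <- rec$current - mean(rec$current[idx_hold])
  sub_sum <- 0
  for (s in rec_subpulses) {
    if (length(s$current) != length(rec$current))
      stop("invalid argument: subpulse length mismatch")
    ih <- which(s$segment_index == 1L)
    sub_sum <- sub_sum + (s$current - mean(s$current[ih]))
  }
  rec$i_corr <- main0 - polarity * sub_sum
  rec$i_density <- rec$i_corr / rec$capacitance
  rec$meta$leak_method <- "P/4"
  rec
}

#' Build the four P/4 subpulse sweeps for a main sweep
#'
#' Command excursions from holding are scaled by `polarity/4`; segment roles
#' are preserved.
#'
#' @param sweep segment data frame of the main sweep.
#' @param hp command holding potential (mV).
#' @param polarity +1 (same polarity) or -1 (inverted).
#' @return list of four segment data frames.
#' @export
p4_subpulses <- function(sweep, hp, polarity = 1) {
  sub <- sweep
  sub$v_start <- hp + polarity * (sweep$v_start - hp) / 4
  sub$v_end <- hp + polarity * (sweep$v_end - hp) / 4
  rep(list(sub), 4L)
}

# Signed peak: extremum of the 3-sample median-smoothed trace, refined as
# the local mean over +/- refine half-width around the detected extremum.
# The refinement removes the upward bias the max statistic picks up from
# wideband noise (the extremum location is noise-selected, its unsmoothed
# neighbors are not).
smoothed_peak <- function(i, smooth = TRUE, refine = 0) {
  y <- if (smooth && length(i) >= 3) stats::runmed(i, 3) else i
  j <- which.max(abs(y))
  if (refine > 0) {
    w <- max(j - refine, 1L):min(j + refine, length(i))
    mean(i[w])
  } else y[j]
}

# Signed peak current within a role window; skip_ms avoids the capacitive /
# gating onset transient, refine_ms sets the local-average half-width.
window_peak <- function(rec, role = "test", skip_ms = 0, smooth = TRUE,
                        refine_ms = 0.25, use = c("i_corr", "current")) {
  use <- match.arg(use)
  idx <- segment_samples(rec, role)
  if (skip_ms > 0) {
    nskip <- round(skip_ms / rec$meta$dt)
    if (nskip < length(idx)) idx <- idx[-seq_len(nskip)]
  }
  y <- if (use == "i_corr" && !is.null(rec$i_corr)) rec$i_corr[idx]
       else rec$current[idx]
  smoothed_peak(y, smooth, refine = round(refine_ms / rec$meta$dt))
}

#' Amplitude-window quality control
#'
#' Partitions recordings by the absolute peak current at the test pulse:
#' cells with peaks inside `[min_peak, max_peak]` pA (closed interval) are
#' kept, the rest excluded with a reason. The conventional prospective
#' window is 100-1000 pA, chosen to limit series-resistance and fit-bias
#' errors.
#'
#' @param recs list of processed sweeps.
#' @param min_peak,max_peak amplitude window (pA).
#' @param role segment role at which the peak is measured.
#' @return list with `kept`, `excluded` (sweep lists) and `report` (data
#'   frame with index, peak and verdict).
#' @export
qc_filter <- function(recs, min_peak = 100, max_peak = 1000, role = "test") {
  if (!length(recs))
    return(list(kept = list(), excluded = list(),
                report = data.frame(index = integer(), peak_pA = numeric(),
                                    kept = logical(), reason = character())))
  peaks <- vapply(recs, function(r)
    abs(window_peak(as_processed(r), role)), numeric(1))
  keep <- peaks >= min_peak & peaks <= max_peak
  reason <- ifelse(keep, "",
                   ifelse(peaks < min_peak, sprintf("peak %.1f pA < %g pA", peaks, min_peak),
                          sprintf("peak %.1f pA > %g pA", peaks, max_peak)))
  report <- data.frame(index = seq_along(recs), peak_pA = peaks, kept = keep,
                       reason = reason, stringsAsFactors = FALSE)
  list(kept = recs[keep], excluded = recs[!keep], report = report)
}

#' Preprocess a list of simulated or imported sweeps
#'
#' Convenience wrapper: junction correction for every sweep, plus offline
#' leak subtraction where a leak step exists (or with a shared leak estimate
#' supplied through `g_leak`/`baseline`).
#'
#' @param recs list of `cav_sweep` objects.
#' @param offset junction offset (mV).
#' @param leak one of `"auto"` (subtract where a leak step exists, otherwise
#'   baseline-only), `"none"`.
#' @param g_leak,baseline shared leak estimate forwarded to
#'   [leak_subtract_offline()].
#' @return list of processed sweeps.
#' @export
preprocess_sweeps <- function(recs, offset = -9.3, leak = c("auto", "none"),
                              g_leak = NULL, baseline = NULL) {
  leak <- match.arg(leak)
  lapply(recs, function(r) {
    r <- correct_junction(r, offset)
    if (leak == "auto") {
      if (has_role(r, "leakstep"))
        r <- leak_subtract_offline(r)
      else if (!is.null(g_leak))
        r <- leak_subtract_offline(r, g_leak = g_leak, baseline = baseline)
    }
    r
  })
}
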