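# Analysis of action-potential-waveform train recordings.

repol_roles <- c("repolarization", "afterhyperpolarization")

#' Per-sweep peak current of an AP train
#'
#' Inward extremum within the repolarization window (from the start of the
#' downstroke ramp to the end of the afterhyperpolarization ramp) of each
#' action-potential sweep, normalized to current density.
#'
#' @param train list of processed sweeps from [build_apw_train()].
#' @return numeric vector of peak densities (pA/pF), one per sweep.
#' @export
peak_per_sweep <- function(train) {
  vapply(train, function(r) {
    r <- as_processed(r)
    idx <- segment_samples(r, repol_roles)
    min(r$i_density[idx])
  }, numeric(1))
}

#' Peak decay over an AP train
#'
#' Percent decrease of the peak current over the train:
#' `100 (mean of first 3 peaks - mean of last 3 peaks) / mean of first 3`.
#' Peaks are inward (negative), so the decay is computed on magnitudes.
#'
#' @param peaks per-sweep peak currents (>= 10 sweeps).
#' @return decay in percent.
#' @export
train_decay <- function(peaks) {
  if (length(peaks) < 10)
    stop("insufficient data: need >= 10 sweeps for train decay")
  first <- mean(abs(peaks[1:3]))
  last <- mean(abs(utils::tail(peaks, 3)))
  100 * (first - last) / first
}

#' Cumulative normalized Ca2+ charge of an AP train
#'
#' Trapezoidal integral of the inward current per sweep (outward samples
#' excluded by sign), cumulated across the train and divided by the
#' magnitude of the reference current (the maximal inward current in a
#' voltage ramp recorded before the train).
#'
#' @param train list of processed sweeps.
#' @param reference reference current magnitude (pA); if `NULL`, taken from
#'   `meta$ramp_reference` of the first sweep.
#' @return data frame with `sweep`, `charge` (per-sweep normalized pA*ms)
#'   and `cum_charge`.
#' @export
integrate_charge <- function(train, reference = NULL) {
  if (is.null(reference))
    reference <- train[[1L]]$meta$ramp_reference
  if (is.null(reference))
    stop("missing normalization reference (pre-train ramp maximum current)")
  per_sweep <- vapply(train, function(r) {
    r <- as_processed(r)
    dt <- r$meta$dt
    inw <- pmin(r$i_corr, 0)
    -sum((inw[-1L] + inw[-length(inw)]) / 2) * dt
  }, numeric(1))
  data.frame(sweep = seq_along(per_sweep),
             charge = per_sweep / abs(reference),
             cum_charge = cumsum(per_sweep) / abs(reference))
}

#' Normalize a fluorescence series to baseline and current density
#'
#' Divides a raw fluorescence series by its baseline F0 and scales by the
#' reciprocal of the cell's current-density magnitude, so that signals are
#' comparable across cells with different expression levels.
#'
#' @param raw_f raw fluorescence series.
#' @param f0 baseline fluorescence (> 0).
#' @param current_density reference current density (pA/pF, non-zero).
#' @return normalized series `(raw_f / f0) / |current_density|`.
#' @export
normalize_fluorescence <- function(raw_f, f0, current_density) {
  if (f0 <= 0) stop("invalid argument: f0 must be > 0")
  if (current_density == 0)
    stop("invalid argument: current_density must be non-zero")
  (raw_f / f0) / abs(current_density)
}

#' Simulate an AP-train run with its reference ramp
#'
#' Convenience wrapper used by the train analyses: simulates the pre-train
#' reference ramp, stores its maximal inward current in each train sweep's
#' metadata, then simulates the APW train itself.
#'
#' @param p a [variant_params()] object.
#' @param cfg a [sim_config()] (Ca carrier for charge/fluorescence work).
#' @param n_sweeps,frequency train length and rate (see [build_apw_train()]).
#' @return list with `train` (sweep list), `ramp` (the ramp recording) and
#'   `ramp_reference` (pA, inward maximum).
#' @export
simulate_apw_run <- function(p, cfg, n_sweeps = 300, frequency = 10) {
  hp_cmd <- -80 - cfg$junction_offset   # true -80 mV, the imaging HP
  ramp <- simulate_protocol(p, build_ramp_protocol(hp_cmd), cfg)[[1L]]
  ramp_ref <- abs(min(ramp$current[segment_samples(ramp, "ramp")]))
  train <- simulate_protocol(p, build_apw_train(n_sweeps, frequency,
                                                hp = hp_cmd), cfg)
  train <- lapply(train, function(r) {
    r$meta$ramp_reference <- ramp_ref
    r
  })
  list(train = train, ramp = ramp, ramp_reference = ramp_ref)
}

#' Summarize an AP-train recording
#'
#' @param train list of processed sweeps.
#' @param reference optional reference current (see [integrate_charge()]).
#' @return list of class `cav_train_summary`: `peak_per_sweep`,
#'   `first_ap_peak`, `decay_pct`, `cum_charge` (data frame).
#' @export
summarize_train <- function(train, reference = NULL) {
  peaks <- peak_per_sweep(train)
  chg <- integrate_charge(train, reference)
  structure(list(peak_per_sweep = peaks, first_ap_peak = peaks[1L],
                 decay_pct = train_decay(peaks), cum_charge = chg),
            class = "cav_train_summary")
}
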