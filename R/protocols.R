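#' Command-voltage segment
#'
#' A protocol sweep is an ordered list of piecewise command-voltage segments,
#' either constant steps or linear ramps. Segments are represented as rows of
#' a data frame with columns `kind`, `v_start`, `v_end`, `duration` (ms) and
#' `role`, the last being a label (`"hold"`, `"test"`, `"conditioning"`, ...)
#' that the analysis functions use to locate measurement windows.
#'
#' @param v_start command voltage at segment start (mV).
#' @param v_end command voltage at segment end (mV); equal to `v_start` for a
#'   step.
#' @param duration segment duration in ms (> 0).
#' @param role label used by analyzers to find this segment.
#' @return one-row data frame describing the segment.
#' @export
seg_step <- function(v_start, duration, role = NA_character_) {
  stopifnot(is.numeric(v_start), length(v_start) == 1L)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid argument: segment duration must be > 0")
  data.frame(kind = "step", v_start = v_start, v_end = v_start,
             duration = duration, role = role, stringsAsFactors = FALSE)
}

#' @rdname seg_step
#' @export
seg_ramp <- function(v_start, v_end, duration, role = NA_character_) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid argument: segment duration must be > 0")
  data.frame(kind = "ramp", v_start = v_start, v_end = v_end,
             duration = duration, role = role, stringsAsFactors = FALSE)
}

#' Voltage-clamp stimulation protocol
#'
#' Container for a family of sweeps sharing a holding potential, a sampling
#' rate and an inter-sweep cadence. Time within a sweep is measured in ms from
#' sweep start; the gap between sweeps is metadata (the cell is held at the
#' holding potential), not samples. Voltages are command voltages before
#' liquid-junction correction.
#'
#' @param name protocol name.
#' @param holding_potential command holding potential (mV).
#' @param sweeps list of segment data frames (see [seg_step()]).
#' @param inter_sweep_interval start-to-start sweep cadence in seconds.
#' @param sample_rate sampling rate in kHz.
#' @param ends_at_hp logical; sweeps are expected to begin and end at the
#'   holding potential unless this is `FALSE` (e.g. action-potential trains).
#' @return an object of class `cav_protocol`.
#' @export
cav_protocol <- function(name, holding_potential, sweeps,
                         inter_sweep_interval = 5, sample_rate = 50,
                         ends_at_hp = TRUE) {
  if (!length(sweeps)) stop("invalid argument: protocol needs at least one sweep")
  if (sample_rate <= 0) stop("invalid argument: sample_rate must be > 0")
  for (sw in sweeps) {
    stopifnot(is.data.frame(sw), nrow(sw) > 0L,
              all(c("kind", "v_start", "v_end", "duration") %in% names(sw)))
    if (any(sw$duration <= 0)) stop("invalid argument: segment duration must be > 0")
    if (ends_at_hp) {
      if (sw$v_start[1L] != holding_potential ||
          sw$v_end[nrow(sw)] != holding_potential)
        stop("protocol sweeps must begin and end at the holding potential")
    }
  }
  structure(list(name = name, holding_potential = holding_potential,
                 sweeps = sweeps, inter_sweep_interval = inter_sweep_interval,
                 sample_rate = sample_rate, ends_at_hp = ends_at_hp),
            class = "cav_protocol")
}

#' @export
print.cav_protocol <- function(x, ...) {
  cat(sprintf("<cav_protocol '%s'>: %d sweep(s), HP %g mV, %g kHz, cadence %g s\n",
              x$name, length(x$sweeps), x$holding_potential, x$sample_rate,
              x$inter_sweep_interval))
  invisible(x)
}

#' Total duration of a sweep (ms)
#' @param sweep a segment data frame.
#' @return sum of segment durations in ms.
#' @export
sweep_duration <- function(sweep) sum(sweep$duration)

# Sample a sweep's command voltage on a uniform dt grid. Samples sit at
# interval midpoints so that step plateaus are reproduced exactly and ramp
# samples are second-order accurate. Returns the voltage vector, the owning
# segment index per sample, and the sample times (ms).
sample_sweep <- function(sweep, dt) {
  n_per <- round(sweep$duration / dt)
  if (any(abs(n_per * dt - sweep$duration) > 1e-9))
    n_per <- pmax(1L, n_per)
  v <- numeric(sum(n_per))
  seg_index <- integer(sum(n_per))
  pos <- 0L
  for (j in seq_len(nrow(sweep))) {
    n <- n_per[j]
    idx <- pos + seq_len(n)
    if (sweep$kind[j] == "step") {
      v[idx] <- sweep$v_start[j]
    } else {
      frac <- (seq_len(n) - 0.5) / n
      v[idx] <- sweep$v_start[j] + (sweep$v_end[j] - sweep$v_start[j]) * frac
    }
    seg_index[idx] <- j
    pos <- pos + n
  }
  list(v = v, seg_index = seg_index,
       time = (seq_along(v) - 0.5) * dt)
}

pad_hold <- function(hp, pad_ms, role = "hold") seg_step(hp, pad_ms, role)

#' Build a current-voltage (I-V) protocol
#'
#' One sweep per test potential: a square depolarizing pulse of the given
#' duration from the holding potential, flanked by short holding segments.
#' The standard acquisition uses 50-ms pulses in 5-mV increments from a
#' -89 mV holding potential.
#'
#' @param hp holding potential (mV).
#' @param v_min,v_max first and last test potential (mV).
#' @param increment grid increment (mV, > 0).
#' @param duration test-pulse duration (ms, > 0).
#' @param pad_ms duration of the holding segments before/after the pulse.
#' @param inter_sweep_interval sweep cadence (s).
#' @return a [cav_protocol()].
#' @export
build_iv_protocol <- function(hp, v_min, v_max, increment = 5, duration = 50,
                              pad_ms = 10, inter_sweep_interval = 5) {
  if (increment <= 0) stop("invalid argument: increment must be > 0")
  if (duration <= 0) stop("invalid argument: duration must be > 0")
  if (v_min > v_max) stop("invalid argument: v_min must be <= v_max")
  grid <- seq(v_min, v_max, by = increment)
  sweeps <- lapply(grid, function(v) {
    rbind(pad_hold(hp, pad_ms),
          seg_step(v, duration, role = "test"),
          pad_hold(hp, pad_ms))
  })
  cav_protocol("iv", hp, sweeps, inter_sweep_interval = inter_sweep_interval)
}

#' Build a steady-state inactivation (SSI) protocol
#'
#' Each sweep holds a 20-ms control pulse to `vmax`, a recovery gap at the
#' holding potential, a 5-s conditioning step, and a 20-ms test pulse to
#' `vmax`. The availability at the conditioning voltage is the test/control
#' peak-current ratio. The sweep cadence is 30 s.
#'
#' @param hp holding potential (mV).
#' @param vmax control/test pulse potential (mV), normally the voltage of
#'   maximal inward current.
#' @param cond_min,cond_max conditioning-voltage range (mV).
#' @param increment conditioning grid increment (mV, > 0).
#' @param cond_ms conditioning duration (ms).
#' @param gap_ms recovery gap between control pulse and conditioning step.
#' @return a [cav_protocol()].
#' @export
build_ssi_protocol <- function(hp, vmax, cond_min, cond_max, increment = 10,
                               cond_ms = 5000, gap_ms = 500) {
  if (increment <= 0) stop("invalid argument: increment must be > 0")
  grid <- seq(cond_min, cond_max, by = increment)
  sweeps <- lapply(grid, function(vc) {
    rbind(pad_hold(hp, 10),
          seg_step(vmax, 20, role = "control"),
          seg_step(hp, gap_ms, role = "gap"),
          seg_step(vc, cond_ms, role = "conditioning"),
          seg_step(vmax, 20, role = "test"),
          pad_hold(hp, 10))
  })
  cav_protocol("ssi", hp, sweeps, inter_sweep_interval = 30)
}

#' Build an action-potential-waveform (APW) train
#'
#' Each sweep is the 100-ms action-potential-like command: a 2.5-ms step from
#' -80 to -60 mV, a 1-ms ramp to +20 mV, a 1.5-ms ramp to -70 mV, a 5-ms
#' afterhyperpolarization ramp back to -60 mV, and 90 ms at -60 mV. Sweeps
#' are applied at the given frequency (cadence = 1/frequency).
#'
#' @param n_sweeps number of action potentials in the train (>= 1).
#' @param frequency stimulation frequency in Hz (> 0).
#' @param hp holding potential (mV), -80 by default.
#' @return a [cav_protocol()] with `ends_at_hp = FALSE`.
#' @export
build_apw_train <- function(n_sweeps, frequency = 10, hp = -80) {
  if (n_sweeps < 1) stop("invalid argument: n_sweeps must be >= 1")
  if (frequency <= 0) stop("invalid argument: frequency must be > 0")
  apw <- rbind(seg_step(-60, 2.5, role = "foot"),
               seg_ramp(-60, 20, 1, role = "upstroke"),
               seg_ramp(20, -70, 1.5, role = "repolarization"),
               seg_ramp(-70, -60, 5, role = "afterhyperpolarization"),
               seg_step(-60, 90, role = "diastolic"))
  sweeps <- rep(list(apw), n_sweeps)
  cav_protocol("apw_train", hp, sweeps,
               inter_sweep_interval = 1 / frequency, ends_at_hp = FALSE)
}

#' Build a tail-current protocol
#'
#' One sweep per repolarization voltage: a strong depolarizing pre-pulse
#' (e.g. +80 mV) followed by a step to the repolarization voltage at which
#' the deactivating tail current is recorded.
#'
#' @param pre_v pre-pulse potential (mV).
#' @param repol_list repolarization potentials (mV), non-empty.
#' @param pre_duration pre-pulse duration (ms).
#' @param tail_duration tail-segment duration (ms).
#' @param hp holding potential (mV).
#' @return a [cav_protocol()].
#' @export
build_tail_protocol <- function(pre_v, repol_list, pre_duration = 20,
                                tail_duration = 20, hp = -79.7) {
  if (!length(repol_list)) stop("invalid argument: repol_list must be non-empty")
  sweeps <- lapply(repol_list, function(vr) {
    rbind(pad_hold(hp, 10),
          seg_step(pre_v, pre_duration, role = "pre"),
          seg_step(vr, tail_duration, role = "tail"),
          pad_hold(hp, 10))
  })
  cav_protocol("tail", hp, sweeps, inter_sweep_interval = 5)
}

#' Build a pharmacology (dose-response) protocol
#'
#' Identical 100-ms square pulses to the cell's voltage of maximal inward
#' current at 0.1 Hz, used for steady-state drug-inhibition measurements.
#' At least three sweeps are required so that a pre-drug control baseline
#' exists.
#'
#' @param vmax pulse potential (mV).
#' @param n_sweeps number of sweeps (>= 3).
#' @param hp holding potential (mV).
#' @param duration pulse duration (ms).
#' @param cadence_s sweep cadence in seconds (10 s = 0.1 Hz).
#' @return a [cav_protocol()].
#' @export
build_pharm_protocol <- function(vmax, n_sweeps, hp = -79.7, duration = 100,
                                 cadence_s = 10) {
  if (n_sweeps < 3)
    stop("invalid argument: pharmacology runs need >= 3 sweeps (control baseline)")
  sw <- rbind(pad_hold(hp, 10), seg_step(vmax, duration, role = "test"),
              pad_hold(hp, 10))
  cav_protocol("pharm", hp, rep(list(sw), n_sweeps),
               inter_sweep_interval = cadence_s)
}

#' Build a prolonged-depolarization (inactivation) protocol
#'
#' A single sweep with a 5-s test depolarization, optionally preceded by a
#' 50-ms hyperpolarizing step (for offline leak estimation) and/or by a 20-ms
#' pre-pulse to `v_ref` whose peak normalizes persistent currents.
#'
#' @param hp holding potential (mV).
#' @param v_test test potential (mV).
#' @param duration test duration (ms), 5000 by default.
#' @param leak_step include a 50-ms step 10 mV below holding for offline leak
#'   subtraction.
#' @param prepulse include a 20-ms pre-pulse before the test step.
#' @param v_ref pre-pulse potential (defaults to `v_test`).
#' @return a [cav_protocol()].
#' @export
build_inactivation_protocol <- function(hp, v_test, duration = 5000,
                                        leak_step = TRUE, prepulse = FALSE,
                                        v_ref = v_test) {
  segs <- list(pad_hold(hp, 10))
  if (leak_step) {
    segs <- c(segs, list(seg_step(hp - 10, 50, role = "leakstep"),
                         seg_step(hp, 50, role = "hold")))
  }
  if (prepulse) {
    segs <- c(segs, list(seg_step(v_ref, 20, role = "prepulse"),
                         seg_step(hp, 50, role = "gap")))
  }
  segs <- c(segs, list(seg_step(v_test, duration, role = "test"),
                       pad_hold(hp, 10)))
  cav_protocol("inactivation", hp, list(do.call(rbind, segs)),
               inter_sweep_interval = 30)
}

#' Build a voltage-ramp protocol
#'
#' A single linear ramp, used as the reference sweep whose maximal inward
#' current normalizes action-potential-train charge and fluorescence.
#'
#' @param hp holding potential (mV).
#' @param v_to ramp end voltage (mV).
#' @param duration ramp duration (ms).
#' @return a [cav_protocol()].
#' @export
build_ramp_protocol <- function(hp, v_to = 80, duration = 200) {
  sw <- rbind(pad_hold(hp, 10),
              seg_ramp(hp, v_to, duration, role = "ramp"),
              pad_hold(hp, 10))
  cav_protocol("ramp", hp, list(sw), inter_sweep_interval = 5)
}

#' Serialize a protocol to JSON
#'
#' Round-trips losslessly through [protocol_from_json()].
#'
#' @param prot a [cav_protocol()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
protocol_to_json <- function(prot, path = NULL) {
  x <- unclass(prot)
  js <- jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname protocol_to_json
#' @param json JSON string or file path produced by [protocol_to_json()].
#' @export
protocol_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  cav_protocol(x$name, x$holding_potential, lapply(x$sweeps, parse_segments),
               inter_sweep_interval = x$inter_sweep_interval,
               sample_rate = x$sample_rate, ends_at_hp = x$ends_at_hp)
}

parse_segments <- function(sw) {
  d <- data.frame(kind = as.character(sw$kind),
                  v_start = as.numeric(sw$v_start),
                  v_end = as.numeric(sw$v_end),
                  duration = as.numeric(sw$duration),
                  stringsAsFactors = FALSE)
  d$role <- if (is.null(sw$role)) NA_character_ else as.character(sw$role)
  d
}
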