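# Tabular text serialization of sweep recordings: one long-format CSV
# (sweep, time_ms, v_command_mV, i_pA) plus a JSON metadata sidecar.

#' Write sweep recordings to CSV + JSON
#'
#' Writes a list of sweeps as a long-format CSV (`sweep`, `time_ms`,
#' `v_command_mV`, `i_pA`) with a JSON sidecar (`<path>.json`) holding the
#' shared metadata (capacitance, carrier, protocol, segments, dt).
#'
#' @param recs list of `cav_sweep` objects sharing a protocol.
#' @param path CSV file path.
#' @return invisibly, the two paths written.
#' @export
write_sweeps <- function(recs, path) {
  stopifnot(length(recs) > 0)
  tab <- do.call(rbind, lapply(recs, function(r)
    data.frame(sweep = r$sweep_index, time_ms = r$time,
               v_command_mV = r$command_v, i_pA = r$current)))
  utils::write.csv(tab, path, row.names = FALSE)
  r1 <- recs[[1L]]
  meta <- list(capacitance = r1$capacitance, carrier = r1$carrier,
               protocol_name = r1$protocol_name, dt = r1$meta$dt,
               hp = r1$meta$hp, junction_offset = r1$meta$junction_offset,
               variant = r1$meta$variant,
               segments = lapply(recs, function(r) r$segments))
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(path, side))
}

#' @rdname write_sweeps
#' @param path CSV file path previously written by [write_sweeps()].
#' @export
read_sweeps <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  segs <- lapply(meta$segments, parse_segments)
  lapply(seq_along(unique(tab$sweep)), function(k) {
    id <- sort(unique(tab$sweep))[k]
    d <- tab[tab$sweep == id, ]
    sweep <- segs[[k]]
    n_per <- round(sweep$duration / meta$dt)
    structure(list(time = d$time_ms, command_v = d$v_command_mV,
                   current = d$i_pA, capacitance = meta$capacitance,
                   carrier = meta$carrier, protocol_name = meta$protocol_name,
                   sweep_index = id, segments = sweep,
                   segment_index = rep(seq_len(nrow(sweep)), n_per),
                   state_end = NULL,
                   meta = list(dt = meta$dt, hp = meta$hp,
                               junction_offset = meta$junction_offset,
                               variant = meta$variant)),
              class = "cav_sweep")
  })
}
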