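# Container I/O. One HDF5 file per recording (groups /lfp, /spikes, /stim,
# /meta); result tables as delimited text with a header line and times
# printed with full float64 precision so a write -> read round trip is
# the identity.

#' Write a recording (plus optional spikes and stimulation) to HDF5
#'
#' Layout: `lfp/data` (channels x samples, float), `lfp/fs`, `lfp/t0`,
#' `meta/channels` (compound table), `spikes/<unit_id>` float64 vectors with
#' a `meta/units` table, `stim/*` protocol fields.
#'
#' @param rec a [recording()].
#' @param path output file path (overwritten if present).
#' @param spikes optional [spike_set()].
#' @param stim optional [stim_protocol()].
#' @export
write_recording <- function(rec, path, spikes = NULL, stim = NULL) {
  validate_recording(rec)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "lfp")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(rec$signal, path, "lfp/data")
  rhdf5::h5write(rec$fs, path, "lfp/fs")
  rhdf5::h5write(rec$t0, path, "lfp/t0")
  # metadata tables are stored column-wise (one dataset per column);
  # compound datasets choke on zero-length strings
  write_cols <- function(df, group) {
    rhdf5::h5createGroup(path, group)
    for (nm in names(df)) {
      v <- df[[nm]]
      if (is.factor(v) || is.character(v)) v <- as.character(v)
      rhdf5::h5write(v, path, paste0(group, "/", nm))
    }
  }
  write_cols(rec$channels, "meta/channels")
  if (!is.null(spikes)) {
    rhdf5::h5createGroup(path, "spikes")
    write_cols(spikes$units, "meta/units")
    for (u in names(spikes$times))
      rhdf5::h5write(spikes$times[[u]], path, paste0("spikes/", u))
  }
  if (!is.null(stim)) {
    rhdf5::h5createGroup(path, "stim")
    rhdf5::h5write(stim$kind, path, "stim/kind")
    rhdf5::h5write(stim$sweep_onsets, path, "stim/sweep_onsets")
    rhdf5::h5write(stim$pulse_onsets, path, "stim/pulse_onsets")
    rhdf5::h5write(stim$pulse_width_s, path, "stim/pulse_width_s")
    rhdf5::h5write(stim$ramp_duration_s, path, "stim/ramp_duration_s")
    rhdf5::h5write(stim$rate_hz, path, "stim/rate_hz")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording container written by [write_recording()]
#'
#' @param path HDF5 file path.
#' @param layout container layout name; only the native `"lfpnet"` layout
#'   (groups `/lfp`, `/spikes`, `/stim`, `/meta`) is supported.
#' @return list with elements `recording`, and `spikes` / `stim` when the
#'   corresponding groups are present (otherwise `NULL`).
#' @export
read_recording <- function(path, layout = "lfpnet") {
  if (!file.exists(path))
    ln_stop(paste0("no such container: ", path), "lfpnet_error_missing_file")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!("lfp" %in% top))
    ln_stop("container lacks /lfp group", "lfpnet_error_missing_field")
  lfp_names <- rhdf5::h5ls(path)$name
  if (!("fs" %in% lfp_names))
    ln_stop("container lacks lfp/fs", "lfpnet_error_missing_field")
  sig <- as.matrix(rhdf5::h5read(path, "lfp/data"))
  fs <- as.numeric(rhdf5::h5read(path, "lfp/fs"))
  t0 <- as.numeric(rhdf5::h5read(path, "lfp/t0"))
  read_cols <- function(group) {
    as.data.frame(lapply(rhdf5::h5read(path, group), as.vector),
                  stringsAsFactors = FALSE)
  }
  ch <- read_cols("meta/channels")
  rec <- recording(sig, fs, ch, t0)  # validates NaN / fs here
  spikes <- NULL
  if ("spikes" %in% top) {
    un <- read_cols("meta/units")
    tms <- lapply(as.character(un$unit_id), function(u)
      as.numeric(rhdf5::h5read(path, paste0("spikes/", u))))
    names(tms) <- as.character(un$unit_id)
    spikes <- spike_set(un, tms)
  }
  stim <- NULL
  if ("stim" %in% top) {
    stim <- stim_protocol(
      kind = as.character(rhdf5::h5read(path, "stim/kind")),
      sweep_onsets = as.numeric(rhdf5::h5read(path, "stim/sweep_onsets")),
      pulse_onsets = as.numeric(rhdf5::h5read(path, "stim/pulse_onsets")),
      pulse_width_s = as.numeric(rhdf5::h5read(path, "stim/pulse_width_s")),
      ramp_duration_s = as.numeric(rhdf5::h5read(path, "stim/ramp_duration_s")),
      rate_hz = as.numeric(rhdf5::h5read(path, "stim/rate_hz")))
  }
  list(recording = rec, spikes = spikes, stim = stim)
}

#' Write an event table (or any result data.frame) as CSV
#'
#' Numeric columns are printed with 15 significant digits so the table
#' re-reads to float64 identity.
#' @param x data.frame (e.g. an [event_table()]).
#' @param path output CSV path.
#' @export
write_tables <- function(x, path) {
  df <- as.data.frame(x)
  fmt <- df
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- formatC(fmt[[j]], digits = 15,
                                                 format = "g")
  ok <- tryCatch({
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ln_stop(paste0("cannot write ", path), "lfpnet_error_unwritable")
  invisible(path)
}

#' Read an event table written by [write_tables()]
#' @param path CSV path with columns channel,start_s,stop_s,duration_s,peak_rms_uv.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  event_table(df$channel, df$start_s, df$stop_s, df$peak_rms_uv)
}
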