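# Domain containers shared by all pipeline stages: multichannel recordings,
# oscillatory-event tables, spike sets, stimulation protocols, spectra and
# fitted MVAR models. All times are seconds (float64), epochs half-open
# [start, stop); channel indices are 1-based throughout the R interface.

REGIONS <- c("LEC", "HP", "PFC")

#' Multichannel continuous recording
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channels data.frame with columns `index` (unique integer),
#'   `region` (one of `"LEC"`, `"HP"`, `"PFC"`), `layer` (free text) and
#'   `depth_um` (numeric).
#' @param t0 recording start time in seconds.
#' @return object of class `"recording"`.
#' @export
recording <- function(signal, fs, channels = NULL, t0 = 0) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  if (is.null(channels)) {
    channels <- data.frame(index = seq_len(nrow(signal)),
                           region = rep_len(REGIONS, nrow(signal)),
                           layer = "", depth_um = 0)
  }
  obj <- structure(list(signal = signal, fs = fs,
                        channels = channels, t0 = t0),
                   class = "recording")
  validate_recording(obj)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.1f s at %g Hz (t0 = %g s)\n",
              nrow(x$signal), ncol(x$signal) / x$fs, x$fs, x$t0))
  invisible(x)
}

validate_recording <- function(x) {
  if (is.null(x$fs)) ln_stop("recording lacks fs", "lfpnet_error_missing_field")
  if (!is_scalar_num(x$fs) || x$fs <= 0)
    ln_stop("fs must be a positive number", "lfpnet_error_fs")
  if (nrow(x$signal) < 1L)
    ln_stop("recording needs at least one channel", "lfpnet_error_channels")
  if (anyNA(x$signal) || any(!is.finite(x$signal)))
    ln_stop("signal contains NaN/Inf samples", "lfpnet_error_nan_signal")
  ch <- x$channels
  need <- c("index", "region", "layer", "depth_um")
  if (!all(need %in% names(ch)))
    ln_stop("channel table lacks required columns", "lfpnet_error_missing_field")
  if (anyDuplicated(ch$index))
    ln_stop("channel indices must be unique", "lfpnet_error_channels")
  if (nrow(ch) != nrow(x$signal))
    ln_stop("channel table and signal row count differ", "lfpnet_error_channels")
  if (!all(ch$region %in% REGIONS))
    ln_stop("region labels must be one of LEC, HP, PFC", "lfpnet_error_channels")
  x
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Table of detected oscillatory events
#'
#' One row per event: `channel`, `start_s`, `stop_s`, `duration_s`,
#' `peak_rms_uv`. Events on one channel must be sorted and non-overlapping.
#' @param channel integer channel index per event.
#' @param start_s,stop_s event bounds in seconds (half-open).
#' @param peak_rms_uv peak RMS amplitude inside the event, microvolts.
#' @return data.frame of class `"event_table"`.
#' @export
event_table <- function(channel = integer(0), start_s = numeric(0),
                        stop_s = numeric(0), peak_rms_uv = numeric(0)) {
  df <- data.frame(channel = as.integer(channel), start_s = start_s,
                   stop_s = stop_s, duration_s = stop_s - start_s,
                   peak_rms_uv = peak_rms_uv)
  df <- df[order(df$channel, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  validate_event_table(df)
}

validate_event_table <- function(x) {
  if (nrow(x) == 0) return(x)
  if (any(x$stop_s <= x$start_s))
    ln_stop("event stop must exceed start", "lfpnet_error_events")
  if (any(abs(x$duration_s - (x$stop_s - x$start_s)) > 1e-9))
    ln_stop("duration must equal stop - start", "lfpnet_error_events")
  for (ch in unique(x$channel)) {
    e <- x[x$channel == ch, ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$stop_s[-nrow(e)]))
      ln_stop("events on one channel must be non-overlapping",
              "lfpnet_error_events")
  }
  x
}

#' Per-unit spike times with region/layer labels
#'
#' @param units data.frame with columns `unit_id`, `region`, `layer`.
#' @param times named list of strictly increasing numeric vectors (seconds),
#'   one per unit, names matching `unit_id`.
#' @param span optional `c(t0, t1)`; spike times must fall inside.
#' @return object of class `"spike_set"`.
#' @export
spike_set <- function(units, times, span = NULL) {
  obj <- structure(list(units = units, times = times, span = span),
                   class = "spike_set")
  validate_spike_set(obj)
}

validate_spike_set <- function(x) {
  if (!all(c("unit_id", "region", "layer") %in% names(x$units)))
    ln_stop("spike set unit table lacks required columns",
            "lfpnet_error_missing_field")
  if (!setequal(names(x$times), as.character(x$units$unit_id)))
    ln_stop("spike time list names must match unit ids", "lfpnet_error_spikes")
  for (u in names(x$times)) {
    tt <- x$times[[u]]
    if (length(tt) > 1 && any(diff(tt) <= 0))
      ln_stop("spike times must be strictly increasing per unit",
              "lfpnet_error_spikes")
    if (!is.null(x$span) && length(tt) > 0 &&
        (min(tt) < x$span[1] || max(tt) > x$span[2]))
      ln_stop("spike times outside recording span", "lfpnet_error_spikes")
  }
  x
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %d unit(s), %d spikes total\n",
              nrow(x$units), sum(lengths(x$times))))
  invisible(x)
}

#' Optogenetic stimulation protocol
#'
#' Pulse-train (`kind = "pulse"`) or linear ramp (`kind = "ramp"`) sweeps.
#' Absolute pulse times are `sweep_onsets[i] + pulse_onsets`.
#'
#' @param kind `"pulse"` or `"ramp"`.
#' @param sweep_onsets sweep start times, seconds (absolute).
#' @param pulse_onsets pulse onsets within a sweep, seconds (relative,
#'   non-negative, increasing). Ignored for ramps.
#' @param pulse_width_s pulse duration, seconds.
#' @param ramp_duration_s ramp duration, seconds.
#' @param rate_hz nominal pulse rate within a sweep, Hz.
#' @return object of class `"stim_protocol"`.
#' @export
stim_protocol <- function(kind = c("pulse", "ramp"), sweep_onsets,
                          pulse_onsets = numeric(0), pulse_width_s = 0.003,
                          ramp_duration_s = 3, rate_hz = 8) {
  kind <- match.arg(kind)
  obj <- structure(list(kind = kind, sweep_onsets = sweep_onsets,
                        pulse_onsets = pulse_onsets,
                        pulse_width_s = pulse_width_s,
                        ramp_duration_s = ramp_duration_s, rate_hz = rate_hz),
                   class = "stim_protocol")
  validate_stim_protocol(obj)
}

validate_stim_protocol <- function(x) {
  if (x$pulse_width_s <= 0)
    ln_stop("pulse width must be positive", "lfpnet_error_stim")
  if (length(x$pulse_onsets) > 0) {
    if (any(x$pulse_onsets < 0) || any(diff(x$pulse_onsets) <= 0))
      ln_stop("pulse onsets must be non-negative and increasing",
              "lfpnet_error_stim")
    if (x$kind == "pulse") {
      span <- max(x$pulse_onsets) - min(x$pulse_onsets)
      n_expected <- round(span * x$rate_hz) + 1L
      if (abs(n_expected - length(x$pulse_onsets)) > 1L)
        ln_stop("pulse count inconsistent with rate and sweep span",
                "lfpnet_error_stim")
    }
  }
  x
}

#' All absolute pulse onset times of a protocol
#' @param protocol a [stim_protocol()].
#' @export
pulse_times <- function(protocol) {
  if (length(protocol$pulse_onsets) == 0) return(numeric(0))
  as.vector(outer(protocol$pulse_onsets, protocol$sweep_onsets, `+`))
}

#' Power spectrum container
#' @param freqs frequency grid, Hz (increasing).
#' @param power power density per frequency (microvolts^2/Hz), all >= 0.
#' @param baseline optional baseline density P0(f) on the same grid.
#' @param normalized logical; `TRUE` if `power` is a ratio P/P0.
#' @param n_segments number of Welch segments averaged.
#' @export
power_spectrum <- function(freqs, power, baseline = NULL,
                           normalized = FALSE, n_segments = NA_integer_) {
  if (any(diff(freqs) <= 0))
    ln_stop("frequency grid must be increasing", "lfpnet_error_spectrum")
  if (any(power < 0))
    ln_stop("power density must be non-negative", "lfpnet_error_spectrum")
  structure(list(freqs = freqs, power = power, baseline = baseline,
                 normalized = normalized, n_segments = n_segments),
            class = "power_spectrum")
}

#' Fitted (or constructed) multivariate autoregressive model
#'
#' @param A numeric array `[k, k, p]` of lag coefficient matrices.
#' @param Sigma innovation covariance `[k, k]` (symmetric PSD).
#' @param fs_model sampling rate of the modeled series, Hz.
#' @param labels optional channel/region labels of length k.
#' @export
mvar_model <- function(A, Sigma, fs_model, labels = NULL) {
  if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
  k <- dim(A)[1L]
  if (dim(A)[2L] != k || !all(dim(Sigma) == k))
    ln_stop("A matrices and Sigma must be k x k", "lfpnet_error_mvar")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    ln_stop("Sigma must be symmetric", "lfpnet_error_mvar")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    ln_stop("Sigma must be positive semi-definite", "lfpnet_error_mvar")
  obj <- structure(list(A = A, Sigma = Sigma, order = dim(A)[3L],
                        fs_model = fs_model,
                        labels = labels %||% paste0("ch", seq_len(k))),
                   class = "mvar_model")
  if (max(Mod(companion_eigenvalues(obj))) >= 1)
    ln_stop("MVAR model is unstable (companion eigenvalue modulus >= 1)",
            "lfpnet_error_unstable_mvar")
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eigenvalues of the MVAR companion matrix (stability check)
#' @param model an [mvar_model()].
#' @export
companion_eigenvalues <- function(model) {
  k <- dim(model$A)[1L]; p <- model$order
  C <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) C[1:k, ((r - 1) * k + 1):(r * k)] <- model$A[, , r]
  if (p > 1) C[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  eigen(C, only.values = TRUE)$values
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> k = %d, order = %d, fs = %g Hz, max |eig| = %.3f\n",
              dim(x$A)[1L], x$order, x$fs_model,
              max(Mod(companion_eigenvalues(x)))))
  invisible(x)
}
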