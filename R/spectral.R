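# Power spectral density of oscillatory epochs (Welch, 1 s non-overlapping
# segments), baseline normalization, band averaging, Morlet time-frequency
# transform.

# pull fixed-length segments of one channel from event / baseline intervals
event_segments <- function(rec, events, channel, seg_s) {
  ci <- match(channel, rec$channels$index)
  ev <- events[events$channel == channel, , drop = FALSE]
  iv <- data.frame(start = ev$start_s, stop = ev$stop_s)
  starts <- tile_intervals(iv, seg_s)
  extract_epochs(rec$signal[ci, ], rec$fs, rec$t0, starts, seg_s)
}

#' Welch power spectral density of oscillatory events
#'
#' Each event on `channel` is tiled into non-overlapping segments of
#' `seg_s` seconds (default 1 s, i.e. 1 Hz resolution at 1 kHz); leftover
#' tail shorter than a segment is discarded. Welch's method (Hamming
#' taper, non-overlapping segments) is applied over all segments pooled
#' across events.
#'
#' @param rec a [recording()].
#' @param events an [event_table()] (ignored when `whole_trace = TRUE`).
#' @param channel channel index to analyze.
#' @param seg_s segment length, s.
#' @param whole_trace tile the entire recording instead of events (the
#'   convention for continuous, non-burst activity).
#' @return a [power_spectrum()] (density, uV^2/Hz).
#' @export
psd_events <- function(rec, events = NULL, channel = 1, seg_s = 1,
                       whole_trace = FALSE) {
  segs <- if (whole_trace) {
    iv <- data.frame(start = rec$t0, stop = rec$t0 + rec_duration(rec))
    extract_epochs(rec$signal[match(channel, rec$channels$index), ],
                   rec$fs, rec$t0, tile_intervals(iv, seg_s), seg_s)
  } else {
    event_segments(rec, events, channel, seg_s)
  }
  if (nrow(segs) == 0)
    ln_stop("no usable segments of the requested length",
            "lfpnet_error_no_segments")
  w <- welch_epochs(segs, fs = rec$fs)
  power_spectrum(w$freqs, Re(w$pxy), n_segments = w$n_epochs)
}

#' Baseline power of windows lacking oscillatory activity
#'
#' Same Welch settings as [psd_events()], on segments tiled from the
#' inter-event intervals of length at least `seg_s`.
#'
#' @inheritParams psd_events
#' @param min_segments warn when fewer baseline segments are available.
#' @export
psd_baseline <- function(rec, events, channel = 1, seg_s = 1,
                         min_segments = 10) {
  ev <- events[events$channel == channel, , drop = FALSE]
  t_end <- rec$t0 + rec_duration(rec)
  bounds <- c(rec$t0, as.vector(rbind(ev$start_s, ev$stop_s)), t_end)
  gaps <- data.frame(start = bounds[seq(1, length(bounds), by = 2)],
                     stop = bounds[seq(2, length(bounds), by = 2)])
  gaps <- gaps[gaps$stop - gaps$start >= seg_s, , drop = FALSE]
  ci <- match(channel, rec$channels$index)
  segs <- extract_epochs(rec$signal[ci, ], rec$fs, rec$t0,
                         tile_intervals(gaps, seg_s), seg_s)
  if (nrow(segs) == 0)
    ln_stop("no inter-event baseline segments available",
            "lfpnet_error_no_segments")
  if (nrow(segs) < min_segments)
    ln_warn(sprintf("only %d baseline segments", nrow(segs)),
            "lfpnet_warning_few_segments")
  w <- welch_epochs(segs, fs = rec$fs)
  power_spectrum(w$freqs, Re(w$pxy), n_segments = w$n_epochs)
}

#' Event power normalized to baseline power
#'
#' @param p event [power_spectrum()] P(f).
#' @param p0 baseline [power_spectrum()] P0(f) on the same frequency grid.
#' @return a [power_spectrum()] holding the ratio P(f)/P0(f)
#'   (`normalized = TRUE`).
#' @export
psd_relative <- function(p, p0) {
  if (length(p$freqs) != length(p0$freqs) ||
      max(abs(p$freqs - p0$freqs)) > 1e-9)
    ln_stop("frequency grids differ", "lfpnet_error_grid")
  if (any(p0$power <= 0))
    ln_stop("baseline power contains non-positive values",
            "lfpnet_error_baseline")
  power_spectrum(p$freqs, p$power / p0$power, baseline = p0$power,
                 normalized = TRUE, n_segments = p$n_segments)
}

#' Arithmetic mean of a spectrum over a frequency band
#'
#' Averages grid points with `f_lo <= f <= f_hi` (inclusive).
#'
#' @param x a [power_spectrum()], coherence spectrum, directed spectrum
#'   (see [gpdc()]), or a list with `freqs` plus a numeric `values` field.
#' @param f_lo,f_hi band edges, Hz.
#' @param ... passed to methods: `value` selects the field for coherence
#'   spectra (`"imag"` or `"magnitude"`); `source`/`target` select the
#'   directed pair for directed spectra.
#' @return scalar band average (or a k x k matrix for directed spectra
#'   when no pair is selected).
#' @export
band_average <- function(x, f_lo, f_hi, ...) UseMethod("band_average")

band_idx <- function(freqs, f_lo, f_hi) {
  sel <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(sel) == 0)
    ln_stop("band contains no frequency grid points", "lfpnet_error_band")
  sel
}

#' @export
band_average.power_spectrum <- function(x, f_lo, f_hi, ...) {
  mean(x$power[band_idx(x$freqs, f_lo, f_hi)])
}

#' @export
band_average.coherence_spectrum <- function(x, f_lo, f_hi,
                                            value = c("imag", "magnitude"),
                                            ...) {
  value <- match.arg(value)
  v <- if (value == "imag") x$imag else x$magnitude
  mean(v[band_idx(x$freqs, f_lo, f_hi)])
}

#' @export
band_average.directed_spectrum <- function(x, f_lo, f_hi, source = NULL,
                                           target = NULL, ...) {
  sel <- band_idx(x$freqs, f_lo, f_hi)
  m <- apply(x$gpdc[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(m) <- list(target = x$labels, source = x$labels)
  if (is.null(source) || is.null(target)) return(m)
  m[target, source]
}

#' @export
band_average.default <- function(x, f_lo, f_hi, ...) {
  mean(x$values[band_idx(x$freqs, f_lo, f_hi)])
}

#' Morlet continuous wavelet transform magnitude
#'
#' FFT-based Morlet transform (center-frequency parameter `omega0 = 6`).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz, strictly inside (0, fs/2).
#' @param omega0 Morlet center-frequency parameter.
#' @return magnitude matrix `[length(freqs) x length(x)]` with attributes
#'   `freqs` and `t`.
#' @export
morlet_tf <- function(x, fs, freqs, omega0 = 6) {
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    ln_stop("analysis frequencies must lie in (0, fs/2)", "lfpnet_error_band")
  n <- length(x)
  X <- stats::fft(x)
  wk <- 2 * pi * (0:(n - 1)) / n * fs   # angular frequency per FFT bin
  wk[wk > pi * fs] <- wk[wk > pi * fs] - 2 * pi * fs
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])   # wavelet scale, seconds
    psi <- pi^(-0.25) * exp(-((s * wk - omega0)^2) / 2) * (wk > 0)
    out[i, ] <- Mod(stats::fft(X * psi, inverse = TRUE) / n) *
      sqrt(2 * pi * s * fs)
  }
  attr(out, "freqs") <- freqs
  attr(out, "t") <- (0:(n - 1)) / fs
  out
}
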