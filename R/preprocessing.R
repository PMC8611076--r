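# Phase-preserving filtering, band splitting, downsampling and RMS
# envelopes. All filters are Butterworth designs applied forward-backward
# (zero group delay; the effective magnitude order doubles and is not
# compensated).

#' Zero-phase Butterworth band-pass filter
#'
#' @param x a [recording()] or a numeric vector.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order of the one-pass design (default 3).
#' @param fs sampling rate, required when `x` is a plain vector.
#' @return filtered object of the same type as `x`.
#' @export
bandpass <- function(x, low, high, order = 3, fs = NULL) {
  if (inherits(x, "recording")) fs <- x$fs
  if (is.null(fs)) ln_stop("fs required for vector input", "lfpnet_error_fs")
  if (!(low > 0 && high > low && high < fs / 2))
    ln_stop("band edges must satisfy 0 < low < high < fs/2",
            "lfpnet_error_band")
  if (inherits(x, "recording")) {
    x$signal <- butter_filter_mat(x$signal, fs, "pass", c(low, high), order)
    x
  } else {
    butter_filter_mat(x, fs, "pass", c(low, high), order)
  }
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass
#' @param cutoff cutoff frequency, Hz.
#' @export
lowpass <- function(x, cutoff, order = 3, fs = NULL) {
  if (inherits(x, "recording")) fs <- x$fs
  if (is.null(fs)) ln_stop("fs required for vector input", "lfpnet_error_fs")
  if (!(cutoff > 0 && cutoff < fs / 2))
    ln_stop("cutoff must lie in (0, fs/2)", "lfpnet_error_band")
  if (inherits(x, "recording")) {
    x$signal <- butter_filter_mat(x$signal, fs, "low", cutoff, order)
    x
  } else {
    butter_filter_mat(x, fs, "low", cutoff, order)
  }
}

#' Convert a wide-band recording to an LFP recording
#'
#' Third-order zero-phase low-pass below 1500 Hz followed by resampling to
#' `target_fs` (default 1000 Hz). Because the 1500 Hz cutoff exceeds the
#' post-resampling Nyquist, an additional anti-alias low-pass (default
#' 400 Hz) is applied unless `antialias = FALSE`; the choice is recorded in
#' the returned recording's `provenance` attribute.
#'
#' @param rec a [recording()] with `fs >= 2 * target_fs`.
#' @param target_fs output sampling rate, Hz.
#' @param antialias apply the extra anti-alias stage (default `TRUE`).
#' @param antialias_cutoff cutoff of the extra stage, Hz.
#' @export
make_lfp <- function(rec, target_fs = 1000, antialias = TRUE,
                     antialias_cutoff = 400) {
  if (rec$fs < 2 * target_fs)
    ln_stop("input sampling rate must be at least twice the target",
            "lfpnet_error_fs")
  out <- rec
  if (1500 < rec$fs / 2)
    out$signal <- butter_filter_mat(out$signal, rec$fs, "low", 1500, 3)
  if (antialias)
    out$signal <- butter_filter_mat(out$signal, rec$fs, "low",
                                    antialias_cutoff, 4)
  n_out <- round(ncol(rec$signal) * target_fs / rec$fs)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    idx <- seq(1L, by = as.integer(round(q)), length.out = n_out)
    out$signal <- out$signal[, idx, drop = FALSE]
  } else {
    out$signal <- t(apply(out$signal, 1L, function(row)
      signal::resample(row, p = target_fs, q = rec$fs)))[, seq_len(n_out),
                                                         drop = FALSE]
  }
  out$fs <- target_fs
  attr(out, "provenance") <- list(lowpass_hz = 1500, order = 3,
                                  antialias = antialias,
                                  antialias_cutoff = if (antialias)
                                    antialias_cutoff else NA)
  out
}

#' Band-pass a wide-band recording into the multi-unit activity band
#'
#' 500-5000 Hz zero-phase band-pass; requires `fs > 10` kHz.
#' @param rec a [recording()].
#' @param order filter order (default 3).
#' @export
mua_band <- function(rec, order = 3) {
  if (rec$fs <= 10000)
    ln_stop("MUA band extraction needs fs > 10 kHz", "lfpnet_error_fs")
  bandpass(rec, 500, 5000, order = order)
}

#' Sliding root-mean-square envelope
#'
#' RMS over windows of `window` seconds advanced by `step` seconds;
#' timestamps are window centers.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window window length, s (`window >= step > 0`).
#' @param step hop, s.
#' @param t0 time of the first sample, s.
#' @return list with `t` (window centers, s) and `rms`.
#' @export
rms_envelope <- function(x, fs, window = 0.2, step = 0.01, t0 = 0) {
  if (!(step > 0 && window >= step))
    ln_stop("need window >= step > 0", "lfpnet_error_window")
  w <- max(1L, round(window * fs))
  s <- max(1L, round(step * fs))
  n <- length(x)
  if (n < w) ln_stop("signal shorter than one window", "lfpnet_error_window")
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, n - w + 1L, by = s)
  rms <- sqrt((cs[starts + w] - cs[starts]) / w)
  list(t = t0 + (starts - 1L + (w - 1L) / 2) / fs, rms = rms)
}
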