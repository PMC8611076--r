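# Internal helpers: classed conditions, zero-phase IIR filtering, Welch
# spectra, FFT resampling, interval arithmetic.

ln_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lfpnet_error")))
}

ln_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "lfpnet_warning")))
}

#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Zero-phase (forward-backward) IIR filtering with reflect padding
#'
#' Pads with odd reflection of 3 x filter length at both ends to suppress
#' edge transients, filters forward and backward, trims the padding.
#' Effective magnitude response is squared; group delay is zero.
#' @noRd
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  npad <- 3L * max(length(a), length(b))
  if (n <= npad) npad <- max(1L, n - 1L)
  # odd (point-reflected) extension as in common filtfilt implementations
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  ext <- c(pre, x, post)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Design a zero-phase Butterworth filter and apply it per row of a matrix
#' @noRd
butter_filter_mat <- function(x, fs, type, cutoff, order) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    ln_stop("cutoff frequencies must lie strictly inside (0, fs/2)",
            "lfpnet_error_band")
  }
  flt <- signal::butter(order, w, type = type)
  if (is.matrix(x)) {
    t(apply(x, 1L, function(row) filtfilt_reflect(flt$b, flt$a, row)))
  } else {
    filtfilt_reflect(flt$b, flt$a, x)
  }
}

#' One-sided Welch auto/cross spectra over pre-cut epochs
#'
#' `x`, `y`: matrices [n_epoch x n_samples] of equal shape. Each epoch is
#' tapered (Hamming) and Fourier transformed; spectra are averaged over
#' epochs. Returns density in units^2/Hz (one-sided).
#' @noRd
welch_epochs <- function(x, y = NULL, fs, taper = c("hamming", "rect")) {
  taper <- match.arg(taper)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.null(y) && !is.matrix(y)) y <- matrix(y, nrow = 1L)
  nseg <- nrow(x)
  nsamp <- ncol(x)
  if (!is.null(y) && !all(dim(y) == dim(x))) {
    ln_stop("x and y epochs must have identical dimensions",
            "lfpnet_error_epochs")
  }
  w <- if (taper == "hamming" && nsamp > 1) {
    0.54 - 0.46 * cos(2 * pi * (0:(nsamp - 1)) / (nsamp - 1))
  } else {
    rep(1, nsamp)
  }
  U <- fs * sum(w^2)  # density normalization
  Fx <- stats::mvfft(t(x * matrix(w, nseg, nsamp, byrow = TRUE)))
  Fy <- if (is.null(y)) Fx else
    stats::mvfft(t(y * matrix(w, nseg, nsamp, byrow = TRUE)))
  nf <- nsamp %/% 2 + 1L
  idx <- seq_len(nf)
  cross <- Fx[idx, , drop = FALSE] * Conj(Fy[idx, , drop = FALSE]) / U
  pxy <- rowMeans(cross)
  scale2 <- rep(2, nf)
  scale2[1L] <- 1
  if (nsamp %% 2 == 0) scale2[nf] <- 1
  pxy <- pxy * scale2
  list(freqs = (idx - 1L) * fs / nsamp, pxy = pxy, n_epochs = nseg)
}

#' FFT-based integer-factor band-limited upsampling
#' @noRd
fft_upsample <- function(x, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  n <- length(x)
  X <- stats::fft(x)
  m <- n * factor
  Y <- complex(m)
  half <- n %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 0) Y[(m - half + 2):m] <- X[(n - half + 2):n]
  if (n %% 2 == 0) { # split Nyquist bin
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- Conj(X[half + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * factor / m
}

#' 1/f^alpha spectrally shaped Gaussian noise, unit standard deviation
#' @noRd
pink_noise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1e-6, seq_len(n - 1)) # avoid DC blow-up
  f <- pmin(f, n - f)          # symmetric frequency index
  X <- X * (1 / f^(exponent / 2))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Intersect two sets of half-open intervals [start, stop)
#' @noRd
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(start = numeric(0), stop = numeric(0)))
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$stop[i], b$stop)
    keep <- e > s
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  o <- order(out_s)
  data.frame(start = out_s[o], stop = out_e[o])
}

#' Tile intervals into non-overlapping fixed-length segments
#' @noRd
tile_intervals <- function(intervals, seg_s) {
  starts <- numeric(0)
  for (i in seq_len(nrow(intervals))) {
    dur <- intervals$stop[i] - intervals$start[i]
    k <- floor(dur / seg_s)
    if (k >= 1) starts <- c(starts, intervals$start[i] + (0:(k - 1)) * seg_s)
  }
  starts
}

#' Extract epochs [n_epoch x n_samp] from one channel of a signal matrix
#' @noRd
extract_epochs <- function(sig, fs, t0, starts, seg_s) {
  nsamp <- round(seg_s * fs)
  idx0 <- round((starts - t0) * fs) + 1L
  keep <- idx0 >= 1L & (idx0 + nsamp - 1L) <= length(sig)
  idx0 <- idx0[keep]
  if (length(idx0) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = nsamp))
  t(vapply(idx0, function(i) sig[i:(i + nsamp - 1L)], numeric(nsamp)))
}
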