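# Coherence (magnitude and imaginary part, with shuffled-epoch null),
# pooled-epoch MVAR estimation and generalized partial directed coherence.
#
# Coherency: C_XY(f) = P_XY(f) / sqrt(P_XX(f) P_YY(f)) with P_* Welch
# auto-/cross-spectra averaged over co-occurring 1 s epochs. Magnitude
# coherence is |C_XY|; the imaginary coherence |Im C_XY| is insensitive to
# instantaneous (volume-conducted) mixing.
#
# gPDC (generalized PDC): with Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs),
#   gpdc[i<-j](f) = (|Abar_ij(f)| / sigma_i) /
#                   sqrt(sum_k |Abar_kj(f)|^2 / sigma_k^2),
# sigma_i = sqrt(Sigma_ii), so each source column is normalized:
# sum_i gpdc[i<-j]^2 = 1 at every frequency.

#' Welch cross- and auto-spectra over paired epochs
#'
#' @param x_epochs,y_epochs matrices `[n_epochs x n_samples]` of
#'   co-occurring epochs (equal shapes).
#' @param fs sampling rate, Hz.
#' @return list of class `"cross_spectra"` with `freqs`, complex `pxy`,
#'   real `pxx`, `pyy`, and `n_epochs`.
#' @export
cross_spectra <- function(x_epochs, y_epochs, fs) {
  wxy <- welch_epochs(x_epochs, y_epochs, fs)
  wxx <- welch_epochs(x_epochs, fs = fs)
  wyy <- welch_epochs(y_epochs, fs = fs)
  structure(list(freqs = wxy$freqs, pxy = wxy$pxy, pxx = Re(wxx$pxy),
                 pyy = Re(wyy$pxy), n_epochs = wxy$n_epochs),
            class = "cross_spectra")
}

#' Magnitude and imaginary coherence from cross-spectra
#'
#' @param cs a [cross_spectra()] object.
#' @return list of class `"coherence_spectrum"` with `freqs`, `magnitude`
#'   (in `[0, 1]`), `imag` (`|Im|` of the coherency) and `n_epochs`.
#' @export
coherence <- function(cs) {
  if (any(cs$pxx <= 0) || any(cs$pyy <= 0))
    ln_stop("zero auto-spectrum; coherence undefined", "lfpnet_error_spectrum")
  coh <- cs$pxy / sqrt(cs$pxx * cs$pyy)
  structure(list(freqs = cs$freqs, magnitude = Mod(coh),
                 imag = abs(Im(coh)), n_epochs = cs$n_epochs),
            class = "coherence_spectrum")
}

#' Shuffled-epoch coherence null
#'
#' Re-pairs the epochs of the two signals by a random derangement (cyclic
#' rotation by a nonzero offset), recomputes the coherence, and averages
#' over `n_shuffle` permutations. Destroys consistent phase relations
#' while keeping the marginal spectra.
#'
#' @inheritParams cross_spectra
#' @param n_shuffle number of permutations (>= 1).
#' @param seed optional RNG seed.
#' @return list of class `"coherence_spectrum"` (mean null `magnitude` and
#'   `imag`).
#' @export
shuffle_null <- function(x_epochs, y_epochs, fs, n_shuffle = 100,
                         seed = NULL) {
  if (n_shuffle < 1)
    ln_stop("n_shuffle must be at least 1", "lfpnet_error_config")
  n <- nrow(x_epochs)
  if (n < 2) ln_stop("need at least 2 epochs to shuffle",
                     "lfpnet_error_epochs")
  if (!is.null(seed)) set.seed(seed)
  acc_mag <- 0; acc_im <- 0; freqs <- NULL
  for (s in seq_len(n_shuffle)) {
    rot <- sample.int(n - 1L, 1L)
    perm <- c((rot + 1L):n, 1L:rot)
    co <- coherence(cross_spectra(x_epochs, y_epochs[perm, , drop = FALSE],
                                  fs))
    freqs <- co$freqs
    acc_mag <- acc_mag + co$magnitude
    acc_im <- acc_im + co$imag
  }
  structure(list(freqs = freqs, magnitude = acc_mag / n_shuffle,
                 imag = acc_im / n_shuffle, n_epochs = n),
            class = "coherence_spectrum")
}

#' Fit a multivariate autoregressive model by pooled least squares
#'
#' Epochs are pooled without crossing epoch boundaries: each epoch
#' contributes rows `p+1 .. n` of its own lagged design. The order is
#' chosen by BIC over `1..p_max` unless `order` is fixed; stability of the
#' selected model is enforced.
#'
#' @param epochs list of numeric matrices `[n_samples x k]` (time by
#'   channel), or a single matrix.
#' @param fs_model sampling rate of the modeled series, Hz.
#' @param order fixed model order, or `NULL` for BIC selection.
#' @param p_max maximum order scanned by BIC.
#' @param labels optional channel labels.
#' @return an [mvar_model()] with extra fields `bic` (scanned values) and
#'   `selected_order`.
#' @export
fit_mvar <- function(epochs, fs_model, order = NULL, p_max = 20,
                     labels = NULL) {
  if (is.matrix(epochs)) epochs <- list(epochs)
  k <- ncol(epochs[[1L]])
  if (k < 2) ln_stop("MVAR fitting needs at least 2 channels",
                     "lfpnet_error_mvar")
  n_tot <- sum(vapply(epochs, nrow, 0L))
  orders <- if (is.null(order)) seq_len(p_max) else order
  if (k^2 * max(orders) * 10 > n_tot * k)
    ln_stop("insufficient samples for the requested order",
            "lfpnet_error_insufficient_samples")
  fit_order <- function(p) {
    Xs <- list(); Ys <- list()
    for (e in epochs) {
      n <- nrow(e)
      if (n <= p) next
      rows <- (p + 1):n
      X <- matrix(0, length(rows), k * p)
      for (r in seq_len(p))
        X[, ((r - 1) * k + 1):(r * k)] <- e[rows - r, , drop = FALSE]
      Xs[[length(Xs) + 1L]] <- X
      Ys[[length(Ys) + 1L]] <- e[rows, , drop = FALSE]
    }
    X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
    N <- nrow(X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      ln_stop("rank-deficient regressor matrix", "lfpnet_error_rank")
    B <- qr.coef(qrX, Y)                       # [k*p x k]
    resid <- Y - X %*% B
    sigma_ml <- crossprod(resid) / N
    bic <- N * determinant(sigma_ml, logarithm = TRUE)$modulus +
      log(N) * p * k^2
    A <- array(0, c(k, k, p))
    for (r in seq_len(p))
      A[, , r] <- t(B[((r - 1) * k + 1):(r * k), , drop = FALSE])
    Sigma <- crossprod(resid) / max(1, N - k * p)
    list(A = A, Sigma = Sigma, bic = as.numeric(bic))
  }
  fits <- lapply(orders, fit_order)
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- which.min(bics)
  f <- fits[[best]]
  Sigma <- (f$Sigma + t(f$Sigma)) / 2
  m <- mvar_model(f$A, Sigma, fs_model, labels = labels)
  m$bic <- stats::setNames(bics, orders)
  m$selected_order <- orders[best]
  m
}

#' Generalized partial directed coherence of an MVAR model
#'
#' @param model an [mvar_model()] with positive innovation variances.
#' @param freqs evaluation frequencies, Hz.
#' @return list of class `"directed_spectrum"` with `freqs`, `labels` and
#'   array `gpdc[target, source, frequency]`, values in `[0, 1]` with
#'   `sum_target gpdc^2 = 1` per source and frequency.
#' @export
gpdc <- function(model, freqs) {
  k <- dim(model$A)[1L]; p <- model$order
  sig2 <- diag(model$Sigma)
  if (any(sig2 <= 0))
    ln_stop("innovation variances must be positive", "lfpnet_error_mvar")
  out <- array(0, c(k, k, length(freqs)))
  for (fi in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[fi] * seq_len(p) / model$fs_model)
    Abar <- diag(k) + 0i
    for (r in seq_len(p)) Abar <- Abar - model$A[, , r] * z[r]
    W <- Mod(Abar)^2 / sig2            # |Abar_ij|^2 / sigma_i^2
    denom <- sqrt(colSums(W))          # per source column j
    out[, , fi] <- (Mod(Abar) / sqrt(sig2)) / rep(denom, each = k)
  }
  structure(list(freqs = freqs, gpdc = out, labels = model$labels),
            class = "directed_spectrum")
}

#' Co-occurring fixed-length epochs across channels
#'
#' Intersects the event intervals of the selected channels and tiles the
#' intersection into `seg_s` segments; only stretches of joint oscillatory
#' activity of at least one segment length contribute.
#'
#' @param events an [event_table()].
#' @param channels channel indices whose events must co-occur.
#' @param seg_s segment length, s.
#' @return numeric vector of epoch start times, s.
#' @export
co_occurring_epochs <- function(events, channels, seg_s = 1) {
  iv <- NULL
  for (ch in channels) {
    e <- events[events$channel == ch, , drop = FALSE]
    cur <- data.frame(start = e$start_s, stop = e$stop_s)
    iv <- if (is.null(iv)) cur else interval_intersect(iv, cur)
  }
  tile_intervals(iv, seg_s)
}

#' Directed connectivity of a recording: epochs -> MVAR -> gPDC
#'
#' Extracts co-occurring oscillatory epochs on one channel per region,
#' band-limits them (zero-phase, default 1-45 Hz), decimates to the model
#' rate (default 100 Hz; the band limit serves as the anti-alias filter),
#' fits a pooled-epoch MVAR and evaluates the gPDC, band-averaged over
#' `band` (default 4-30 Hz).
#'
#' @param rec a [recording()].
#' @param events an [event_table()] (e.g. from [detect_oscillations()]).
#' @param region_channels named integer vector: one channel index per
#'   region, at least two entries.
#' @param band band for the summary average, Hz.
#' @param bp_band pre-fit band-pass, Hz (also the anti-alias filter).
#' @param fs_model model sampling rate, Hz (divides `rec$fs`).
#' @param order,p_max passed to [fit_mvar()].
#' @param seg_s epoch length, s.
#' @return list with `gpdc` (the [gpdc()] directed spectrum), `band_matrix`
#'   (band-averaged `[target x source]`), `model`, and `n_epochs`.
#' @export
gpdc_pipeline <- function(rec, events, region_channels, band = c(4, 30),
                          bp_band = c(1, 45), fs_model = 100,
                          order = NULL, p_max = 20, seg_s = 1) {
  if (length(region_channels) < 2)
    ln_stop("need channels from at least two regions", "lfpnet_error_config")
  dec <- rec$fs / fs_model
  if (abs(dec - round(dec)) > 1e-9)
    ln_stop("fs_model must divide the recording rate", "lfpnet_error_config")
  dec <- as.integer(round(dec))
  if (bp_band[2] >= fs_model / 2)
    ln_stop("band-pass upper edge must lie below fs_model/2 (anti-alias)",
            "lfpnet_error_band")
  starts <- co_occurring_epochs(events, region_channels, seg_s)
  if (length(starts) == 0)
    ln_stop("no co-occurring epochs", "lfpnet_error_no_segments")
  epochs <- vector("list", length(starts))
  chan_rows <- match(region_channels, rec$channels$index)
  filtered <- lapply(chan_rows, function(ci)
    bandpass(rec$signal[ci, ], bp_band[1], bp_band[2], fs = rec$fs))
  nsamp <- round(seg_s * rec$fs)
  keep_idx <- seq(1L, nsamp, by = dec)
  for (i in seq_along(starts)) {
    i0 <- round((starts[i] - rec$t0) * rec$fs) + 1L
    epochs[[i]] <- vapply(filtered, function(x)
      x[i0:(i0 + nsamp - 1L)][keep_idx], numeric(length(keep_idx)))
  }
  labels <- names(region_channels) %||%
    as.character(rec$channels$region[chan_rows])
  model <- fit_mvar(epochs, fs_model, order = order, p_max = p_max,
                    labels = labels)
  freqs <- seq(1, floor(fs_model / 2) - 1)
  ds <- gpdc(model, freqs)
  list(gpdc = ds, band_matrix = band_average(ds, band[1], band[2]),
       model = model, n_epochs = length(starts))
}
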