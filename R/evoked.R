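# Quantification of light-evoked spiking (firing probability, PSTH,
# modulation index with a sign-flip permutation test), evoked field
# responses, laminar current source density, ramp-epoch power/coherence
# changes, and evoked-EPSC features.

count_in_windows <- function(spike_times, win_starts, win_len) {
  # number of spikes in each half-open window [s, s + win_len)
  if (length(spike_times) == 0) return(integer(length(win_starts)))
  vapply(win_starts, function(s)
    sum(spike_times >= s & spike_times < s + win_len), 0L)
}

#' Light-evoked firing probability per unit
#'
#' Spikes in the 20 ms window after each pulse onset, divided by the total
#' number of pulses (spikes, not pulses, are counted: a pulse with two
#' evoked spikes contributes 2).
#'
#' @param spikes a [spike_set()].
#' @param protocol a pulse [stim_protocol()].
#' @param window_s evoked window after pulse onset, s (default 0.020).
#' @return named numeric vector of firing probabilities per unit.
#' @export
firing_probability <- function(spikes, protocol, window_s = 0.020) {
  pt <- pulse_times(protocol)
  if (length(pt) == 0)
    ln_stop("protocol contains no pulses", "lfpnet_error_stim")
  vapply(spikes$times, function(tt)
    sum(count_in_windows(tt, pt, window_s)) / length(pt), 0)
}

#' Firing rate per unit and pooled over units
#'
#' @param spikes a [spike_set()].
#' @param window `c(t0, t1)` analyzed window, s.
#' @return list with `per_unit` (Hz, named) and `pooled` (all spikes of
#'   all units divided by the window duration, the per-animal convention).
#' @export
firing_rate <- function(spikes, window) {
  dur <- window[2] - window[1]
  if (dur <= 0) ln_stop("empty analysis window", "lfpnet_error_window")
  per <- vapply(spikes$times, function(tt)
    sum(tt >= window[1] & tt < window[2]) / dur, 0)
  list(per_unit = per, pooled = sum(per))
}

#' Peri-stimulus spike-probability histogram
#'
#' Spike probability per bin = spikes in the bin pooled over pulses,
#' divided by the pulse count. Bins are aligned at the pulse onset so that
#' the bins covering `[0, 20)` ms sum to the firing probability.
#'
#' @param spikes a [spike_set()].
#' @param protocol a pulse [stim_protocol()].
#' @param bin_ms bin width, ms.
#' @param span_ms `c(pre, post)` window around the pulse onset, ms.
#' @return list with `breaks_ms`, `mids_ms` and matrix `prob`
#'   `[n_units x n_bins]` (rownames = unit ids).
#' @export
psth <- function(spikes, protocol, bin_ms = 1, span_ms = c(-10, 50)) {
  pt <- pulse_times(protocol)
  if (length(pt) == 0)
    ln_stop("protocol contains no pulses", "lfpnet_error_stim")
  breaks <- seq(span_ms[1], span_ms[2], by = bin_ms)
  prob <- t(vapply(spikes$times, function(tt) {
    rel <- unlist(lapply(pt, function(p) (tt[tt >= p + span_ms[1] / 1000 &
                                               tt < p + span_ms[2] / 1000] - p) * 1000))
    if (length(rel) == 0) return(numeric(length(breaks) - 1))
    graphics::hist(rel, breaks = breaks, plot = FALSE)$counts / length(pt)
  }, numeric(length(breaks) - 1)))
  rownames(prob) <- names(spikes$times)
  list(breaks_ms = breaks, mids_ms = (breaks[-1] + breaks[-length(breaks)]) / 2,
       prob = prob)
}

#' Modulation index and responder classification per unit
#'
#' MI = (r_during - r_pre) / (r_during + r_pre) from per-sweep spike rates
#' (0/0 -> 0). Significance by a per-sweep label permutation test: the
#' pre/during labels of each sweep's counts are flipped independently;
#' two-sided p at `alpha`. Units are `"activated"` (MI > 0, significant),
#' `"inhibited"` (MI < 0, significant), else `"unchanged"`.
#'
#' @param spikes a [spike_set()].
#' @param protocol a [stim_protocol()]; sweeps define the during windows.
#' @param pre_s,during_s window lengths before / from the sweep onset, s.
#' @param n_perm permutations (default 1000).
#' @param alpha two-sided significance level.
#' @param seed optional RNG seed for the permutations.
#' @return data.frame: `unit_id`, `mi`, `p`, `responder_class`,
#'   `rate_pre_hz`, `rate_during_hz`.
#' @export
modulation_index <- function(spikes, protocol, pre_s = 1.5, during_s = 3,
                             n_perm = 1000, alpha = 0.05, seed = NULL) {
  sw <- protocol$sweep_onsets
  if (length(sw) < 5)
    ln_stop("responder classification needs at least 5 sweeps",
            "lfpnet_error_stim")
  if (!is.null(seed)) set.seed(seed)
  ns <- length(sw)
  flips <- matrix(stats::runif(n_perm * ns) < 0.5, n_perm, ns)
  signs <- 1 - 2 * flips   # +1 keep, -1 flip
  res <- lapply(names(spikes$times), function(u) {
    tt <- spikes$times[[u]]
    c_pre <- count_in_windows(tt, sw - pre_s, pre_s)
    c_dur <- count_in_windows(tt, sw, during_s)
    r_pre <- mean(c_pre) / pre_s
    r_dur <- mean(c_dur) / during_s
    mi <- if (r_pre + r_dur == 0) 0 else (r_dur - r_pre) / (r_dur + r_pre)
    d <- c_dur / during_s - c_pre / pre_s
    obs <- sum(d)
    perm <- as.vector(signs %*% d)
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    cls <- if (p < alpha && mi > 0) "activated"
      else if (p < alpha && mi < 0) "inhibited" else "unchanged"
    data.frame(unit_id = u, mi = mi, p = p, responder_class = cls,
               rate_pre_hz = r_pre, rate_during_hz = r_dur)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stimulus-locked average LFP and evoked amplitude
#'
#' Averages the LFP around every pulse; baseline is the mean of the 50 ms
#' preceding the pulse; the amplitude is the largest absolute deviation
#' from baseline within 100 ms after onset, reported with its latency and
#' signed polarity.
#'
#' @param rec a [recording()].
#' @param protocol a pulse [stim_protocol()].
#' @param channel channel index.
#' @param pre_s,post_s trace window around onset, s.
#' @param baseline_s baseline window before onset, s.
#' @param search_s post-onset search window for the peak, s.
#' @return list with `t` (s, relative to onset), `trace` (uV),
#'   `amplitude_uv`, `latency_s`, `polarity` (+/- 1), `n_pulses`.
#' @export
evoked_lfp <- function(rec, protocol, channel = 1, pre_s = 0.05,
                       post_s = 0.15, baseline_s = 0.05, search_s = 0.1) {
  pt <- pulse_times(protocol)
  if (length(pt) == 0)
    ln_stop("protocol contains no pulses", "lfpnet_error_stim")
  ci <- match(channel, rec$channels$index)
  npre <- round(pre_s * rec$fs); npost <- round(post_s * rec$fs)
  segs <- extract_epochs(rec$signal[ci, ], rec$fs, rec$t0, pt - pre_s,
                         pre_s + post_s)
  if (nrow(segs) == 0)
    ln_stop("no pulses fall inside the recording", "lfpnet_error_stim")
  trace <- colMeans(segs)
  t_rel <- (seq_along(trace) - 1) / rec$fs - pre_s
  bl <- mean(trace[t_rel >= -baseline_s & t_rel < 0])
  sel <- which(t_rel >= 0 & t_rel <= search_s)
  dev <- trace[sel] - bl
  pk <- sel[which.max(abs(dev))]
  list(t = t_rel, trace = trace, amplitude_uv = abs(trace[pk] - bl),
       latency_s = t_rel[pk], polarity = sign(trace[pk] - bl),
       n_pulses = nrow(segs))
}

#' Laminar current source density
#'
#' Second spatial difference of the laminar LFP,
#' `CSD_i = -(V_{i-1} - 2 V_i + V_{i+1}) / dz^2`, with Vaknin padding
#' (duplicated end channels) and optional 3-point Hamming spatial
#' smoothing. The sink is the most negative extremum.
#'
#' @param lfp numeric matrix `[n_channels x n_time]` (averaged evoked LFP),
#'   ordered by depth; needs >= 3 channels.
#' @param spacing_um inter-channel spacing, micrometers.
#' @param smooth apply 3-point spatial Hamming smoothing.
#' @return list with `csd` matrix (same shape, uV/um^2), `sink_channel`,
#'   `sink_time_index`.
#' @export
csd <- function(lfp, spacing_um, smooth = FALSE) {
  if (!is.matrix(lfp) || nrow(lfp) < 3)
    ln_stop("CSD needs at least 3 channels", "lfpnet_error_channels")
  V <- rbind(lfp[1, ], lfp, lfp[nrow(lfp), ])   # Vaknin padding
  if (smooth) {
    w <- c(0.23, 0.54, 0.23)
    Vs <- V
    for (i in 2:(nrow(V) - 1))
      Vs[i, ] <- w[1] * V[i - 1, ] + w[2] * V[i, ] + w[3] * V[i + 1, ]
    V <- Vs
  }
  n <- nrow(lfp)
  out <- -(V[1:n, , drop = FALSE] - 2 * V[2:(n + 1), , drop = FALSE] +
             V[3:(n + 2), , drop = FALSE]) / spacing_um^2
  mn <- which(out == min(out), arr.ind = TRUE)[1, ]
  list(csd = out, sink_channel = unname(mn[1]),
       sink_time_index = unname(mn[2]))
}

band_power_window <- function(sig, fs, t0, start, len, band) {
  seg <- extract_epochs(sig, fs, t0, start, len)
  if (nrow(seg) == 0) return(NA_real_)
  w <- welch_epochs(seg, fs = fs)
  mean(Re(w$pxy)[band_idx(w$freqs, band[1], band[2])])
}

#' Relative band-power change across ramp stimulation
#'
#' Per sweep, compares the band power of the 1.5 s window preceding the
#' ramp onset with the last 1.5 s of the ramp:
#' `(P_last - P_pre) / P_pre`, averaged over sweeps.
#'
#' @param rec a [recording()].
#' @param protocol a ramp [stim_protocol()].
#' @param band frequency band, Hz.
#' @param channel channel index.
#' @param window_s comparison window length, s (default 1.5).
#' @return mean relative change (0 = no change, +1 = doubling).
#' @export
ramp_power_change <- function(rec, protocol, band, channel = 1,
                              window_s = 1.5) {
  ci <- match(channel, rec$channels$index)
  sig <- rec$signal[ci, ]
  changes <- vapply(protocol$sweep_onsets, function(on) {
    p_pre <- band_power_window(sig, rec$fs, rec$t0, on - window_s,
                               window_s, band)
    p_last <- band_power_window(sig, rec$fs, rec$t0,
                                on + protocol$ramp_duration_s - window_s,
                                window_s, band)
    if (is.na(p_pre) || p_pre <= 0)
      ln_stop("pre-stimulation power unavailable or zero",
              "lfpnet_error_baseline")
    (p_last - p_pre) / p_pre
  }, 0)
  mean(changes)
}

#' Relative band-coherence change across stimulation
#'
#' Band-averaged magnitude coherence between two channels is computed over
#' the per-sweep pre windows and over the per-sweep stimulation windows
#' (for ramps: the last `window_s` of the ramp; for `mode = "post"`: the
#' window after the pulse-train offset, the presynaptic-silencing
#' convention), and the change `during/pre - 1` is returned.
#'
#' @param rec a [recording()].
#' @param protocol a [stim_protocol()].
#' @param channels length-2 channel indices.
#' @param band frequency band, Hz.
#' @param mode `"during"` (ramp window) or `"post"` (after train offset).
#' @param window_s window length, s.
#' @param train_s train duration for `mode = "post"`, s (defaults to the
#'   ramp duration field).
#' @return relative change of band coherence (`during/pre - 1`).
#' @export
ramp_coherence_change <- function(rec, protocol, channels, band,
                                  mode = c("during", "post"),
                                  window_s = 1.5, train_s = NULL) {
  mode <- match.arg(mode)
  ci <- match(channels, rec$channels$index)
  train <- train_s %||% protocol$ramp_duration_s
  on <- protocol$sweep_onsets
  stim_start <- if (mode == "during") on + train - window_s else on + train
  band_coh <- function(starts) {
    xe <- extract_epochs(rec$signal[ci[1], ], rec$fs, rec$t0, starts,
                         window_s)
    ye <- extract_epochs(rec$signal[ci[2], ], rec$fs, rec$t0, starts,
                         window_s)
    co <- coherence(cross_spectra(xe, ye, rec$fs))
    band_average(co, band[1], band[2], value = "magnitude")
  }
  pre <- band_coh(on - window_s)
  dur <- band_coh(stim_start)
  if (pre <= 0)
    ln_stop("pre-stimulation coherence is zero", "lfpnet_error_baseline")
  dur / pre - 1
}

#' Relative band-power change after a silencing pulse train
#'
#' Post/pre band-power ratio minus 1, with the post window starting at the
#' pulse-train offset (`train_s` after each sweep onset).
#' @inheritParams ramp_power_change
#' @param train_s pulse-train duration, s.
#' @export
silencing_power_change <- function(rec, protocol, band, channel = 1,
                                   window_s = 1.5, train_s = 4) {
  ci <- match(channel, rec$channels$index)
  sig <- rec$signal[ci, ]
  changes <- vapply(protocol$sweep_onsets, function(on) {
    p_pre <- band_power_window(sig, rec$fs, rec$t0, on - window_s,
                               window_s, band)
    p_post <- band_power_window(sig, rec$fs, rec$t0, on + train_s,
                                window_s, band)
    if (is.na(p_pre) || p_pre <= 0)
      ln_stop("pre-stimulation power unavailable or zero",
              "lfpnet_error_baseline")
    (p_post - p_pre) / p_pre
  }, 0)
  mean(changes)
}

#' Evoked-EPSC features from voltage-clamp sweeps
#'
#' Sweeps are averaged; the peak amplitude is the baseline-subtracted
#' inward peak (reported as a positive magnitude), the onset latency is the
#' first post-stimulus time at which |dI/dt| exceeds `slope_pa_ms`
#' (default 10 pA/ms) on the average trace, the rise time spans 20-80% of
#' the peak, and the CV is the SD/mean of the per-sweep peak amplitudes.
#' The cell is `responsive` when the average peak exceeds 3 x the baseline
#' SD and the onset latency is below 9 ms.
#'
#' @param traces numeric matrix `[n_sweeps x n_samples]`, current in pA
#'   (inward negative).
#' @param fs sampling rate, Hz.
#' @param stim_onset_s stimulus time within the sweep, s.
#' @param slope_pa_ms onset slope criterion, pA/ms.
#' @param search_s post-stimulus search window, s.
#' @param max_latency_s responsiveness latency bound, s (default 0.009).
#' @return list of class `"epsc_features"`: `amplitude_pa`,
#'   `onset_latency_ms`, `rise_time_ms`, `cv`, `responsive`, `avg_trace`,
#'   `t`.
#' @export
eepsc_features <- function(traces, fs, stim_onset_s, slope_pa_ms = 10,
                           search_s = 0.05, max_latency_s = 0.009) {
  if (!is.matrix(traces) || nrow(traces) < 2)
    ln_stop("need at least 2 sweeps", "lfpnet_error_epochs")
  avg <- colMeans(traces)
  t <- (seq_along(avg) - 1) / fs
  pre <- t < stim_onset_s
  bl <- mean(avg[pre]); bl_sd <- stats::sd(avg[pre])
  post <- which(t >= stim_onset_s & t <= stim_onset_s + search_s)
  dev <- bl - avg[post]                    # inward (negative) as positive
  pk_i <- post[which.max(dev)]
  amplitude <- max(dev)
  # onset: response speed on the average trace; the derivative is taken
  # over a 0.2 ms span so sample-to-sample noise does not trip the
  # criterion
  hw <- max(1L, round(0.0001 * fs))
  idx <- (hw + 1):(length(avg) - hw)
  slope <- rep(0, length(avg))
  slope[idx] <- abs(avg[idx + hw] - avg[idx - hw]) / (2 * hw / fs * 1000)
  on_i <- post[which(slope[post] > slope_pa_ms)[1]]
  onset_ms <- if (is.na(on_i)) NA_real_ else (t[on_i] - stim_onset_s) * 1000
  # 20-80% rise on the average trace
  rise_ms <- NA_real_
  if (amplitude > 0 && !is.na(on_i)) {
    seg <- post[post <= pk_i]
    d <- bl - avg[seg]
    i20 <- seg[which(d >= 0.2 * amplitude)[1]]
    i80 <- seg[which(d >= 0.8 * amplitude)[1]]
    if (!is.na(i20) && !is.na(i80)) rise_ms <- (t[i80] - t[i20]) * 1000
  }
  per_sweep <- apply(traces, 1, function(tr)
    max(mean(tr[pre]) - tr[post]))
  cv <- if (mean(per_sweep) > 0) stats::sd(per_sweep) / mean(per_sweep)
    else 0
  responsive <- is.finite(onset_ms) && amplitude > 3 * bl_sd &&
    onset_ms < max_latency_s * 1000
  structure(list(amplitude_pa = amplitude, onset_latency_ms = onset_ms,
                 rise_time_ms = rise_ms, cv = cv, responsive = responsive,
                 avg_trace = avg, t = t),
            class = "epsc_features")
}
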