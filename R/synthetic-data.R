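# Ground-truth generator. Three latent region processes (LEC, HP, PFC)
# follow a stable MVAR with resonant theta/beta poles and directed
# lag-1 coupling (LEC->HP strong, HP->PFC intermediate, LEC->PFC weak).
# The latent process runs at a low model rate, is band-limited upsampled
# to the LFP rate, gated by raised-cosine burst envelopes, and summed with
# a continuous 2-4 Hz slow rhythm and 1/f background noise. Optional
# instantaneous mixing emulates volume conduction; optional laminar
# projection spreads each region over a multi-site probe with a known
# dipole (sink/source) geometry.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analyses assume: discontinuous
#' theta-beta spindle bursts (mean duration 3 s, about 8/min) riding on a
#' continuous 2-4 Hz slow rhythm, 6 dB in-burst SNR in the 4-30 Hz band,
#' and directed coupling LEC->HP > HP->PFC > LEC->PFC. The `"GE"` group
#' scales the LEC->HP coupling gain by `ge_gain_mult` (default 0.4), the
#' burst power by `ge_burst_power_mult` (default 0.5), and lowers the
#' light-responder fraction (0.27 -> 0.11, the responsive-unit proportions
#' of the in vivo data).
#'
#' @param seed integer RNG seed; identical configs are bit-reproducible.
#' @param group `"CON"` or `"GE"`.
#' @param duration_s recording length, s.
#' @param fs output LFP sampling rate, Hz (integer multiple of `fs_latent`).
#' @param fs_latent sampling rate of the latent MVAR process, Hz.
#' @param theta_pole,beta_pole `c(freq_hz, pole_radius)` of the two
#'   resonances shared by all regions.
#' @param coupling named directed gains, names `"LEC->HP"` etc.
#' @param burst_rate_per_min mean burst rate, events/min.
#' @param burst_dur_meanlog,burst_dur_sdlog log-normal burst duration
#'   parameters (defaults give mean 3 s).
#' @param burst_min_dur_s minimum burst duration, s.
#' @param burst_min_gap_s minimum inter-burst gap, s.
#' @param burst_edge_s raised-cosine on/off edge, s.
#' @param burst_snr_db in-burst 4-30 Hz SNR over background, dB.
#' @param slow_band,slow_amp_uv band (Hz) and RMS amplitude (uV) of the
#'   continuous slow rhythm.
#' @param noise_exponent 1/f^a exponent of the background noise.
#' @param noise_amp_uv background RMS amplitude, uV.
#' @param mixing optional instantaneous k x k mixing matrix
#'   (volume-conduction emulation); `NULL` = identity.
#' @param n_channels_per_region 1 for one channel per region, or >= 3 for a
#'   laminar probe per region.
#' @param laminar list: `spacing_um`, `sink_channel`, `source_sep`
#'   (channels), `spread` (channels), `channel_noise` (relative SD).
#' @param ge_gain_mult,ge_burst_power_mult,responder_fraction group
#'   contrast parameters (responder_fraction is `c(CON=,GE=)`).
#' @param spikes list: `n_units_per_region`, `baseline_rate_hz`,
#'   `coupling_strength` (log-rate gain on the 4-30 Hz LFP amplitude),
#'   `p_resp` (per-pulse response probability of responder units),
#'   `resp_latency_s` (`c(min,max)` window after pulse onset).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, group = c("CON", "GE"), duration_s = 600,
                       fs = 1000, fs_latent = 100,
                       theta_pole = c(8, 0.90), beta_pole = c(20, 0.65),
                       coupling = c("LEC->HP" = 0.35, "HP->PFC" = 0.25,
                                    "LEC->PFC" = 0.08),
                       burst_rate_per_min = 8,
                       burst_dur_meanlog = log(3) - 0.4^2 / 2,
                       burst_dur_sdlog = 0.4,
                       burst_min_dur_s = 1.2, burst_min_gap_s = 1,
                       burst_edge_s = 0.1, burst_snr_db = 6,
                       slow_band = c(2, 4), slow_amp_uv = 25,
                       noise_exponent = 1, noise_amp_uv = 40,
                       mixing = NULL, n_channels_per_region = 1,
                       laminar = list(spacing_um = 50, sink_channel = 8,
                                      source_sep = 2, spread = 1.5,
                                      channel_noise = 0.05),
                       ge_gain_mult = 0.4, ge_burst_power_mult = 0.5,
                       responder_fraction = c(CON = 0.27, GE = 0.11),
                       spikes = list(n_units_per_region = 5,
                                     baseline_rate_hz = 0.5,
                                     coupling_strength = 0.5,
                                     p_resp = 0.6,
                                     resp_latency_s = c(0.003, 0.010))) {
  group <- match.arg(group)
  cfg <- as.list(environment())
  if (any(cfg$coupling < 0))
    ln_stop("coupling gains must be non-negative", "lfpnet_error_config")
  if (!is.null(mixing) && (!is.matrix(mixing) || nrow(mixing) != ncol(mixing)))
    ln_stop("mixing matrix must be square", "lfpnet_error_config")
  if (cfg$spikes$p_resp < 0 || cfg$spikes$p_resp > 1)
    ln_stop("p_resp must lie in [0, 1]", "lfpnet_error_config")
  if (abs(fs / fs_latent - round(fs / fs_latent)) > 1e-9)
    ln_stop("fs must be an integer multiple of fs_latent",
            "lfpnet_error_config")
  class(cfg) <- "sim_config"
  cfg
}

#' The true latent MVAR model implied by a configuration
#'
#' Each region has an AR(4) diagonal polynomial (product of the theta and
#' beta pole pairs); directed coupling enters at lag 1. Innovations are
#' unit-variance white. In the `"GE"` group the LEC->HP gain is multiplied
#' by `ge_gain_mult`.
#'
#' @param cfg a [sim_config()].
#' @return an [mvar_model()] (errors if the implied model is unstable).
#' @export
mvar_from_config <- function(cfg) {
  k <- 3L
  ar2 <- function(f, r, fs) c(2 * r * cos(2 * pi * f / fs), -r^2)
  th <- ar2(cfg$theta_pole[1], cfg$theta_pole[2], cfg$fs_latent)
  be <- ar2(cfg$beta_pole[1], cfg$beta_pole[2], cfg$fs_latent)
  # characteristic polynomial product -> AR(4) coefficients
  poly <- convolve(c(1, -th), rev(c(1, -be)), type = "open")
  diag_coef <- -poly[-1]
  p <- length(diag_coef)
  A <- array(0, c(k, k, p))
  for (r in seq_len(p)) diag(A[, , r]) <- diag_coef[r]
  g <- cfg$coupling
  if (cfg$group == "GE") g["LEC->HP"] <- g["LEC->HP"] * cfg$ge_gain_mult
  idx <- function(region) match(region, REGIONS)
  for (nm in names(g)) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1]]
    A[idx(pair[2]), idx(pair[1]), 1] <- A[idx(pair[2]), idx(pair[1]), 1] + g[[nm]]
  }
  mvar_model(A, diag(k), cfg$fs_latent, labels = REGIONS)
}

#' Simulate a stationary sample path of an MVAR model
#'
#' Uses the current RNG state; innovations are N(0, Sigma).
#' @param model an [mvar_model()].
#' @param n number of samples to return (after burn-in).
#' @param burn_in discarded initial samples.
#' @return numeric matrix `[k x n]`.
#' @export
simulate_mvar <- function(model, n, burn_in = 500) {
  k <- dim(model$A)[1L]; p <- model$order
  L <- t(chol(model$Sigma + diag(1e-12, k)))
  ntot <- n + burn_in
  E <- L %*% matrix(stats::rnorm(k * ntot), k, ntot)
  Z <- matrix(0, k, ntot)
  Amat <- matrix(model$A, k, k * p) # [k x k*p], lag blocks side by side
  for (t in (p + 1):ntot) {
    past <- as.vector(Z[, t - seq_len(p), drop = FALSE])
    Z[, t] <- Amat %*% past + E[, t]
  }
  Z[, (burn_in + 1):ntot, drop = FALSE]
}

#' Laminar dipole weight profile across a probe
#'
#' Difference of two Gaussians: a sink at `sink_channel` and a source
#' `source_sep` channels deeper, each with spatial SD `spread` channels.
#' @param n_ch number of probe channels.
#' @param sink_channel sink location (channel index).
#' @param source_sep sink-source separation in channels.
#' @param spread Gaussian spatial spread in channels.
#' @return numeric weights of length `n_ch`, peak magnitude 1.
#' @export
dipole_weights <- function(n_ch, sink_channel, source_sep = 2, spread = 1.5) {
  i <- seq_len(n_ch)
  w <- -exp(-((i - sink_channel)^2) / (2 * spread^2)) +
    exp(-((i - sink_channel - source_sep)^2) / (2 * spread^2))
  w / max(abs(w))
}

# burst onsets/offsets as a renewal process with mean inter-onset 60/rate
burst_intervals <- function(cfg) {
  rate <- cfg$burst_rate_per_min
  mean_dur <- exp(cfg$burst_dur_meanlog + cfg$burst_dur_sdlog^2 / 2)
  slack <- 60 / rate - cfg$burst_min_gap_s - mean_dur
  if (slack <= 0.2)
    ln_stop("burst rate too high for the configured durations",
            "lfpnet_error_config")
  draw_dur <- function() {
    d <- stats::rlnorm(1, cfg$burst_dur_meanlog, cfg$burst_dur_sdlog)
    while (d < cfg$burst_min_dur_s)
      d <- stats::rlnorm(1, cfg$burst_dur_meanlog, cfg$burst_dur_sdlog)
    d
  }
  starts <- numeric(0); stops <- numeric(0)
  t <- stats::rexp(1, 1 / slack)
  while (TRUE) {
    d <- draw_dur()
    if (t + d > cfg$duration_s - 0.2) break
    starts <- c(starts, t); stops <- c(stops, t + d)
    t <- t + d + cfg$burst_min_gap_s + stats::rexp(1, 1 / slack)
  }
  data.frame(start = starts, stop = stops)
}

burst_envelope <- function(intervals, n, fs, edge_s) {
  env <- numeric(n)
  ne <- max(1L, round(edge_s * fs))
  ramp <- 0.5 * (1 - cos(pi * seq_len(ne) / ne))
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, round(intervals$start[i] * fs) + 1L)
    i1 <- min(n, round(intervals$stop[i] * fs))
    if (i1 - i0 + 1L < 2L * ne + 2L) next
    seg <- rep(1, i1 - i0 + 1L)
    seg[seq_len(ne)] <- ramp
    seg[(length(seg) - ne + 1L):length(seg)] <- rev(ramp)
    env[i0:i1] <- pmax(env[i0:i1], seg)
  }
  env
}

#' Simulate a multichannel LFP recording with known ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (the simulated [recording()]),
#'   `events` (ground-truth [event_table()], one copy per channel),
#'   `model` (the generating latent [mvar_model()]), `envelope`
#'   (burst gate at the LFP rate) and `scales` (per-region burst
#'   amplitude scale factors, uV).
#' @export
simulate_lfp <- function(cfg) {
  set.seed(cfg$seed)
  model <- mvar_from_config(cfg)  # errors on unstable configurations
  k <- 3L
  n <- round(cfg$duration_s * cfg$fs)
  up <- as.integer(round(cfg$fs / cfg$fs_latent))
  n_lat <- n %/% up
  Z <- simulate_mvar(model, n_lat)
  osc <- t(apply(Z, 1L, fft_upsample, factor = up))[, seq_len(n), drop = FALSE]
  iv <- burst_intervals(cfg)
  env <- burst_envelope(iv, n, cfg$fs, cfg$burst_edge_s)

  # equalize burst energy across events with a per-burst gain common to
  # all regions: every event then sits at the configured SNR (the
  # stochastic envelope of the narrowband latent process would otherwise
  # spread individual bursts over many dB), while the common gain leaves
  # the cross-region MVAR structure untouched
  all_idx <- which(env > 0.7)
  ref_rms <- sqrt(mean(osc[, all_idx]^2))
  for (b in seq_len(nrow(iv))) {
    idx <- max(1L, round(iv$start[b] * cfg$fs) + 1L):
      min(n, round(iv$stop[b] * cfg$fs))
    g_b <- sqrt(mean(osc[, idx]^2))
    if (g_b > 0) osc[, idx] <- osc[, idx] * (ref_rms / g_b)
  }

  # background: 1/f noise + continuous slow rhythm, per region. The slow
  # rhythm is quasi-sinusoidal with a wandering frequency inside the band
  # and near-stable amplitude (respiration-locked rhythms do not wax and
  # wane like narrowband noise), so it raises the RMS baseline without
  # mimicking burst-like excursions.
  bg <- matrix(0, k, n)
  for (i in seq_len(k)) {
    pk <- pink_noise(n, cfg$noise_exponent) * cfg$noise_amp_uv
    f0 <- stats::runif(1, cfg$slow_band[1] + 0.4, cfg$slow_band[2] - 0.4)
    wobble <- butter_filter_mat(stats::rnorm(n), cfg$fs, "low", 0.1, 2)
    wobble <- wobble / max(stats::sd(wobble), 1e-12)
    f_inst <- pmin(cfg$slow_band[2], pmax(cfg$slow_band[1], f0 + 0.15 * wobble))
    am_mod <- butter_filter_mat(stats::rnorm(n), cfg$fs, "low", 0.1, 2)
    am <- 1 + 0.1 * am_mod / max(stats::sd(am_mod), 1e-12)
    slow <- am * sin(2 * pi * cumsum(f_inst) / cfg$fs +
                       stats::runif(1, 0, 2 * pi))
    slow <- slow / stats::sd(slow) * cfg$slow_amp_uv
    bg[i, ] <- pk + slow
  }

  # calibrate the in-burst oscillation amplitude: burst_snr_db is the RMS
  # of the gated oscillation relative to the RMS of the background in the
  # event-detection band (3-100 Hz), so a 6 dB configuration yields about
  # 10 dB inside/outside power contrast within the 4-30 Hz band
  power_mult <- if (cfg$group == "GE") cfg$ge_burst_power_mult else 1
  scales <- numeric(k)
  sig <- matrix(0, k, n)
  inb <- env > 0.7
  for (i in seq_len(k)) {
    bg_band_sd <- stats::sd(butter_filter_mat(bg[i, ], cfg$fs, "pass",
                                              c(3, 100), 3))
    osc_gated <- osc[i, ] * env
    osc_sd <- stats::sd(osc_gated[inb])
    scales[i] <- bg_band_sd * 10^(cfg$burst_snr_db / 20) *
      sqrt(power_mult) / osc_sd
    sig[i, ] <- osc_gated * scales[i] + bg[i, ]
  }

  if (!is.null(cfg$mixing)) sig <- cfg$mixing %*% sig

  nch <- cfg$n_channels_per_region
  if (nch == 1) {
    signal <- sig
    channels <- data.frame(index = 1:3, region = REGIONS, layer = "",
                           depth_um = 0)
  } else {
    w <- dipole_weights(nch, cfg$laminar$sink_channel,
                        cfg$laminar$source_sep, cfg$laminar$spread)
    signal <- matrix(0, k * nch, n)
    channels <- data.frame(index = seq_len(k * nch),
                           region = rep(REGIONS, each = nch), layer = "",
                           depth_um = rep((seq_len(nch) - 1L) *
                                            cfg$laminar$spacing_um, k))
    for (i in seq_len(k)) {
      noise_sd <- cfg$laminar$channel_noise * stats::sd(sig[i, ])
      for (j in seq_len(nch)) {
        signal[(i - 1L) * nch + j, ] <- w[j] * sig[i, ] +
          stats::rnorm(n, sd = noise_sd)
      }
    }
  }

  rec <- recording(signal, cfg$fs, channels, t0 = 0)
  ev <- event_table(channel = rep(channels$index, each = nrow(iv)),
                    start_s = rep(iv$start, nrow(channels)),
                    stop_s = rep(iv$stop, nrow(channels)),
                    peak_rms_uv = rep(scales[
                      match(channels$region, REGIONS)], each = nrow(iv)))
  list(recording = rec, events = ev, model = model, envelope = env,
       scales = scales)
}

#' Simulate spike trains coupled to the LFP, with light-evoked responses
#'
#' Inhomogeneous Poisson trains whose log-rate follows the z-scored 4-30 Hz
#' amplitude of the unit's region LFP (mean rate equals the configured
#' baseline). Responder units additionally emit one spike with probability
#' `p_resp` in the configured latency window after each light pulse.
#'
#' @param rec a [recording()].
#' @param cfg a [sim_config()]; `cfg$spikes` holds the spike parameters and
#'   `cfg$responder_fraction[cfg$group]` the fraction of responder units.
#' @param protocol optional [stim_protocol()] (pulse kind) for light-evoked
#'   spikes.
#' @param seed optional seed (defaults to `cfg$seed + 1`).
#' @return a [spike_set()]; `units$responder` flags ground-truth responders.
#' @export
simulate_spikes <- function(rec, cfg, protocol = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  sp <- cfg$spikes
  dur <- rec_duration(rec)
  n <- ncol(rec$signal)
  frac <- unname(cfg$responder_fraction[cfg$group])
  units <- list(); times <- list()
  uid <- 0L
  for (region in unique(rec$channels$region)) {
    ch <- which(rec$channels$region == region)[1L]
    z <- if (sp$coupling_strength > 0 && sp$baseline_rate_hz > 0) {
      b <- bandpass(rec$signal[ch, ], 4, 30, fs = rec$fs)
      a <- abs(b)
      (a - mean(a)) / stats::sd(a)
    } else numeric(n)
    rate <- sp$baseline_rate_hz *
      exp(sp$coupling_strength * z - sp$coupling_strength^2 / 2)
    p_samp <- pmin(rate / rec$fs, 0.5)
    for (u in seq_len(sp$n_units_per_region)) {
      uid <- uid + 1L
      tt <- if (sp$baseline_rate_hz > 0) {
        rec$t0 + (which(stats::runif(n) < p_samp) - 0.5) / rec$fs
      } else numeric(0)
      responder <- stats::runif(1) < frac
      if (responder && !is.null(protocol) && protocol$kind == "pulse") {
        pt <- pulse_times(protocol)
        hit <- stats::runif(length(pt)) < sp$p_resp
        lat <- stats::runif(sum(hit), sp$resp_latency_s[1],
                            sp$resp_latency_s[2])
        tt <- c(tt, pt[hit] + lat)
      }
      tt <- sort(tt)
      if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) >= 0.001)] # dead time
      tt <- tt[tt >= rec$t0 & tt <= rec$t0 + dur]
      units[[uid]] <- data.frame(unit_id = sprintf("%s_u%d", region, u),
                                 region = region, layer = "",
                                 responder = responder)
      times[[uid]] <- tt
    }
  }
  un <- do.call(rbind, units)
  names(times) <- un$unit_id
  spike_set(un, times, span = c(rec$t0, rec$t0 + dur))
}

#' Simulate behavioral interaction-time tables
#'
#' Per-animal novel/familiar interaction times drawn from truncated normal
#' distributions; a configurable fraction of animals explore below the
#' 20 cm/min threshold to exercise the exclusion rule.
#'
#' @param n_per_group animals per group.
#' @param effects named list of `c(novel=, familiar=)` mean interaction
#'   times (s) per group.
#' @param sd_s common SD of interaction times, s.
#' @param task task label.
#' @param low_explorer_frac fraction of animals with velocity below
#'   20 cm/min.
#' @param seed RNG seed.
#' @return data.frame with columns `animal_id`, `group`, `task`,
#'   `t_novel_s`, `t_familiar_s`, `velocity_cm_min`.
#' @export
simulate_behavior <- function(n_per_group = 20,
                              effects = list(CON = c(novel = 5.25,
                                                     familiar = 2.13),
                                             GE = c(novel = 3.81,
                                                    familiar = 1.93)),
                              sd_s = 1.0, task = "NOPd",
                              low_explorer_frac = 0.1, seed = 1L) {
  set.seed(seed)
  rtnorm <- function(n, mean, sd, lo = 0.05) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x < lo)) x[x < lo] <- stats::rnorm(sum(x < lo), mean, sd)
    x
  }
  out <- list()
  for (g in names(effects)) {
    low <- stats::runif(n_per_group) < low_explorer_frac
    vel <- ifelse(low, rtnorm(n_per_group, 15, 3, 1),
                  rtnorm(n_per_group, 30, 5, 1))
    out[[g]] <- data.frame(
      animal_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
      group = g, task = task,
      t_novel_s = rtnorm(n_per_group, effects[[g]]["novel"], sd_s),
      t_familiar_s = rtnorm(n_per_group, effects[[g]]["familiar"], sd_s),
      velocity_cm_min = vel)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
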