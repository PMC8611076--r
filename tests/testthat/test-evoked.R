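pulse_prot <- function(n_sweeps = 5, sweep_gap = 4, n_pulses = 24,
                       rate = 8) {
  stim_protocol("pulse",
                sweep_onsets = seq(1, by = sweep_gap, length.out = n_sweeps),
                pulse_onsets = seq(0, by = 1 / rate,
                                   length.out = n_pulses),
                pulse_width_s = 0.003, rate_hz = rate)
}

test_that("firing probability counts spikes, not pulses", {
  prot <- stim_protocol("pulse", sweep_onsets = 0,
                        pulse_onsets = seq(0, 9, by = 1),
                        pulse_width_s = 0.003, rate_hz = 1)
  mk <- function(tt) spike_set(data.frame(unit_id = "u", region = "HP",
                                          layer = ""), list(u = tt))
  # 3 pulses contain one spike each -> 0.3
  expect_equal(firing_probability(mk(c(0.005, 2.01, 5.012)), prot)[["u"]],
               0.3)
  # one pulse contains 2 spikes -> 0.2
  expect_equal(firing_probability(mk(c(3.004, 3.012)), prot)[["u"]], 0.2)
  # spikes outside the 20 ms window are not evoked
  expect_equal(firing_probability(mk(c(0.5, 1.021)), prot)[["u"]], 0)
  expect_error(firing_probability(mk(1), stim_protocol("ramp", 0)),
               class = "lfpnet_error_stim")
})

test_that("firing rate follows count / duration, pooled per animal", {
  sp <- spike_set(data.frame(unit_id = c("a", "b"), region = "HP",
                             layer = ""),
                  list(a = seq(0.25, 60, by = 0.5), b = numeric(0)))
  fr <- firing_rate(sp, c(0, 60))
  expect_equal(fr$per_unit[["a"]], 2)
  expect_equal(fr$per_unit[["b"]], 0)
  expect_equal(fr$pooled, 2)
  set.seed(1)
  n <- rpois(1, 5 * 600)
  sp2 <- spike_set(data.frame(unit_id = "p", region = "HP", layer = ""),
                   list(p = sort(runif(n, 0, 600))))
  expect_lt(abs(firing_rate(sp2, c(0, 600))$per_unit[["p"]] - 5), 0.3)
})

test_that("PSTH localizes fixed-latency responses and sums to the firing probability", {
  prot <- pulse_prot()
  pt <- pulse_times(prot)
  sp <- spike_set(data.frame(unit_id = "r", region = "HP", layer = ""),
                  list(r = pt + 0.0055))
  ps <- psth(sp, prot, bin_ms = 1)
  expect_equal(ps$mids_ms[which.max(ps$prob["r", ])], 5.5)
  in20 <- ps$mids_ms > 0 & ps$mids_ms < 20
  expect_equal(sum(ps$prob["r", in20]),
               firing_probability(sp, prot)[["r"]])
  # a Poisson non-responder stays flat: identity still holds
  set.seed(2)
  spn <- spike_set(data.frame(unit_id = "n", region = "HP", layer = ""),
                   list(n = sort(runif(400, 0, 25))))
  psn <- psth(spn, prot, bin_ms = 1)
  expect_equal(sum(psn$prob["n", in20]),
               firing_probability(spn, prot)[["n"]])
})

test_that("modulation index follows its formula and classifies responders", {
  sw <- seq(10, by = 10, length.out = 40)
  prot <- stim_protocol("ramp", sweep_onsets = sw, ramp_duration_s = 3)
  set.seed(3)
  # rate doubles during stimulation -> MI ~ 1/3, activated
  pre_spk <- unlist(lapply(sw, function(s) s - 1.5 + sort(runif(rpois(1, 6), 0, 1.5))))
  dur_spk <- unlist(lapply(sw, function(s) s + sort(runif(rpois(1, 12), 0, 1.5))))
  sp <- spike_set(data.frame(unit_id = "u", region = "PFC", layer = ""),
                  list(u = sort(unique(c(pre_spk, dur_spk)))))
  mi <- modulation_index(sp, prot, pre_s = 1.5, during_s = 1.5,
                         n_perm = 500, seed = 1)
  expect_lt(abs(mi$mi - 1 / 3), 0.12)
  expect_equal(mi$responder_class, "activated")

  # silent during stimulation -> MI = -1, inhibited
  sp_inh <- spike_set(data.frame(unit_id = "u", region = "PFC",
                                 layer = ""),
                      list(u = sort(unlist(lapply(sw, function(s)
                        s - 1.5 + sort(runif(8, 0, 1.4)))))))
  mi_inh <- modulation_index(sp_inh, prot, pre_s = 1.5, during_s = 1.5,
                             n_perm = 500, seed = 2)
  expect_equal(mi_inh$mi, -1)
  expect_equal(mi_inh$responder_class, "inhibited")

  # silent unit: MI defined as 0
  sp0 <- spike_set(data.frame(unit_id = "u", region = "PFC", layer = ""),
                   list(u = numeric(0)))
  expect_equal(modulation_index(sp0, prot, 1.5, 1.5, n_perm = 100)$mi, 0)

  expect_error(modulation_index(sp, stim_protocol("ramp",
                                                  sweep_onsets = 1:4),
                                1.5, 1.5),
               class = "lfpnet_error_stim")
})

test_that("evoked LFP recovers an injected deflection", {
  set.seed(4)
  fs <- 1000
  prot <- stim_protocol("pulse",
                        sweep_onsets = seq(1, by = 1.3,
                                           length.out = 300),
                        pulse_onsets = 0, pulse_width_s = 0.003,
                        rate_hz = 8)
  sig <- rnorm(400 * fs, sd = 20)
  wave <- -40 * exp(-((seq(0, 0.06, by = 1 / fs) - 0.015)^2) /
                      (2 * 0.004^2))
  for (p in pulse_times(prot)) {
    i0 <- round(p * fs) + 1
    sig[i0:(i0 + 60)] <- sig[i0:(i0 + 60)] + wave
  }
  ev <- evoked_lfp(one_channel_rec(sig, fs, region = "HP"), prot, 1)
  expect_lt(abs(ev$amplitude_uv - 40), 3)
  expect_lt(abs(ev$latency_s - 0.015), 0.002)
  expect_equal(ev$polarity, -1)
  # no evoked component: amplitude near the averaged noise floor
  ev0 <- evoked_lfp(one_channel_rec(rnorm(400 * fs, sd = 20), fs), prot, 1)
  expect_lt(ev0$amplitude_uv, 5 * 20 / sqrt(300))
  expect_error(evoked_lfp(one_channel_rec(sig, fs),
                          stim_protocol("ramp", 1)),
               class = "lfpnet_error_stim")
})

test_that("CSD localizes the dipole sink and vanishes on linear profiles", {
  w <- dipole_weights(16, 8)
  V <- outer(w, sin(seq(0, pi, length.out = 40)))
  cs <- csd(V, spacing_um = 50)
  expect_lte(abs(cs$sink_channel - 8), 1)
  # linear depth profile: interior CSD is exactly zero (Vaknin padding
  # leaves the duplicated edge channels nonzero by construction)
  lin <- outer(2 * (1:10) + 3, rep(1, 5))
  cl <- csd(lin, 50)
  expect_true(all(abs(cl$csd[2:9, ]) < 1e-12))
  # dipolar source: interior CSD sums to ~0 (conservation)
  colsum <- colSums(cs$csd[2:15, ])
  expect_lt(max(abs(colsum)), 0.1 * max(abs(cs$csd)))
  expect_error(csd(matrix(0, 2, 5), 50), class = "lfpnet_error_channels")
})

test_that("ramp power change measures the relative band-power difference", {
  set.seed(5)
  fs <- 1000
  prot <- stim_protocol("ramp", sweep_onsets = seq(5, by = 8,
                                                   length.out = 12),
                        ramp_duration_s = 3)
  base <- bandpass(rnorm(110 * fs, sd = 30), 12, 30, fs = fs) +
    rnorm(110 * fs, sd = 5)
  rec0 <- one_channel_rec(base, fs)
  expect_lt(abs(ramp_power_change(rec0, prot, c(12, 30))), 0.15)
  # amplitude gain sqrt(2) during the ramp -> power doubles -> +1.0
  gained <- base
  for (on in prot$sweep_onsets) {
    idx <- round((on) * fs):round((on + 3) * fs)
    gained[idx] <- gained[idx] * sqrt(2)
  }
  ch <- ramp_power_change(one_channel_rec(gained, fs), prot, c(12, 30))
  expect_lt(abs(ch - 1), 0.25)
})

test_that("ramp coherence change is zero for stationary coupling", {
  set.seed(6)
  fs <- 1000
  n <- 110 * fs
  s <- bandpass(rnorm(n), 8, 20, fs = fs)
  x <- s + 0.3 * rnorm(n)
  y <- s + 0.3 * rnorm(n)
  rec <- recording(rbind(x, y), fs,
                   data.frame(index = 1:2, region = c("HP", "PFC"),
                              layer = "", depth_um = 0))
  prot <- stim_protocol("ramp", sweep_onsets = seq(5, by = 8,
                                                   length.out = 12),
                        ramp_duration_s = 3)
  ch <- ramp_coherence_change(rec, prot, c(1, 2), c(8, 20))
  expect_lt(abs(ch), 0.1)
})

test_that("eEPSC features recover a synthetic alpha-function response", {
  set.seed(7)
  tr <- epsc_sweeps(amp_pa = 45, delay_s = 0.006)
  ef <- eepsc_features(tr, fs = 20000, stim_onset_s = 0.05)
  expect_lt(abs(ef$amplitude_pa - 45), 2)
  expect_lt(abs(ef$onset_latency_ms - 6), 0.5)
  expect_true(ef$responsive)
  expect_gt(ef$rise_time_ms, 0)

  # identical sweeps: CV = 0
  tr_id <- epsc_sweeps(noise_sd = 0)
  expect_equal(eepsc_features(tr_id, 20000, 0.05)$cv, 0)

  # flat traces: not responsive, near-zero amplitude
  flat <- matrix(rnorm(20 * 2001, sd = 0.5), 20, 2001)
  ef0 <- eepsc_features(flat, 20000, 0.05)
  expect_false(ef0$responsive)
  expect_lt(ef0$amplitude_pa, 2)
  expect_error(eepsc_features(tr[1, , drop = FALSE], 20000, 0.05),
               class = "lfpnet_error_epochs")
})
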