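test_that("identical config and seed give bit-identical output", {
  cfg <- fast_cfg(seed = 7, duration_s = 70)
  a <- simulate_lfp(cfg)
  b <- simulate_lfp(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$events, b$events)
  sa <- simulate_spikes(a$recording, cfg)
  sb <- simulate_spikes(b$recording, cfg)
  expect_identical(sa$times, sb$times)
})

test_that("burst count stays within the Poisson 99% CI of the rate", {
  cfg <- sim_config(seed = 3, duration_s = 600)
  sim <- simulate_lfp(cfg)
  n_events <- sum(sim$events$channel == 1)
  lambda <- cfg$burst_rate_per_min * cfg$duration_s / 60
  ci <- qpois(c(0.005, 0.995), lambda)
  expect_gte(n_events, ci[1])
  expect_lte(n_events, ci[2])
})

test_that("zero coupling gives vanishing off-diagonal true gPDC", {
  cfg <- fast_cfg(coupling = c("LEC->HP" = 0, "HP->PFC" = 0,
                               "LEC->PFC" = 0))
  ds <- gpdc(mvar_from_config(cfg), seq(1, 45))
  offdiag <- ds$gpdc
  for (f in seq_along(ds$freqs)) diag(offdiag[, , f]) <- 0
  expect_lt(max(offdiag), 0.05)
})

test_that("GE coupling reduction shows in the generating-model gPDC", {
  con <- band_average(gpdc(mvar_from_config(fast_cfg(group = "CON")),
                           1:45), 4, 30)
  ge <- band_average(gpdc(mvar_from_config(fast_cfg(group = "GE")),
                          1:45), 4, 30)
  expect_lt(ge["HP", "LEC"], con["HP", "LEC"])
  # ordering the generator encodes: LEC->HP strongest, LEC->PFC weakest
  expect_gt(con["HP", "LEC"], con["PFC", "LEC"])
})

test_that("unstable configurations are rejected", {
  expect_error(mvar_from_config(fast_cfg(theta_pole = c(8, 1.01))),
               class = "lfpnet_error_unstable_mvar")
})

test_that("in-burst band power clearly exceeds the out-of-burst baseline", {
  sim <- simulate_lfp(sim_config(seed = 5, duration_s = 300))
  p_in <- psd_events(sim$recording, sim$events, channel = 1)
  p_out <- psd_baseline(sim$recording, sim$events, channel = 1)
  # integrated 4-30 Hz contrast implied by the 6 dB amplitude calibration
  # against the 3-100 Hz background (about 9 dB); assert > 6 dB
  contrast_db <- 10 * log10(band_average(p_in, 4, 30) /
                              band_average(p_out, 4, 30))
  expect_gt(contrast_db, 6)
})

test_that("responder spikes follow the per-pulse response probability", {
  cfg <- sim_config(seed = 11, duration_s = 130,
                    responder_fraction = c(CON = 1, GE = 0.11),
                    spikes = list(n_units_per_region = 1,
                                  baseline_rate_hz = 0,
                                  coupling_strength = 0, p_resp = 1,
                                  resp_latency_s = c(0.003, 0.010)))
  sim <- simulate_lfp(cfg)
  prot <- stim_protocol("pulse", sweep_onsets = seq(1, 121, by = 2.4),
                        pulse_onsets = seq(0, 2.875, by = 0.125),
                        pulse_width_s = 0.003)
  sp <- simulate_spikes(sim$recording, cfg, prot)
  fp <- firing_probability(sp, prot)
  expect_true(all(fp >= 0.99))

  # p_resp = 0 with a plain Poisson baseline: counts in the 20 ms windows
  # stay within the Poisson 99% CI of rate x window
  cfg0 <- sim_config(seed = 12, duration_s = 130,
                     responder_fraction = c(CON = 1, GE = 0.11),
                     spikes = list(n_units_per_region = 3,
                                   baseline_rate_hz = 2,
                                   coupling_strength = 0, p_resp = 0,
                                   resp_latency_s = c(0.003, 0.010)))
  sim0 <- simulate_lfp(cfg0)
  sp0 <- simulate_spikes(sim0$recording, cfg0, prot)
  fp0 <- firing_probability(sp0, prot)
  n_pulses <- length(pulse_times(prot))
  lam <- 2 * 0.020 * n_pulses        # expected evoked-window count per unit
  ci <- qpois(c(0.005, 0.995), lam) / n_pulses
  expect_true(all(fp0 >= ci[1] & fp0 <= ci[2]))

  # silent configuration -> empty trains
  cfgs <- sim_config(seed = 13, duration_s = 70,
                     spikes = list(n_units_per_region = 2,
                                   baseline_rate_hz = 0,
                                   coupling_strength = 0, p_resp = 0,
                                   resp_latency_s = c(0.003, 0.010)))
  sims <- simulate_lfp(cfgs)
  sps <- simulate_spikes(sims$recording, cfgs)
  expect_true(all(lengths(sps$times) == 0))
})

test_that("laminar mode projects a known dipole across the probe", {
  cfg <- fast_cfg(seed = 21, duration_s = 70, n_channels_per_region = 16)
  sim <- simulate_lfp(cfg)
  expect_equal(nrow(sim$recording$signal), 48)
  w <- dipole_weights(16, cfg$laminar$sink_channel)
  # channel amplitude profile within a region follows |w|
  sds <- apply(sim$recording$signal[1:16, ], 1, sd)
  expect_gt(cor(sds, abs(w)), 0.95)
})

test_that("behavior generator reproduces the configured group contrast", {
  beh <- simulate_behavior(n_per_group = 20, seed = 5)
  con <- beh[beh$group == "CON", ]
  di <- discrimination_index(con$t_novel_s, con$t_familiar_s)
  expect_gt(mean(di), 0.3)
  expect_lt(mean(di), 0.55)

  # zero effect: mean DI near 0 by symmetry
  beh0 <- simulate_behavior(n_per_group = 50,
                            effects = list(CON = c(novel = 4,
                                                   familiar = 4)),
                            seed = 6)
  di0 <- discrimination_index(beh0$t_novel_s, beh0$t_familiar_s)
  expect_lt(abs(mean(di0)), 0.1)

  # low-velocity animals are present and flagged for exclusion
  flt <- exclusion_filter(beh)
  expect_gt(flt$n_excluded, 0)
  expect_true(all(flt$excluded$velocity_cm_min < 20))
})
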