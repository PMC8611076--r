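# shared fixtures: tiny recordings and fast simulation configs

one_channel_rec <- function(x, fs, region = "LEC", t0 = 0) {
  recording(matrix(x, nrow = 1), fs,
            data.frame(index = 1L, region = region, layer = "",
                       depth_um = 0), t0 = t0)
}

region_channels <- function() stats::setNames(1:3, c("LEC", "HP", "PFC"))

fast_cfg <- function(seed = 1L, group = "CON", duration_s = 90, ...) {
  sim_config(seed = seed, group = group, duration_s = duration_s, ...)
}

# alpha-function synthetic EPSC sweeps (inward negative), pA
epsc_sweeps <- function(n_sweeps = 20, fs = 20000, amp_pa = 45,
                        stim_onset_s = 0.05, delay_s = 0.006,
                        tau_s = 0.003, noise_sd = 1, dur_s = 0.1) {
  t <- seq(0, dur_s, by = 1 / fs)
  t0 <- stim_onset_s + delay_s
  base <- ifelse(t > t0, -amp_pa * (t - t0) / tau_s * exp(1 - (t - t0) / tau_s),
                 0)
  t(vapply(seq_len(n_sweeps),
           function(i) base + stats::rnorm(length(t), sd = noise_sd),
           numeric(length(t))))
}
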