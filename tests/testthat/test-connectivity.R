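make_epochs <- function(n_ep, n_samp, gen) {
  t(vapply(seq_len(n_ep), function(i) gen(), numeric(n_samp)))
}

test_that("cross-spectra obey self-identity and the shift theorem", {
  set.seed(1)
  fs <- 1000
  xe <- make_epochs(50, fs, function() rnorm(fs))
  cs <- cross_spectra(xe, xe, fs)
  expect_equal(Re(cs$pxy), cs$pxx, tolerance = 1e-10)
  expect_lt(max(abs(Im(cs$pxy))), 1e-10)

  # delayed copy: cross-spectral phase is linear with slope 2 pi delay
  d <- 10  # samples
  xl <- make_epochs(80, fs + d, function() rnorm(fs + d))
  xe2 <- xl[, 1:fs]
  ye2 <- xl[, (d + 1):(fs + d)]
  cs2 <- cross_spectra(xe2, ye2, fs)
  sel <- cs2$freqs >= 5 & cs2$freqs <= 80
  ph <- Arg(cs2$pxy[sel])
  slope <- coef(lm(signal::unwrap(ph) ~ cs2$freqs[sel]))[2]
  expect_lt(abs(abs(slope) - 2 * pi * d / fs) / (2 * pi * d / fs), 0.05)

  # independent epochs: |Pxy| shrinks like 1/sqrt(n)
  mags <- vapply(c(10, 40, 160), function(n_ep) {
    a <- make_epochs(n_ep, 500, function() rnorm(500))
    b <- make_epochs(n_ep, 500, function() rnorm(500))
    co <- coherence(cross_spectra(a, b, fs))
    mean(co$magnitude)
  }, 0)
  expect_lt(mags[2], mags[1])
  expect_lt(mags[3], mags[2])
})

test_that("coherence identities: self, independence bias, quadrature", {
  set.seed(2)
  fs <- 1000
  xe <- make_epochs(60, fs, function() rnorm(fs))
  co <- coherence(cross_spectra(xe, xe, fs))
  expect_true(all(abs(co$magnitude - 1) < 1e-9))
  expect_true(all(co$imag < 1e-9))

  n_ep <- 200
  a <- make_epochs(n_ep, 500, function() rnorm(500))
  b <- make_epochs(n_ep, 500, function() rnorm(500))
  ci <- coherence(cross_spectra(a, b, fs))
  expect_lt(mean(ci$magnitude), 3 / sqrt(n_ep))
  expect_true(all(ci$imag <= ci$magnitude + 1e-12))

  # 90 degree shifted narrowband pair: coherency nearly pure imaginary
  t <- seq_len(fs) / fs
  ph <- runif(80, 0, 2 * pi)
  xe3 <- t(vapply(ph, function(p) sin(2 * pi * 10 * t + p) +
                    0.1 * rnorm(fs), numeric(fs)))
  ye3 <- t(vapply(ph, function(p) cos(2 * pi * 10 * t + p) +
                    0.1 * rnorm(fs), numeric(fs)))
  cq <- coherence(cross_spectra(xe3, ye3, fs))
  i10 <- which(cq$freqs == 10)
  expect_gt(cq$imag[i10] / cq$magnitude[i10], 0.95)
})

test_that("shuffled null separates coupled pairs from independent ones", {
  set.seed(3)
  fs <- 1000
  t <- seq_len(fs) / fs
  ph <- runif(60, 0, 2 * pi)
  xe <- t(vapply(ph, function(p) sin(2 * pi * 12 * t + p) +
                   0.3 * rnorm(fs), numeric(fs)))
  ye <- t(vapply(ph, function(p) sin(2 * pi * 12 * t + p + 1) +
                   0.3 * rnorm(fs), numeric(fs)))
  obs <- coherence(cross_spectra(xe, ye, fs))
  null <- shuffle_null(xe, ye, fs, n_shuffle = 20, seed = 1)
  i12 <- which(obs$freqs == 12)
  expect_gt(obs$magnitude[i12], 5 * null$magnitude[i12])

  a <- make_epochs(60, fs, function() rnorm(fs))
  b <- make_epochs(60, fs, function() rnorm(fs))
  obs_i <- coherence(cross_spectra(a, b, fs))
  null_i <- shuffle_null(a, b, fs, n_shuffle = 20, seed = 2)
  expect_lt(abs(mean(obs_i$magnitude) - mean(null_i$magnitude)), 0.05)
  expect_error(shuffle_null(a, b, fs, n_shuffle = 0),
               class = "lfpnet_error_config")
})

test_that("MVAR estimation recovers known coefficients and selects order", {
  A <- array(0, c(3, 3, 3))
  A[, , 1] <- diag(c(0.5, 0.4, 0.3)); A[1, 2, 1] <- 0.3
  A[, , 2] <- diag(c(-0.3, -0.2, -0.25)); A[3, 1, 2] <- 0.2
  A[, , 3] <- diag(c(0.1, 0.1, 0.05))
  truth <- mvar_model(A, diag(3), 100)
  orders <- integer(10); rmse <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    X <- t(simulate_mvar(truth, 6000))
    fit <- fit_mvar(X, 100, p_max = 10)
    orders[s] <- fit$selected_order
    Afit <- array(0, c(3, 3, 3))
    Afit[, , seq_len(min(3, fit$selected_order))] <-
      fit$A[, , seq_len(min(3, fit$selected_order))]
    rmse[s] <- sqrt(mean((Afit - A)^2))
  }
  expect_gte(mean(orders == 3), 0.9)
  expect_lt(max(rmse), 0.05)

  # white noise: small selected order, near-zero off-diagonals
  set.seed(20)
  W <- matrix(rnorm(3 * 4000), 4000, 3)
  fw <- fit_mvar(W, 100, p_max = 6)
  expect_lte(fw$selected_order, 2)
  offd <- fw$A[, , 1]; diag(offd) <- 0
  expect_lt(max(abs(offd)), 0.08)

  expect_error(fit_mvar(matrix(rnorm(150), 50, 3), 100, p_max = 50),
               class = "lfpnet_error_insufficient_samples")
})

test_that("gPDC matches hand-derived values and its normalization identity", {
  # bivariate x -> y only: Abar(0) = [[1-a, 0], [-c, 1]];
  # gpdc(y<-x, 0) = c / sqrt((1-a)^2 + c^2) = 0.4/sqrt(0.25+0.16)
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.4
  m <- mvar_model(A, diag(2), 100)
  ds <- gpdc(m, c(0, 5, 10, 25))
  expect_equal(ds$gpdc[2, 1, 1], 0.4 / sqrt(0.25 + 0.16), tolerance = 1e-10)
  expect_true(all(ds$gpdc[1, 2, ] < 0.05))  # no y -> x coupling

  # diagonal model: off-diagonal identically zero, diagonal one
  Ad <- array(0, c(3, 3, 2))
  Ad[, , 1] <- diag(c(0.5, 0.3, 0.4)); Ad[, , 2] <- diag(c(-0.2, 0.1, 0))
  dsd <- gpdc(mvar_model(Ad, diag(c(1, 2, 0.5)), 100), seq(0, 45, by = 5))
  for (f in 1:10) {
    off <- dsd$gpdc[, , f]; diag(off) <- 0
    expect_true(all(off == 0))
    expect_true(all(abs(diag(dsd$gpdc[, , f]) - 1) < 1e-12))
  }

  # column normalization holds for random stable models
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    Ar <- array(rnorm(k * k * 2, sd = 0.15), c(k, k, 2))
    S <- crossprod(matrix(rnorm(k * k), k, k)) + diag(k) * 0.1
    mm <- tryCatch(mvar_model(Ar, S, 100), error = function(e) NULL)
    if (is.null(mm)) next
    dd <- gpdc(mm, seq(1, 45, by = 3))
    expect_lt(max(abs(apply(dd$gpdc^2, c(2, 3), sum) - 1)), 1e-8)
  }
})

test_that("fitted gPDC matches the generating model within estimation error", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(1.2, 0, 0.35, 1.1), 2, 2, byrow = TRUE)
  A[, , 2] <- diag(c(-0.5, -0.45))
  truth <- mvar_model(A, diag(2), 100)
  set.seed(6)
  X <- t(simulate_mvar(truth, 6000))     # 60 s at 100 Hz
  fit <- fit_mvar(X, 100, order = 2)
  freqs <- seq(1, 45)
  g_true <- gpdc(truth, freqs)$gpdc
  g_fit <- gpdc(fit, freqs)$gpdc
  expect_lt(sqrt(mean((g_true - g_fit)^2)), 0.05)
})

test_that("gPDC pipeline recovers the configured directionality", {
  sim <- simulate_lfp(fast_cfg(seed = 8, duration_s = 120))
  gp <- gpdc_pipeline(sim$recording, sim$events, region_channels(),
                      p_max = 8)
  bm <- gp$band_matrix
  expect_gt(bm["HP", "LEC"], bm["LEC", "HP"])
  expect_gt(bm["HP", "LEC"], bm["PFC", "LEC"])
  expect_lt(max(abs(apply(gp$gpdc$gpdc^2, c(2, 3), sum) - 1)), 1e-8)
  expect_error(gpdc_pipeline(sim$recording, sim$events, c(LEC = 1L)),
               class = "lfpnet_error_config")
})

test_that("volume conduction inflates magnitude but not imaginary coherence", {
  set.seed(7)
  fs <- 1000
  n_ep <- 100
  xe <- matrix(0, n_ep, fs); ye <- matrix(0, n_ep, fs)
  for (i in seq_len(n_ep)) {
    s1 <- bandpass(rnorm(fs), 4, 30, fs = fs)
    s2 <- bandpass(rnorm(fs), 4, 30, fs = fs)
    xe[i, ] <- s1 + 0.5 * s2
    ye[i, ] <- 0.5 * s1 + s2
  }
  co <- coherence(cross_spectra(xe, ye, fs))
  expect_gt(band_average(co, 4, 30, value = "magnitude"), 0.3)
  expect_lt(band_average(co, 4, 30, value = "imag"), 0.05)
})
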