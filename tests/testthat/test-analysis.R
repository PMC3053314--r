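test_that("stationary statistics: degenerate input and ACF lag-0 identity", {
  expect_error(stationary_stats(rep(0.5, 4), 0.1), "too short")
  st <- stationary_stats(rep(0.5, 1000), 0.1)
  expect_equal(st$variance, 0)
  expect_null(st$acf$fit)
  set.seed(1)
  z <- ou_simulate(1, 2, 5e4, 0.1)
  st <- stationary_stats(z, 0.1)
  expect_identical(st$acf$values[1], st$variance)
})

test_that("ACF fit recovers OU parameters within 10% at 1e6 samples", {
  set.seed(2)
  sigma <- 0.8
  tau <- 3
  z <- ou_simulate(sigma, tau, 1e6, 0.1)
  st <- stationary_stats(z, 0.1)
  expect_lt(abs(st$acf$fit$tau - tau) / tau, 0.1)
  expect_lt(abs(st$acf$fit$amplitude - sigma^2) / sigma^2, 0.1)
})

test_that("spike detection handles flat, single-AP and periodic traces", {
  expect_length(detect_spikes(rep(-65, 1000), 0.01), 0)
  t <- seq(0, 20, by = 0.01)
  ap <- -65 + 100 * exp(-(t - 10)^2 / 0.5)
  s <- detect_spikes(ap, 0.01)
  expect_length(s, 1)
  expect_equal(s, 10, tolerance = 0.6)
  # deterministic suprathreshold run: spike count equals cycles of the
  # limit-cycle period
  fx <- hh_small_fixture()
  r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                          stim_dc(15), 1000, 0.01,
                          backend = "deterministic")
  isi <- diff(r$spikes)
  period <- mean(isi[-1]) # drop the onset transient
  expect_equal(length(r$spikes), floor(1000 / period) + 1, tolerance = 1)
  expect_lt(isi_statistics(r$spikes, 1000)$cv, 0.05)
})

test_that("ISI statistics: periodic, Poisson and undefined cases", {
  per <- seq(10, 990, by = 20)
  st <- isi_statistics(per, 1000)
  expect_equal(st$cv, 0)
  expect_equal(st$rate_hz, length(per))
  set.seed(3)
  pois <- cumsum(rexp(2000, rate = 0.05))
  st <- isi_statistics(pois[pois < 30000], 30000)
  expect_equal(st$cv, 1, tolerance = 0.1)
  st2 <- isi_statistics(c(5, 9), 100)
  expect_false(st2$cv_defined)
  expect_true(is.na(st2$cv))
})

test_that("efficacy, latency and jitter follow their definitions", {
  tr <- spike_train_set(rep(list(12.5), 10), 50)
  e <- efficacy_latency_jitter(tr, 10, 20)
  expect_equal(e$efficacy, 1)
  expect_equal(e$latency_ms, 2.5)
  expect_equal(e$jitter_ms, 0)
  none <- spike_train_set(rep(list(numeric(0)), 10), 50)
  e0 <- efficacy_latency_jitter(none, 10, 20)
  expect_equal(e0$efficacy, 0)
  expect_true(is.na(e0$latency_ms))
})

test_that("reliability is 1 for identical trains and low for Poisson trains", {
  tr <- spike_train_set(rep(list(c(40, 120, 260)), 8), 400)
  rp <- reliability_precision(tr)
  expect_identical(rp$reliability, 1)
  expect_equal(rp$precision_ms, 0)
  set.seed(4)
  pois <- lapply(1:10, function(i) {
    s <- cumsum(rexp(100, rate = 0.01))
    s[s < 2000]
  })
  rp2 <- reliability_precision(spike_train_set(pois, 2000))
  expect_lt(rp2$reliability, 0.5)
})

test_that("Welch PSD is flat for white noise and Lorentzian for an OU", {
  set.seed(5)
  x <- rnorm(2e5)
  w <- welch_psd(x, 0.1, window_ms = 200)
  expect_equal(sum(w$power) * diff(w$freq_hz[1:2]), var(x),
               tolerance = 0.05)
  thirds <- cut(seq_along(w$freq_hz), 3)
  band <- tapply(w$power, thirds, mean)
  expect_lt(max(band) / min(band), 1.15)

  tau <- 5
  z <- ou_simulate(1, tau, 1e6, 0.1)
  wz <- welch_psd(z, 0.1, window_ms = 2000)
  fc <- 1000 / (2 * pi * tau)
  plateau <- mean(wz$power[wz$freq_hz > fc / 40 & wz$freq_hz < fc / 10])
  at_fc <- mean(wz$power[abs(wz$freq_hz - fc) < fc / 10])
  expect_equal(at_fc / plateau, 0.5, tolerance = 0.15)
})

test_that("spike blanking excludes contaminated windows", {
  set.seed(6)
  x <- rnorm(1e4)
  w_all <- welch_psd(x, 0.1, window_ms = 100)
  w_blank <- welch_psd(x, 0.1, window_ms = 100,
                       spike_times = c(300, 600), blank_ms = c(2, 8))
  expect_lt(w_blank$n_segments, w_all$n_segments)
  expect_error(welch_psd(x, 0.1, window_ms = 100,
                         spike_times = seq(0, 1000, by = 20),
                         blank_ms = c(50, 50)),
               "blanked")
})
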