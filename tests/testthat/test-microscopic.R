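test_that("population stepping conserves channels and respects zero rates", {
  sch <- two_state_scheme(0, 0)
  st <- population_state(c(40L, 60L))
  A <- transition_matrix(sch, 0)
  expect_identical(step_population(st, A, 0.01)$counts, st$counts)

  set.seed(1)
  sch <- constant_n4_scheme(2, 1)
  A <- transition_matrix(sch, 0)
  st <- sample_stationary_counts(sch, 0, 500L)
  for (i in 1:200) {
    st <- step_population(st, A, 0.01)
    expect_identical(sum(st$counts), 500L)
    expect_true(all(st$counts >= 0L))
  }
})

test_that("too-large steps raise an error naming the offending state", {
  sch <- two_state_scheme(200, 1)
  A <- transition_matrix(sch, 0)
  st <- population_state(c(50L, 50L))
  expect_error(step_population(st, A, 0.01), "state 1")
})

test_that("symmetric 2-state population reaches the binomial stationary law", {
  set.seed(42)
  sch <- two_state_scheme(1, 1) # tau = 0.5 ms, p = 0.5
  N <- 200L
  r <- run_voltage_clamp(channel_population(sch, N), 0, 4000, dt = 0.01,
                         backend = "microscopic", burn_in = 100,
                         record_every = 100L) # 1 ms = 2 tau apart
  z <- r$z
  se_mean <- sqrt(0.25 / N / length(z)) # nearly independent samples
  expect_lt(abs(mean(z) - 0.5), 3 * se_mean * 1.5)
  # occupancy histogram consistent with Binomial(N, 1/2)
  counts <- round(z * N)
  probs <- dbinom(0:N, N, 0.5)
  lo <- qbinom(0.0005, N, 0.5)
  hi <- qbinom(0.9995, N, 0.5)
  bins <- c(-1, seq(lo, hi, by = 4), N + 1)
  obs <- table(cut(counts, bins))
  expv <- diff(pbinom(bins, N, 0.5))
  p <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = expv)$p.value)
  expect_gt(p, 0.01)
})

test_that("open fraction is the conducting-state share with binomial variance", {
  sch <- constant_n4_scheme(1, 1)
  M <- n_states(sch)
  all_open <- population_state(c(rep(0L, M - 1L), 100L))
  expect_equal(open_fraction(all_open, sch), 1)
  none_open <- population_state(c(100L, rep(0L, M - 1L)))
  expect_equal(open_fraction(none_open, sch), 0)

  set.seed(7)
  kn <- hh_potassium_scheme()
  pop <- channel_population(kn, 1800L, e_rev = -77)
  r <- run_voltage_clamp(pop, -35, 4000, dt = 0.01,
                         backend = "microscopic", burn_in = 200)
  sp <- covariance_spectrum(kn, -35, 1800L)
  st <- stationary_stats(r$z, 0.01)
  se <- vclamp_se(sp, 3800)
  expect_lt(abs(st$variance - sum(sp$sigma_sq)), 3 * se$var)
})

test_that("clamped microscopic mean matches n_inf^4 and is dt-robust", {
  kn <- hh_potassium_scheme()
  pop <- channel_population(kn, 1800L, e_rev = -77)
  v <- -40
  p_open <- attr(covariance_spectrum(kn, v, 1800L), "p_open")
  se <- vclamp_se(covariance_spectrum(kn, v, 1800L), 5800)
  set.seed(11)
  r1 <- run_voltage_clamp(pop, v, 6000, dt = 0.01,
                          backend = "microscopic", burn_in = 200)
  expect_lt(abs(mean(r1$z) - p_open), 3 * se$mean)
  set.seed(12)
  r2 <- run_voltage_clamp(pop, v, 6000, dt = 0.005,
                          backend = "microscopic", burn_in = 200)
  expect_lt(abs(mean(r2$z) - mean(r1$z)), 4 * se$mean)
  expect_lt(abs(var(r2$z) - var(r1$z)), 5 * se$var)
})

test_that("microscopic runs are bit-for-bit reproducible from a seed", {
  kn <- hh_potassium_scheme()
  pop <- channel_population(kn, 360L, e_rev = -77)
  a <- run_voltage_clamp(pop, -30, 50, backend = "microscopic", seed = 99L)
  b <- run_voltage_clamp(pop, -30, 50, backend = "microscopic", seed = 99L)
  expect_identical(a$z, b$z)
})

test_that("autocovariance of clamped counts decays as the spectrum predicts", {
  set.seed(13)
  kn <- hh_potassium_scheme()
  pop <- channel_population(kn, 1800L, e_rev = -77)
  v <- -30
  r <- run_voltage_clamp(pop, v, 10000, dt = 0.01,
                         backend = "microscopic", burn_in = 500,
                         record_every = 5L)
  sp <- covariance_spectrum(kn, v, 1800L)
  st <- stationary_stats(r$z, 0.05, max_lag_ms = 5 * max(sp$tau))
  pred <- spectrum_acov(sp, st$acf$lags_ms)
  # multi-exponential prediction tracks the empirical ACF
  expect_lt(mean(abs(st$acf$values - pred)) / sum(sp$sigma_sq), 0.1)
  # fitted single-exponential tau lies between the extreme kinetic taus
  expect_gt(st$acf$fit$tau, min(sp$tau) / 2)
  expect_lt(st$acf$fit$tau, max(sp$tau) * 2)
})
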