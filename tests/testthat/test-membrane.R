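test_that("geometry and conductance bookkeeping are consistent", {
  g <- cylinder_geometry(30, 30)
  expect_equal(g$area_um2, pi * 30 * 30)
  fx <- build_hh_fixture()
  # gamma * N / area reproduces the classical maximal conductances
  gna <- fx$populations$na$gamma_ps * fx$populations$na$n_channels /
    fx$geometry$area_um2 * 0.1
  gk <- fx$populations$k$gamma_ps * fx$populations$k$n_channels /
    fx$geometry$area_um2 * 0.1
  expect_equal(gna, 120, tolerance = 1e-4)
  expect_equal(gk, 36, tolerance = 1e-4)
  expect_error(build_hh_fixture(list(nonsense = 1)), "unknown")
})

test_that("stimulus builders realise the declared waveforms", {
  p <- build_stimulus_trace(stim_pulse(5, 1, 2), 500, 0.01)
  expect_equal(sum(p > 0) * 0.01, 2)
  expect_equal(max(p), 5)
  b <- build_stimulus_trace(stim_biphasic(-2, 3, 6, 1, onset_ms = 1), 800,
                            0.01)
  expect_equal(range(b), c(-2, 6))
  expect_equal(sum(b < 0) * 0.01, 3)
  expect_equal(sum(b > 0) * 0.01, 1)
  # frozen OU stimulus: identical across builds, independent of caller RNG
  s <- stim_ou(3, 1, 5, seed = 77L)
  set.seed(1)
  o1 <- build_stimulus_trace(s, 1000, 0.01)
  set.seed(2)
  o2 <- build_stimulus_trace(s, 1000, 0.01)
  expect_identical(o1, o2)
  expect_equal(mean(o1), 3, tolerance = 0.5)
})

test_that("deterministic membrane at rest stays at rest with no spikes", {
  fx <- hh_small_fixture()
  r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                          stim_dc(0), 300, 0.01, backend = "deterministic")
  expect_length(r$spikes, 0)
  vr <- resting_potential(fx$membrane, fx$populations, fx$geometry$area_um2)
  expect_lt(max(abs(r$v - vr)), 0.02)
})

test_that("deterministic spike times converge under step halving", {
  fx <- hh_small_fixture()
  r1 <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                           stim_dc(10), 500, 0.001,
                           backend = "deterministic")
  r2 <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                           stim_dc(10), 500, 0.0005,
                           backend = "deterministic")
  expect_equal(length(r1$spikes), length(r2$spikes))
  expect_lt(max(abs(r1$spikes - r2$spikes)), 0.1)
  # and the error is first order: halving dt roughly halves the drift
  r3 <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                           stim_dc(10), 500, 0.002,
                           backend = "deterministic")
  n <- min(length(r3$spikes), length(r2$spikes))
  d_coarse <- max(abs(r3$spikes[seq_len(n)] - r2$spikes[seq_len(n)]))
  d_fine <- max(abs(r1$spikes - r2$spikes))
  expect_lt(d_fine, d_coarse)
})

test_that("every stochastic backend reduces to the deterministic trace with noise off", {
  fx <- hh_small_fixture()
  ref <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                            stim_dc(8), 200, 0.01,
                            backend = "deterministic")
  for (b in c("microscopic", "effective", "reduced", "fox")) {
    r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                            stim_dc(8), 200, 0.01, backend = b,
                            noise_off = TRUE, seed = 1L)
    expect_lt(max(abs(r$v - ref$v)), 0.01)
  }
})

test_that("current-clamp runs are reproducible and carry full metadata", {
  fx <- hh_small_fixture()
  a <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                          stim_dc(3), 100, 0.01, backend = "effective",
                          seed = 5L)
  b <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                          stim_dc(3), 100, 0.01, backend = "effective",
                          seed = 5L)
  expect_identical(a$v, b$v)
  expect_identical(a$spikes, b$spikes)
  expect_equal(a$metadata$backend, "effective")
  expect_equal(a$metadata$clip, "none")
  expect_true(all(c("seed", "dt", "v0", "n_channels", "stimulus") %in%
                    names(a$metadata)))
})

test_that("microscopic and effective subthreshold voltage variance agree", {
  fx <- cached("fx20", build_hh_fixture(list(diameter_um = 20,
                                             length_um = 20)))
  vm <- cached("memb_micro_var", {
    r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                            stim_dc(1), 8000, 0.01,
                            backend = "microscopic", seed = 21L,
                            record_every = 10L)
    var(r$v[r$time > 500])
  })
  ve <- cached("memb_eff_var", {
    r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                            stim_dc(1), 8000, 0.01, backend = "effective",
                            seed = 22L, record_every = 10L)
    var(r$v[r$time > 500])
  })
  expect_lt(abs(ve / vm - 1), 0.2)
})

test_that("protocol runner produces tidy per-trial structures", {
  fx <- hh_small_fixture()
  trains <- run_protocol("pulse_trials",
                         list(fixture = fx,
                              stimulus = stim_pulse(60, 2, 0.5),
                              n_trials = 5L, duration_ms = 15,
                              dt = 0.005, backend = "effective",
                              seed = 3L))
  expect_s3_class(trains, "spike_train_set")
  expect_length(trains$trials, 5L)
  e <- efficacy_latency_jitter(trains, 2, 10)
  expect_equal(e$efficacy, 1) # far above threshold: every trial spikes
})
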