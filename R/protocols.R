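#' Deterministic per-trial seed derivation
#'
#' Counter-based mixing of a master seed with a trial index, so that trial
#' streams are reproducible and independent of how many trials run before
#' them.
#'
#' @param master master seed (integer).
#' @param index trial counter (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(master) %% m) * 48271 %% m
  as.integer((s + (index + 1) * 16807) %% m)
}

#' Run a named experimental protocol
#'
#' Orchestrates repeated [integrate_membrane()] / [run_voltage_clamp()]
#' calls with per-trial seeds. Available protocols:
#'
#' * `"voltage_clamp"`: open-fraction statistics of one population across
#'   holding voltages and backends. Config: `population`, `voltages`,
#'   `backends`, `duration_ms`, `dt`, `burn_in_ms`, `record_every`,
#'   `seed`.
#' * `"fi_curve"`: mean firing rate vs DC amplitude. Config: `fixture`,
#'   `amplitudes`, `backend`, `n_rep`, `duration_ms`, `dt`, `seed`.
#' * `"pulse_trials"`: repeated mono-/biphasic pulse responses. Config:
#'   `fixture`, `stimulus`, `n_trials`, `duration_ms`, `dt` (default
#'   0.001 ms for latency resolution), `backend`, `seed`.
#' * `"reliability_trials"`: repeated identical (frozen) stimulus. Config:
#'   `fixture`, `stimulus`, `n_trials`, `duration_ms`, `dt`, `backend`,
#'   `seed`.
#' * `"psd_recording"`: a long subthreshold trace plus its Welch spectrum.
#'   Config: `fixture`, `i_hold`, `duration_ms`, `dt`, `backend`,
#'   `record_every`, `window_ms`, `seed`.
#'
#' @param protocol protocol name.
#' @param config named list (see above).
#' @return protocol-specific structured result (see details).
#' @export
run_protocol <- function(protocol = c("voltage_clamp", "fi_curve",
                                      "pulse_trials", "reliability_trials",
                                      "psd_recording"),
                         config = list()) {
  protocol <- match.arg(protocol)
  switch(protocol,
         voltage_clamp = protocol_voltage_clamp(config),
         fi_curve = protocol_fi_curve(config),
         pulse_trials = protocol_pulse_trials(config),
         reliability_trials = protocol_reliability_trials(config),
         psd_recording = protocol_psd_recording(config))
}

cfg_get <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

protocol_voltage_clamp <- function(config) {
  pop <- config$population
  stopifnot(inherits(pop, "channel_population"))
  voltages <- cfg_get(config, "voltages", seq(-60, -20, by = 10))
  backends <- cfg_get(config, "backends", c("microscopic", "effective"))
  duration <- cfg_get(config, "duration_ms", 5000)
  dt <- cfg_get(config, "dt", 0.01)
  burn <- cfg_get(config, "burn_in_ms", 200)
  re <- cfg_get(config, "record_every", 1L)
  seed <- cfg_get(config, "seed", 1L)
  rows <- list()
  k <- 0L
  for (v in voltages) {
    sp <- covariance_spectrum(pop$scheme, v, pop$n_channels)
    for (b in backends) {
      k <- k + 1L
      r <- run_voltage_clamp(pop, v, duration, dt, backend = b,
                             burn_in = burn, record_every = re,
                             seed = derive_seed(seed, k))
      st <- stationary_stats(r$z, dt * re)
      rows[[k]] <- data.frame(
        v = v, backend = b, mean = st$mean, variance = st$variance,
        acf_tau = if (is.null(st$acf$fit)) NA_real_ else st$acf$fit$tau,
        p_open = attr(sp, "p_open"),
        var_theory = sum(sp$sigma_sq))
    }
  }
  do.call(rbind, rows)
}

protocol_fi_curve <- function(config) {
  fx <- config$fixture
  amplitudes <- config$amplitudes
  stopifnot(inherits(fx, "hh_fixture"), is.numeric(amplitudes))
  backend <- cfg_get(config, "backend", "effective")
  n_rep <- cfg_get(config, "n_rep", 10L)
  duration <- cfg_get(config, "duration_ms", 5000)
  dt <- cfg_get(config, "dt", 0.01)
  seed <- cfg_get(config, "seed", 1L)
  rows <- list()
  k <- 0L
  for (amp in amplitudes) {
    rates <- vapply(seq_len(n_rep), function(rep) {
      k <<- k + 1L
      r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                              stim_dc(amp), duration, dt, backend = backend,
                              seed = derive_seed(seed, k),
                              record_every = cfg_get(config, "record_every",
                                                     5L))
      isi_statistics(r$spikes, duration)$rate_hz
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      amplitude = amp, backend = backend, rate_hz = mean(rates),
      rate_sd = if (n_rep > 1L) sd(rates) else NA_real_, n_rep = n_rep)
  }
  do.call(rbind, rows)
}

protocol_trials <- function(config, default_dt) {
  fx <- config$fixture
  stopifnot(inherits(fx, "hh_fixture"),
            inherits(config$stimulus, "stimulus"))
  n_trials <- cfg_get(config, "n_trials", 100L)
  duration <- cfg_get(config, "duration_ms", 30)
  dt <- cfg_get(config, "dt", default_dt)
  backend <- cfg_get(config, "backend", "effective")
  seed <- cfg_get(config, "seed", 1L)
  re <- cfg_get(config, "record_every", 1L)
  seeds <- vapply(seq_len(n_trials), function(i) derive_seed(seed, i),
                  integer(1))
  trials <- lapply(seeds, function(s) {
    integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                       config$stimulus, duration, dt, backend = backend,
                       seed = s, record_every = re)$spikes
  })
  spike_train_set(trials, duration, stimulus = config$stimulus,
                  seeds = seeds)
}

protocol_pulse_trials <- function(config) {
  # fine default step for sub-ms latency and jitter resolution
  protocol_trials(config, default_dt = 0.001)
}

protocol_reliability_trials <- function(config) {
  protocol_trials(config, default_dt = 0.01)
}

protocol_psd_recording <- function(config) {
  fx <- config$fixture
  stopifnot(inherits(fx, "hh_fixture"))
  i_hold <- cfg_get(config, "i_hold", 0)
  duration <- cfg_get(config, "duration_ms", 20000)
  dt <- cfg_get(config, "dt", 0.01)
  backend <- cfg_get(config, "backend", "effective")
  re <- cfg_get(config, "record_every", 10L)
  window <- cfg_get(config, "window_ms", 1024)
  seed <- cfg_get(config, "seed", 1L)
  r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                          stim_dc(i_hold), duration, dt, backend = backend,
                          seed = seed, record_every = re)
  psd <- welch_psd(r$v, dt * re, window_ms = window,
                   spike_times = r$spikes,
                   blank_ms = cfg_get(config, "blank_ms", c(2, 8)))
  list(result = r, psd = psd)
}

#' Side-by-side backend comparisons for the standard experiments
#'
#' Runs a named experiment under several channel-noise backends with
#' matched per-trial seed policy and returns tidy side-by-side statistics.
#'
#' @param experiment one of `"vclamp_stats"`, `"spontaneous"`, `"fi"`,
#'   `"pulse_response"`, `"reliability"`, `"psd"`.
#' @param config named list; common fields `fixture` (or `population` for
#'   `vclamp_stats`), `backends`, `seed`, plus the per-protocol fields of
#'   [run_protocol()].
#' @return a data frame (or named list of per-backend results for
#'   `"pulse_response"`, `"reliability"` and `"psd"`).
#' @export
compare_backends <- function(experiment = c("vclamp_stats", "spontaneous",
                                            "fi", "pulse_response",
                                            "reliability", "psd"),
                             config = list()) {
  experiment <- match.arg(experiment)
  backends <- cfg_get(config, "backends",
                      c("microscopic", "effective", "fox"))
  seed <- cfg_get(config, "seed", 1L)
  if (experiment == "vclamp_stats") {
    config$backends <- backends
    return(protocol_voltage_clamp(config))
  }
  if (experiment == "spontaneous") {
    fx <- config$fixture
    duration <- cfg_get(config, "duration_ms", 10000)
    dt <- cfg_get(config, "dt", 0.01)
    amp <- cfg_get(config, "amplitude", 0)
    rows <- lapply(seq_along(backends), function(i) {
      r <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                              stim_dc(amp), duration, dt,
                              backend = backends[i],
                              seed = derive_seed(seed, i),
                              record_every = cfg_get(config, "record_every",
                                                     5L))
      st <- isi_statistics(r$spikes, duration)
      data.frame(backend = backends[i], rate_hz = st$rate_hz, cv = st$cv,
                 n_spikes = st$n_spikes)
    })
    return(do.call(rbind, rows))
  }
  if (experiment == "fi") {
    rows <- lapply(seq_along(backends), function(i) {
      cfg <- config
      cfg$backend <- backends[i]
      cfg$seed <- derive_seed(seed, i * 10000L)
      protocol_fi_curve(cfg)
    })
    return(do.call(rbind, rows))
  }
  out <- lapply(seq_along(backends), function(i) {
    cfg <- config
    cfg$backend <- backends[i]
    cfg$seed <- derive_seed(seed, i * 100000L)
    switch(experiment,
           pulse_response = protocol_pulse_trials(cfg),
           reliability = protocol_reliability_trials(cfg),
           psd = protocol_psd_recording(cfg))
  })
  names(out) <- backends
  out
}
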