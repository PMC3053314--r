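#' Passive membrane parameters
#'
#' @param c_m specific membrane capacitance (uF/cm^2, > 0).
#' @param g_leak leak conductance (mS/cm^2, >= 0).
#' @param e_leak leak reversal potential (mV).
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(c_m = 1, g_leak = 0.3, e_leak = -54.387) {
  stopifnot(c_m > 0, g_leak >= 0)
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak),
            class = "membrane_params")
}

#' Cylindrical single-compartment geometry
#'
#' Membrane area is the lateral surface `pi * d * L`, excluding end caps
#' (the convention of compartmental simulators).
#'
#' @param length_um,diameter_um cylinder dimensions (um, > 0).
#' @return object of class `cylinder_geometry` with the derived `area_um2`.
#' @export
cylinder_geometry <- function(length_um = 30, diameter_um = 30) {
  stopifnot(length_um > 0, diameter_um > 0)
  structure(list(length_um = length_um, diameter_um = diameter_um,
                 area_um2 = pi * diameter_um * length_um),
            class = "cylinder_geometry")
}

#' Stimulus waveforms
#'
#' Current-density stimuli (uA/cm^2) for current-clamp protocols:
#'
#' * `stim_dc(amplitude)` — constant current from `onset_ms` on;
#' * `stim_pulse(amplitude, onset_ms, duration_ms)` — monophasic pulse;
#' * `stim_biphasic(...)` — a preconditioning phase followed immediately by
#'   a second phase;
#' * `stim_ou(mean, sd, tau_ms, seed)` — exponentially filtered white noise
#'   (an OU process); with a fixed `seed` the same ("frozen") realisation is
#'   reproduced across trials.
#'
#' @param amplitude current density (uA/cm^2).
#' @param onset_ms stimulus onset (ms).
#' @param duration_ms phase duration (ms); `Inf` for "until the end".
#' @return object of class `stimulus`.
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_dc <- function(amplitude, onset_ms = 0) {
  structure(list(kind = "dc", amplitude = amplitude, onset_ms = onset_ms),
            class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_pulse <- function(amplitude, onset_ms, duration_ms) {
  stopifnot(duration_ms >= 0)
  structure(list(kind = "monophasic_pulse", amplitude = amplitude,
                 onset_ms = onset_ms, duration_ms = duration_ms),
            class = "stimulus")
}

#' @rdname stimulus
#' @param amplitude2,duration2_ms second-phase amplitude and duration.
#' @export
stim_biphasic <- function(amplitude, duration_ms, amplitude2, duration2_ms,
                          onset_ms = 0) {
  stopifnot(duration_ms >= 0, duration2_ms >= 0)
  structure(list(kind = "biphasic_pulse", amplitude = amplitude,
                 duration_ms = duration_ms, amplitude2 = amplitude2,
                 duration2_ms = duration2_ms, onset_ms = onset_ms),
            class = "stimulus")
}

#' @rdname stimulus
#' @param mean,sd stationary mean and SD of the OU stimulus (uA/cm^2).
#' @param tau_ms correlation time of the OU stimulus (ms).
#' @param seed optional integer seed freezing the realisation.
#' @export
stim_ou <- function(mean, sd, tau_ms, seed = NULL, onset_ms = 0) {
  stopifnot(sd >= 0, tau_ms > 0)
  structure(list(kind = "ou_noise", mean = mean, sd = sd, tau_ms = tau_ms,
                 seed = seed, onset_ms = onset_ms),
            class = "stimulus")
}

#' Realise a stimulus on a time grid
#'
#' @param stim a [stimulus] object.
#' @param nsteps number of integration steps.
#' @param dt step (ms).
#' @return numeric vector of length `nsteps` (uA/cm^2).
#' @export
build_stimulus_trace <- function(stim, nsteps, dt) {
  stopifnot(inherits(stim, "stimulus"))
  t <- (seq_len(nsteps) - 1L) * dt
  switch(stim$kind,
    dc = ifelse(t >= stim$onset_ms, stim$amplitude, 0),
    monophasic_pulse = ifelse(t >= stim$onset_ms &
                                t < stim$onset_ms + stim$duration_ms,
                              stim$amplitude, 0),
    biphasic_pulse = {
      out <- numeric(nsteps)
      t1 <- stim$onset_ms + stim$duration_ms
      out[t >= stim$onset_ms & t < t1] <- stim$amplitude
      out[t >= t1 & t < t1 + stim$duration2_ms] <- stim$amplitude2
      out
    },
    ou_noise = {
      if (!is.null(stim$seed)) {
        out <- local_seed_eval(stim$seed, {
          stim$mean + ou_simulate(stim$sd, stim$tau_ms, nsteps, dt)
        })
      } else {
        out <- stim$mean + ou_simulate(stim$sd, stim$tau_ms, nsteps, dt)
      }
      out[t < stim$onset_ms] <- 0
      out
    }
  )
}

# Evaluate expr under a private RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards.
local_seed_eval <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- force(expr)
  if (has_seed) {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

rate_law_code <- function(rl) {
  if (!inherits(rl, "rate_law")) {
    stop("membrane integration requires parametric rate laws ",
         "(see rate_law()); plain-function rates are supported only in ",
         "the kinetics and voltage-clamp paths", call. = FALSE)
  }
  c(match(rl$type, c("constant", "linexp", "exponential", "sigmoid")) - 1L,
    rl$a, rl$v_half, rl$k)
}

# Pack a channel_population into the list consumed by the C++ integrator.
pack_current <- function(pop, area_um2, v0, backend, noise_off) {
  scheme <- pop$scheme
  if (scheme$kind != "composed") {
    stop("membrane integration supports subunit-composed schemes only",
         call. = FALSE)
  }
  nsub <- length(scheme$subunits)
  rates <- t(vapply(scheme$subunits, function(s) {
    c(rate_law_code(s$rates$alpha), rate_law_code(s$rates$beta))
  }, numeric(8)))
  # pS * count / um^2 -> mS / cm^2
  g_max <- pop$gamma_ps * pop$n_channels / area_um2 * 1e-1
  gates0 <- co_gates(scheme, v0)
  out <- list(counts = co_counts(scheme), rates = rates,
              n_channels = as.numeric(pop$n_channels), g_max = g_max,
              e_rev = pop$e_rev, gates0 = as.numeric(gates0))
  if (backend == "microscopic" && !noise_off) {
    out$counts0 <- sample_stationary_counts(scheme, v0,
                                            pop$n_channels)$counts
  }
  if (backend %in% c("effective", "reduced") && !noise_off) {
    co <- effective_coefficients(scheme, v0, pop$n_channels)
    if (backend == "effective") {
      out$zeta0 <- rnorm(nrow(co)) * sqrt(co$sigma_sq)
    } else {
      out$zeta0 <- rnorm(1L) * sqrt(sum(co$sigma_sq))
    }
  } else if (backend %in% c("effective", "reduced")) {
    co <- effective_coefficients(scheme, v0, pop$n_channels)
    out$zeta0 <- numeric(if (backend == "effective") nrow(co) else 1L)
  }
  out
}

#' Deterministic resting potential
#'
#' Root of the steady-state current-balance equation with all gates at
#' steady state and no injected current.
#'
#' @param membrane a [membrane_params()].
#' @param populations list of [channel_population()].
#' @param area_um2 membrane area (um^2).
#' @param interval search interval (mV).
#' @return resting potential (mV).
#' @export
resting_potential <- function(membrane, populations, area_um2,
                              interval = c(-90, -40)) {
  g <- vapply(populations, function(p) {
    p$gamma_ps * p$n_channels / area_um2 * 1e-1
  }, numeric(1))
  f <- function(v) {
    i <- membrane$g_leak * (v - membrane$e_leak)
    for (j in seq_along(populations)) {
      scheme <- populations[[j]]$scheme
      z <- prod(co_gates(scheme, v)^co_counts(scheme))
      i <- i + g[j] * z * (v - populations[[j]]$e_rev)
    }
    i
  }
  uniroot(f, interval, tol = 1e-10)$root
}

#' Integrate the single-compartment current-balance equation
#'
#' Advances \eqn{C_m \dot V = I_{ext} - g_L(V - E_L) - \sum_c g_{max,c}
#' z_c (V - E_{rev,c})} by forward Euler, with the per-population open
#' fractions \eqn{z_c} advanced each step by the chosen channel-noise
#' backend at the instantaneous voltage:
#'
#' * `"deterministic"` — gates only (Rush-Larsen exponential update);
#' * `"microscopic"` — exact occupancy-count Monte-Carlo;
#' * `"effective"` — gates + per-term OU noise (diffusion approximation);
#' * `"reduced"` — gates + a single variance-preserving OU term;
#' * `"fox"` — Fox-Lu gating-variable Langevin.
#'
#' All backends share the same deterministic core, so with `noise_off =
#' TRUE` every backend reproduces the deterministic trajectory exactly.
#' Initial voltage defaults to the deterministic resting potential, gates
#' (or state counts) start at steady state there.
#'
#' @param membrane a [membrane_params()].
#' @param geometry a [cylinder_geometry()].
#' @param populations list of [channel_population()].
#' @param stimulus a [stimulus] object.
#' @param duration_ms simulated time (ms).
#' @param dt integration step (ms); default 0.01.
#' @param backend channel-noise backend (see above).
#' @param seed optional integer seed.
#' @param noise_off zero all noise sources.
#' @param clip clip effective/reduced open fractions to `[0, 1]` at the
#'   conductance evaluation. Default `FALSE`: clipping truncates the
#'   Gaussian conductance fluctuations and measurably depresses
#'   noise-assisted firing at realistic channel counts, while the rare
#'   unclipped negative excursions are far too small to destabilise the
#'   integration. Set `TRUE` to guarantee non-negative conductances; the
#'   policy used is recorded in the result metadata.
#' @param record_every record every k-th sample.
#' @param v0 initial voltage (mV); default: deterministic resting
#'   potential.
#' @param spike_threshold,spike_refractory_ms spike-detection parameters
#'   passed to [detect_spikes()].
#' @return object of class `simulation_result`: list with `time` (ms), `v`
#'   (mV), `z` (matrix, one column per population), `spikes` (ms), and
#'   `metadata` (all resolved parameters).
#' @export
integrate_membrane <- function(membrane, geometry, populations, stimulus,
                               duration_ms, dt = 0.01,
                               backend = c("deterministic", "microscopic",
                                           "effective", "reduced", "fox"),
                               seed = NULL, noise_off = FALSE, clip = FALSE,
                               record_every = 1L, v0 = NULL,
                               spike_threshold = 0,
                               spike_refractory_ms = 2) {
  backend <- match.arg(backend)
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(geometry, "cylinder_geometry"),
            length(populations) >= 1L, duration_ms > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(v0)) {
    v0 <- resting_potential(membrane, populations, geometry$area_um2)
  }
  nsteps <- floor(duration_ms / dt)
  stim <- build_stimulus_trace(stimulus, nsteps, dt)
  if (backend == "microscopic" && !noise_off) {
    for (pop in populations) {
      A <- transition_matrix(pop$scheme, 60) # fastest kinetics near spikes
      if (max(-diag(A)) * dt >= 0.5) {
        stop("dt too large for microscopic stepping at depolarised ",
             "voltages", call. = FALSE)
      }
    }
  }
  cl <- lapply(populations, pack_current, area_um2 = geometry$area_um2,
               v0 = v0, backend = backend, noise_off = noise_off)
  bid <- match(backend, c("deterministic", "microscopic", "effective",
                          "reduced", "fox")) - 1L
  res <- cpp_integrate_membrane(membrane$c_m, membrane$g_leak,
                                membrane$e_leak, cl, stim, dt, bid, v0,
                                noise_off, clip, as.integer(record_every))
  dtr <- dt * record_every
  time <- seq_len(length(res$v)) * dtr - dtr
  spikes <- detect_spikes(res$v, dtr, threshold = spike_threshold,
                          refractory_ms = spike_refractory_ms)
  colnames(res$z) <- vapply(populations, `[[`, character(1), "name")
  structure(list(time = time, v = res$v, z = res$z, spikes = spikes,
                 metadata = list(backend = backend, seed = seed, dt = dt,
                                 record_every = record_every,
                                 duration_ms = duration_ms,
                                 noise_off = noise_off,
                                 clip = if (clip) "conductance" else "none",
                                 v0 = v0, stimulus = unclass(stimulus),
                                 area_um2 = geometry$area_um2,
                                 n_channels = vapply(populations, `[[`,
                                                     integer(1),
                                                     "n_channels"))),
            class = "simulation_result")
}

#' Deterministic rheobase of a fixture
#'
#' Minimal DC current density sustaining repetitive deterministic firing,
#' found by bisection on the spike count in the second half of a trial.
#'
#' @param fixture an [build_hh_fixture()] result.
#' @param interval bracketing interval (uA/cm^2).
#' @param duration_ms trial length per probe (ms).
#' @param dt integration step (ms).
#' @param tol bisection tolerance (uA/cm^2).
#' @return rheobase estimate (uA/cm^2).
#' @export
find_rheobase <- function(fixture, interval = c(1, 20), duration_ms = 600,
                          dt = 0.01, tol = 0.05) {
  fires <- function(amp) {
    r <- integrate_membrane(fixture$membrane, fixture$geometry,
                            fixture$populations, stim_dc(amp),
                            duration_ms, dt, backend = "deterministic")
    sum(r$spikes > duration_ms / 2) >= 3
  }
  lo <- interval[1]
  hi <- interval[2]
  if (fires(lo) || !fires(hi)) {
    stop("rheobase not bracketed by the search interval", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
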