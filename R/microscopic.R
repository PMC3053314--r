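#' A population of identical stochastic channels
#'
#' Binds a kinetic scheme to a population size, single-channel conductance
#' and reversal potential. The population size is either given directly or
#' derived from an areal density as `round(density * area)` (round half to
#' even, for determinism).
#'
#' @param scheme a [channel_scheme()].
#' @param n_channels population size N (>= 1); alternatively supply
#'   `density_um2` and `area_um2`.
#' @param density_um2 channel density (1/um^2).
#' @param area_um2 membrane area (um^2).
#' @param gamma_ps single-channel conductance (pS, > 0).
#' @param e_rev reversal potential (mV).
#' @param name label used in outputs.
#' @return object of class `channel_population`.
#' @export
channel_population <- function(scheme, n_channels = NULL, density_um2 = NULL,
                               area_um2 = NULL, gamma_ps = 20, e_rev = 0,
                               name = "current") {
  stopifnot(inherits(scheme, "channel_scheme"), gamma_ps > 0)
  if (is.null(n_channels)) {
    stopifnot(!is.null(density_um2), !is.null(area_um2),
              density_um2 > 0, area_um2 > 0)
    n_channels <- round(density_um2 * area_um2)
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("population must contain at least one channel", call. = FALSE)
  }
  structure(list(scheme = scheme, n_channels = n_channels,
                 gamma_ps = gamma_ps, e_rev = e_rev, name = name,
                 density_um2 = density_um2, area_um2 = area_um2),
            class = "channel_population")
}

#' Occupancy-count state of a channel population
#'
#' @param counts integer occupancy per scheme state; must sum to
#'   `n_channels` and be non-negative.
#' @param n_channels population size.
#' @return object of class `population_state`.
#' @export
population_state <- function(counts, n_channels = sum(counts)) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 0L), sum(counts) == n_channels)
  structure(list(counts = counts, n_channels = as.integer(n_channels)),
            class = "population_state")
}

#' Sample stationary occupancy counts
#'
#' Draws the initial per-state occupancy from a multinomial over the
#' stationary distribution of the scheme at the given gating point.
#'
#' @param scheme a [channel_scheme()].
#' @param v gating-variable value.
#' @param n_channels population size.
#' @return a [population_state()].
#' @export
sample_stationary_counts <- function(scheme, v, n_channels) {
  p <- stationary_distribution(transition_matrix(scheme, v))
  population_state(as.integer(rmultinom(1L, n_channels, p)), n_channels)
}

#' Advance a channel population by one Monte-Carlo step
#'
#' For each state `s` with occupancy `n_s`, the numbers of channels leaving
#' towards each neighbouring state within `dt` are drawn from the
#' multinomial with per-destination probabilities `rate(s -> s') * dt`
#' (realised as sequential conditional binomials). Channel count is
#' conserved exactly. Statistically identical to per-channel uniform draws
#' for independent channels, but the cost scales with the number of states,
#' not channels.
#'
#' @param state a [population_state()].
#' @param A transition-rate matrix at the current gating point (see
#'   [transition_matrix()]).
#' @param dt time step (ms). For every state the total exit probability
#'   `sum(outgoing rates) * dt` must stay below 1; an error names the
#'   offending state otherwise.
#' @return the updated [population_state()].
#' @export
step_population <- function(state, A, dt) {
  stopifnot(inherits(state, "population_state"), is.matrix(A),
            nrow(A) == length(state$counts), dt > 0)
  exit <- -diag(A) * dt
  if (any(exit >= 1)) {
    stop("time step too large: state ", which.max(exit),
         " has total exit probability ", signif(max(exit), 3),
         " >= 1", call. = FALSE)
  }
  M <- nrow(A)
  counts <- state$counts
  moved <- integer(M)
  for (s in seq_len(M)) {
    n_s <- counts[s]
    if (n_s == 0L) next
    dests <- which(A[, s] > 0 & seq_len(M) != s)
    if (!length(dests)) next
    rem <- n_s
    acc <- 0
    for (d in dests) {
      p <- A[d, s] * dt
      cond <- p / (1 - acc)
      b <- rbinom(1L, rem, min(1, cond))
      moved[d] <- moved[d] + b
      moved[s] <- moved[s] - b
      rem <- rem - b
      acc <- acc + p
      if (rem == 0L) break
    }
  }
  population_state(counts + moved, state$n_channels)
}

#' Fraction of channels in the conducting state
#'
#' @param state a [population_state()].
#' @param scheme the [channel_scheme()] the counts refer to.
#' @return `z` in `[0, 1]`.
#' @export
open_fraction <- function(state, scheme) {
  stopifnot(inherits(state, "population_state"))
  state$counts[open_state_index(scheme)] / state$n_channels
}

#' Voltage-clamp simulation of a channel population
#'
#' Holds the gating variable fixed and records the open fraction `z` at
#' every `record_every`-th step after a burn-in, under one of the
#' channel-noise backends:
#'
#' * `"microscopic"`: exact occupancy-count Monte-Carlo (any scheme; the
#'   rate matrix is constant under clamp). Initial occupancy is a
#'   multinomial draw from the stationary distribution.
#' * `"effective"`: `z = p_open + sum_i zeta_i` with one exact-update OU
#'   process per noise-spectrum term.
#' * `"reduced"`: single OU term from [reduce_to_single_term()].
#' * `"fox"`: per-subunit gating-variable Langevin dynamics (composed
#'   schemes only), `z` the product of gate powers.
#'
#' @param pop a [channel_population()].
#' @param v_hold holding value of the gating variable (mV).
#' @param duration total simulated time (ms), burn-in included.
#' @param dt time step (ms). The microscopic backend requires the maximal
#'   total exit probability per step to stay below 0.1.
#' @param backend one of `"microscopic"`, `"effective"`, `"reduced"`,
#'   `"fox"`.
#' @param burn_in initial stretch discarded from the output (ms).
#' @param record_every record every k-th step (thinning).
#' @param seed optional integer seed (applied via `set.seed`).
#' @param reduce_method `"taylor"` or `"best_fit"` (reduced backend).
#' @param clip for `"effective"`/`"reduced"`: clip recorded `z` to `[0,1]`
#'   (`TRUE`) or return the unclipped Gaussian process (`FALSE`, default —
#'   the diffusion approximation's statistics are exact only unclipped).
#' @return data frame with columns `time` (ms) and `z`, with attributes
#'   `backend`, `dt`, `v_hold`, `n_channels`, `seed`, `clip`.
#' @export
run_voltage_clamp <- function(pop, v_hold, duration, dt = 0.01,
                              backend = c("microscopic", "effective",
                                          "reduced", "fox"),
                              burn_in = 0, record_every = 1L, seed = NULL,
                              reduce_method = "taylor", clip = FALSE) {
  stopifnot(inherits(pop, "channel_population"), duration > burn_in, dt > 0)
  backend <- match.arg(backend)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- floor(duration / dt)
  nburn <- floor(burn_in / dt)
  scheme <- pop$scheme
  N <- pop$n_channels

  z <- switch(backend,
    microscopic = {
      A <- transition_matrix(scheme, v_hold)
      maxexit <- max(-diag(A)) * dt
      if (maxexit >= 0.1) {
        stop("time step too large for microscopic accuracy: state ",
             which.max(-diag(A)), " has exit probability ",
             signif(maxexit, 3), " per step (limit 0.1)", call. = FALSE)
      }
      counts0 <- sample_stationary_counts(scheme, v_hold, N)$counts
      cpp_vclamp_micro(A, open_state_index(scheme) - 1L, counts0,
                       nsteps, dt, as.integer(record_every))
    },
    effective = ,
    reduced = {
      sp <- covariance_spectrum(scheme, v_hold, N)
      if (backend == "reduced") {
        r <- reduce_to_single_term(sp, method = reduce_method)
        sp <- noise_spectrum(r$sigma_sq, r$tau, N, attr(sp, "p_open"))
      }
      nrec <- nsteps %/% record_every + 1L
      zdet <- attr(sp, "p_open")
      zz <- rep(zdet, nrec)
      dtr <- dt * record_every
      for (i in seq_len(nrow(sp))) {
        zz <- zz + ou_simulate(sqrt(sp$sigma_sq[i]), sp$tau[i], nrec, dtr)
      }
      if (clip) zz <- pmin(pmax(zz, 0), 1)
      zz
    },
    fox = {
      if (scheme$kind != "composed") {
        stop("the fox backend requires a subunit-composed scheme",
             call. = FALSE)
      }
      gates <- lapply(scheme$subunits, function(s) {
        ss <- subunit_steady_state(s$rates, v_hold)
        a <- eval_rate(s$rates$alpha, v_hold)
        b <- eval_rate(s$rates$beta, v_hold)
        cpp_fox_gate_clamp(a, b, N, ss$x_inf, nsteps, dt,
                           as.integer(record_every))
      })
      counts <- vapply(scheme$subunits, `[[`, integer(1), "count")
      zz <- rep(1, nsteps %/% record_every + 1L)
      for (j in seq_along(gates)) zz <- zz * gates[[j]]^counts[j]
      zz
    }
  )
  tgrid <- seq(0L, nsteps %/% record_every) * (dt * record_every)
  keep <- tgrid >= burn_in
  out <- data.frame(time = tgrid[keep], z = z[keep])
  attr(out, "backend") <- backend
  attr(out, "dt") <- dt
  attr(out, "v_hold") <- v_hold
  attr(out, "n_channels") <- N
  attr(out, "seed") <- seed
  attr(out, "clip") <- clip
  out
}
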