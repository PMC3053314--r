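#' Effective (diffusion-approximation) channel-population state
#'
#' The effective model replaces the occupancy counts of a composed scheme by
#' deterministic subunit gates \eqn{x_j} plus one zero-mean OU process
#' \eqn{\zeta_i} per noise-spectrum term; the stochastic open fraction is
#' \eqn{z = \prod_j x_j^{q_j} + \sum_i \zeta_i}. With every
#' \eqn{\sigma_i = 0} the deterministic description is recovered exactly.
#'
#' @param scheme a composed [channel_scheme()].
#' @param v initial gating-variable value; gates start at steady state,
#'   noise terms at a stationary draw.
#' @param n_channels population size N used for the noise scaling.
#' @param reduced if `TRUE`, use a single OU term (see
#'   [reduce_to_single_term()]).
#' @param reduce_method `"taylor"` or `"best_fit"` when `reduced`.
#' @return object of class `effective_channel_state` with fields `gates`
#'   (named numeric), `noise` (data frame `value`, `sigma`, `tau`, one row
#'   per term, in fixed exponent-grid order), and `z_det`.
#' @export
effective_channel_state <- function(scheme, v, n_channels, reduced = FALSE,
                                    reduce_method = "taylor") {
  stopifnot(inherits(scheme, "channel_scheme"), scheme$kind == "composed")
  co <- effective_coefficients(scheme, v, n_channels)
  if (reduced) {
    sp <- covariance_spectrum(scheme, v, n_channels)
    r <- reduce_to_single_term(sp, method = reduce_method)
    noise <- data.frame(value = rnorm(1L) * sqrt(r$sigma_sq),
                        sigma = sqrt(r$sigma_sq), tau = r$tau)
  } else {
    noise <- data.frame(value = rnorm(nrow(co)) * sqrt(co$sigma_sq),
                        sigma = sqrt(co$sigma_sq), tau = co$tau)
  }
  structure(list(gates = co_gates(scheme, v), noise = noise,
                 z_det = prod(co_gates(scheme, v)^co_counts(scheme)),
                 reduced = reduced, reduce_method = reduce_method),
            class = "effective_channel_state")
}

co_counts <- function(scheme) {
  vapply(scheme$subunits, `[[`, integer(1), "count")
}

co_gates <- function(scheme, v) {
  x <- vapply(scheme$subunits,
              function(s) subunit_steady_state(s$rates, v)$x_inf,
              numeric(1))
  names(x) <- vapply(scheme$subunits, `[[`, character(1), "name")
  x
}

# Noise-term coefficients of a composed scheme at one gating point, in the
# fixed exponent-grid order (stable across voltages, unlike the canonical
# sorted order of noise_spectrum(), so OU terms keep their identity while
# the voltage moves).
effective_coefficients <- function(scheme, v, n_channels) {
  ss <- lapply(scheme$subunits, function(s) subunit_steady_state(s$rates, v))
  x <- vapply(ss, `[[`, numeric(1), "x_inf")
  taux <- vapply(ss, `[[`, numeric(1), "tau")
  counts <- co_counts(scheme)
  grid <- as.matrix(expand.grid(lapply(counts, function(q) 0:q),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  sigma_sq <- apply(grid, 1L, function(k) {
    prod(choose(counts, k) * x^(2 * (counts - k)) * (x * (1 - x))^k)
  }) / n_channels
  data.frame(sigma_sq = sigma_sq,
             tau = 1 / as.numeric(grid %*% (1 / taux)))
}

#' Advance an effective channel population by one step
#'
#' Deterministic gates are advanced by the exponential (Rush-Larsen) update
#' \eqn{x \leftarrow x_\infty + (x - x_\infty) e^{-dt/\tau_x}} (exact for
#' frozen gating variable, unconditionally stable). Each OU term's
#' \eqn{(\sigma_i, \tau_i)} is refreshed from the instantaneous gating point
#' — the slow-gating assumption of the diffusion approximation — and then
#' stepped with the exact OU update.
#'
#' @param state an [effective_channel_state()].
#' @param scheme the composed [channel_scheme()].
#' @param v instantaneous gating-variable value.
#' @param n_channels population size.
#' @param dt time step (ms, > 0).
#' @param noise_off force all `sigma_i` to zero (the trajectory is then the
#'   deterministic model exactly).
#' @return the updated state.
#' @export
step_effective_channels <- function(state, scheme, v, n_channels, dt,
                                    noise_off = FALSE) {
  stopifnot(inherits(state, "effective_channel_state"), dt > 0)
  ss <- lapply(scheme$subunits, function(s) subunit_steady_state(s$rates, v))
  xinf <- vapply(ss, `[[`, numeric(1), "x_inf")
  taux <- vapply(ss, `[[`, numeric(1), "tau")
  state$gates <- xinf + (state$gates - xinf) * exp(-dt / taux)
  if (state$reduced) {
    sp <- covariance_spectrum(scheme, v, n_channels)
    r <- reduce_to_single_term(sp, method = state$reduce_method)
    sig <- sqrt(r$sigma_sq)
    tau <- r$tau
  } else {
    co <- effective_coefficients(scheme, v, n_channels)
    sig <- sqrt(co$sigma_sq)
    tau <- co$tau
  }
  if (noise_off) sig[] <- 0
  e <- exp(-dt / tau)
  state$noise$value <- state$noise$value * e +
    sig * sqrt(1 - e * e) * rnorm(length(e))
  state$noise$sigma <- sig
  state$noise$tau <- tau
  state$z_det <- prod(state$gates^co_counts(scheme))
  state
}

#' Stochastic open fraction of an effective state
#'
#' `z = z_det + sum(zeta_i)`, optionally clipped to `[0, 1]` at the point of
#' conductance evaluation (the state variables are never modified, so the OU
#' statistics are preserved).
#'
#' @param state an [effective_channel_state()].
#' @param clip `"conductance"` (clip the returned value, default) or
#'   `"none"`.
#' @return `z`, the effective fraction of open channels.
#' @export
effective_open_fraction <- function(state, clip = c("conductance", "none")) {
  clip <- match.arg(clip)
  z <- state$z_det + sum(state$noise$value)
  if (clip == "conductance") z <- min(max(z, 0), 1)
  z
}
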