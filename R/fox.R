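#' Fox-Lu Langevin comparator state
#'
#' In the classical Langevin treatment of channel noise (Fox & Lu 1994; Fox
#' 1997) each gating variable keeps its deterministic ODE and receives a
#' single additive white-noise term:
#' \deqn{dx = [\alpha_x(1-x) - \beta_x x]\,dt + \xi_x(t)\,dt,}
#' where \eqn{\xi_x} is Gaussian, zero-mean and white with covariance
#' \deqn{\langle \xi_x(t)\,\xi_x(t')\rangle =
#'   \frac{\alpha_x (1-x) + \beta_x x}{N}\,\delta(t-t'),}
#' `N` being the number of channels carrying the current. Conductances are
#' then formed from the gate products (`m^3 h`, `n^4`) exactly as in the
#' deterministic model. At a fixed gating point a single gate has stationary
#' variance \eqn{x_\infty(1-x_\infty)/N} — identical to the 2-state
#' diffusion approximation — but the *powers and products* of gates do not
#' reproduce the open-fraction statistics of multi-subunit channels: the
#' variance of `n^4` is overestimated and that of `m^3 h` underestimated,
#' with mismatched autocorrelation, which is what the effective backend
#' corrects.
#'
#' @param scheme a composed [channel_scheme()].
#' @param v initial gating value; gates start at steady state.
#' @return object of class `fox_state`: named gate vector in `[0, 1]`.
#' @export
fox_state <- function(scheme, v) {
  stopifnot(inherits(scheme, "channel_scheme"), scheme$kind == "composed")
  structure(list(gates = co_gates(scheme, v)), class = "fox_state")
}

#' Advance a Fox-Lu state by one step
#'
#' The deterministic drift is integrated with the same exponential
#' (Rush-Larsen) update as every other backend; the white-noise increment
#' `sqrt(dt * (alpha (1 - x) + beta x) / N) * xi` is then added and the gate
#' clipped back to `[0, 1]` (the noise can push it out of range).
#'
#' @param state a [fox_state()].
#' @param scheme the composed [channel_scheme()].
#' @param v instantaneous gating-variable value.
#' @param n_channels number of channels carrying the current.
#' @param dt time step (ms); should be small against the gate time
#'   constants.
#' @param noise_off suppress the noise increment (deterministic limit,
#'   equivalently N -> Inf).
#' @return the updated state.
#' @export
step_fox <- function(state, scheme, v, n_channels, dt, noise_off = FALSE) {
  stopifnot(inherits(state, "fox_state"), dt > 0)
  x <- state$gates
  for (j in seq_along(scheme$subunits)) {
    s <- scheme$subunits[[j]]
    a <- eval_rate(s$rates$alpha, v)
    b <- eval_rate(s$rates$beta, v)
    xinf <- a / (a + b)
    x[j] <- xinf + (x[j] - xinf) * exp(-dt * (a + b))
    if (!noise_off) {
      # Fox (1997): white-noise covariance (alpha (1 - x) + beta x) / N
      x[j] <- x[j] +
        sqrt(dt * (a * (1 - x[j]) + b * x[j]) / n_channels) * rnorm(1L)
      x[j] <- min(max(x[j], 0), 1)
    }
  }
  state$gates <- x
  state
}

#' Open fraction of a Fox-Lu state
#'
#' @param state a [fox_state()].
#' @param scheme the composed [channel_scheme()].
#' @return product of gate powers, in `[0, 1]`.
#' @export
fox_open_fraction <- function(state, scheme) {
  prod(state$gates^co_counts(scheme))
}
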