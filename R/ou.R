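#' Ornstein-Uhlenbeck process state
#'
#' A zero-mean OU process with stationary standard deviation `sigma` and
#' autocorrelation time `tau`; its stationary autocovariance is
#' \eqn{\sigma^2 e^{-t/\tau}}. These processes are the building blocks of
#' the effective channel-noise terms.
#'
#' @param value current sample (default: a draw from the stationary law).
#' @param sigma stationary standard deviation (>= 0).
#' @param tau autocorrelation time constant (ms, > 0).
#' @return object of class `ou_process`.
#' @export
ou_process <- function(sigma, tau, value = NULL) {
  stopifnot(is.numeric(sigma), sigma >= 0, is.numeric(tau), tau > 0)
  if (is.null(value)) value <- rnorm(1L) * sigma
  structure(list(value = value, sigma = sigma, tau = tau),
            class = "ou_process")
}

#' Advance an OU process by one time step
#'
#' `ou_step_exact()` uses the exact conditional law of the OU process,
#' \deqn{x(t+\Delta t) = x(t)\,e^{-\Delta t/\tau} +
#'   \sigma\sqrt{1 - e^{-2\Delta t/\tau}}\;\xi,\qquad \xi \sim N(0,1),}
#' which is distributionally exact for *any* step size (the step needs to be
#' neither uniform nor small). `ou_step_euler()` is the first-order
#' Euler-Maruyama version,
#' \deqn{x(t+\Delta t) = x(t)(1 - \Delta t/\tau) +
#'   \sigma\sqrt{2\Delta t/\tau}\;\xi,}
#' accurate only for \eqn{\Delta t \ll \tau}; it warns when
#' `dt > 0.1 * tau`.
#'
#' @param p an [ou_process()].
#' @param dt time step (ms, >= 0).
#' @return the updated `ou_process`.
#' @export
ou_step_exact <- function(p, dt) {
  stopifnot(inherits(p, "ou_process"), dt >= 0)
  if (dt == 0) return(p)
  e <- exp(-dt / p$tau)
  p$value <- p$value * e + p$sigma * sqrt(1 - e * e) * rnorm(1L)
  p
}

#' @rdname ou_step_exact
#' @export
ou_step_euler <- function(p, dt) {
  stopifnot(inherits(p, "ou_process"), dt >= 0)
  if (dt == 0) return(p)
  if (dt > 0.1 * p$tau) {
    warning("Euler OU update with dt > 0.1 * tau is inaccurate; ",
            "use ou_step_exact()", call. = FALSE)
  }
  p$value <- p$value * (1 - dt / p$tau) +
    p$sigma * sqrt(2 * dt / p$tau) * rnorm(1L)
  p
}

#' Simulate an OU sample path
#'
#' Generates `n` consecutive samples spaced `dt` apart, starting from a
#' stationary draw (or `init`). Both updates are linear AR(1) recursions, so
#' the whole path is produced by a recursive filter.
#'
#' @param sigma,tau stationary SD and time constant (ms).
#' @param n number of samples.
#' @param dt sampling step (ms).
#' @param method `"exact"` or `"euler"`.
#' @param init optional initial value (defaults to a stationary draw).
#' @return numeric vector of length `n`.
#' @export
ou_simulate <- function(sigma, tau, n, dt, method = c("exact", "euler"),
                        init = NULL) {
  method <- match.arg(method)
  stopifnot(sigma >= 0, tau > 0, n >= 1, dt > 0)
  if (is.null(init)) init <- rnorm(1L) * sigma
  if (method == "exact") {
    a <- exp(-dt / tau)
    s <- sigma * sqrt(1 - a * a)
  } else {
    a <- 1 - dt / tau
    s <- sigma * sqrt(2 * dt / tau)
  }
  as.numeric(stats::filter(rnorm(n) * s, a, method = "recursive",
                           init = init))
}
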