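#' Parametric voltage-dependent rate laws
#'
#' Transition rates of Markov channel models are smooth functions of the
#' gating variable (membrane potential, ligand concentration, ...). Four
#' parametric families cover the classical Hodgkin-Huxley rate expressions:
#'
#' * `"constant"`: \eqn{a}
#' * `"linexp"`: \eqn{a (v - v_{1/2}) / (1 - e^{-(v - v_{1/2})/k})}
#' * `"exponential"`: \eqn{a\, e^{(v - v_{1/2})/k}}
#' * `"sigmoid"`: \eqn{a / (1 + e^{-(v - v_{1/2})/k})}
#'
#' The `"linexp"` family has a removable singularity at \eqn{v = v_{1/2}}
#' (0/0); it is evaluated there by its analytic limit \eqn{a k}, with a
#' guarded series expansion in a narrow window around the singular voltage so
#' no `NaN` can be produced.
#'
#' Rates are in 1/ms, voltages in mV.
#'
#' @param type one of `"constant"`, `"linexp"`, `"exponential"`, `"sigmoid"`.
#' @param a rate amplitude (1/ms; for `"linexp"`, 1/ms/mV).
#' @param v_half half-point / reference voltage (mV). Ignored for
#'   `"constant"`.
#' @param k slope factor (mV); may be negative for decaying exponentials.
#' @return an object of class `rate_law`, callable via [eval_rate()].
#' @seealso [rate_pair()], [hh_rate_laws()]
#' @export
#' @examples
#' am <- rate_law("linexp", a = 0.1, v_half = -40, k = 10)
#' eval_rate(am, c(-80, -40, 0)) # finite at the removable singularity
rate_law <- function(type = c("constant", "linexp", "exponential", "sigmoid"),
                     a, v_half = 0, k = 1) {
  type <- match.arg(type)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(v_half), length(v_half) == 1L,
            is.numeric(k), length(k) == 1L, k != 0 || type == "constant")
  structure(list(type = type, a = a, v_half = v_half, k = k),
            class = "rate_law")
}

#' Evaluate a rate at one or more gating-variable values
#'
#' @param rate a [rate_law()] object or a plain R function of the gating
#'   variable (used for general schemes).
#' @param v gating-variable values (mV for voltage-gated channels).
#' @return numeric vector of rates (1/ms), finite and non-negative.
#' @export
eval_rate <- function(rate, v) {
  if (is.function(rate)) {
    r <- rate(v)
  } else if (inherits(rate, "rate_law")) {
    r <- switch(rate$type,
      constant = rep.int(rate$a, length(v)),
      linexp = {
        u <- (v - rate$v_half) / rate$k
        out <- numeric(length(u))
        small <- abs(u) < 1e-6
        # series of u / (1 - exp(-u)) about u = 0
        out[small] <- rate$a * rate$k *
          (1 + u[small] / 2 + u[small]^2 / 12)
        out[!small] <- rate$a * rate$k * u[!small] / (1 - exp(-u[!small]))
        out
      },
      exponential = rate$a * exp((v - rate$v_half) / rate$k),
      sigmoid = rate$a / (1 + exp(-(v - rate$v_half) / rate$k))
    )
  } else {
    stop("`rate` must be a rate_law or a function", call. = FALSE)
  }
  if (any(!is.finite(r))) {
    stop("rate evaluates to a non-finite value on the requested domain",
         call. = FALSE)
  }
  if (any(r < 0)) stop("negative rate encountered", call. = FALSE)
  r
}

#' Forward/backward rate pair of a two-state gate
#'
#' A 2-state gating mechanism (closed <-> open) is specified by its opening
#' rate `alpha` and closing rate `beta`, both functions of the gating
#' variable.
#'
#' @param alpha,beta [rate_law()] objects or functions of the gating
#'   variable, returning non-negative finite rates (1/ms).
#' @return an object of class `rate_pair`.
#' @export
rate_pair <- function(alpha, beta) {
  for (r in list(alpha, beta)) {
    if (!(is.function(r) || inherits(r, "rate_law"))) {
      stop("alpha and beta must be rate_law objects or functions",
           call. = FALSE)
    }
  }
  structure(list(alpha = alpha, beta = beta), class = "rate_pair")
}

#' Steady state and relaxation time of a two-state gate
#'
#' For opening rate \eqn{\alpha} and closing rate \eqn{\beta} the occupancy
#' of the active state relaxes exponentially towards
#' \eqn{x_\infty = \alpha/(\alpha+\beta)} with time constant
#' \eqn{\tau_x = 1/(\alpha+\beta)}.
#'
#' @param rates a [rate_pair()].
#' @param v gating-variable value(s).
#' @return list with numeric fields `x_inf` (probability) and `tau` (ms),
#'   each the length of `v`.
#' @export
#' @examples
#' rp <- rate_pair(rate_law("constant", 3), rate_law("constant", 1))
#' subunit_steady_state(rp, 0) # x_inf = 0.75, tau = 0.25 ms
subunit_steady_state <- function(rates, v) {
  stopifnot(inherits(rates, "rate_pair"))
  a <- eval_rate(rates$alpha, v)
  b <- eval_rate(rates$beta, v)
  s <- a + b
  if (any(s <= 0)) {
    stop("degenerate kinetics: alpha + beta = 0, no stationary relaxation",
         call. = FALSE)
  }
  list(x_inf = a / s, tau = 1 / s)
}
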