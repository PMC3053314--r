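#' Noise spectrum of a channel population's open fraction
#'
#' At a fixed gating point the fraction of open channels `z` of a population
#' of `N` independent M-state channels is a stationary stochastic process
#' with mean `p_open` (the stationary occupancy of the conducting state) and
#' autocovariance a weighted sum of `M - 1` decaying exponentials,
#' \deqn{C(t) = \sum_i \sigma_i^2 e^{-t/\tau_i},}
#' where \eqn{\sum_i \sigma_i^2 = p_{open}(1 - p_{open})/N} (the binomial
#' stationary variance). The set of pairs \eqn{\{\sigma_i^2, \tau_i\}} is the
#' *noise spectrum*: it is exactly the data needed to drive one
#' Ornstein-Uhlenbeck process per term in the effective (diffusion)
#' approximation.
#'
#' `noise_spectrum()` is the low-level constructor; use
#' [covariance_spectrum()] to derive a spectrum from a scheme.
#'
#' @param sigma_sq non-negative variance contributions.
#' @param tau positive autocorrelation time constants (ms).
#' @param n_channels population size used for the 1/N scaling.
#' @param p_open stationary open probability (stored for checks).
#' @return object of class `noise_spectrum`: a data frame with columns
#'   `sigma_sq` and `tau` in canonical order (decreasing `tau`, ties broken
#'   by decreasing `sigma_sq`), with attributes `n_channels` and `p_open`.
#' @export
noise_spectrum <- function(sigma_sq, tau, n_channels, p_open = NA_real_) {
  stopifnot(length(sigma_sq) == length(tau), length(sigma_sq) >= 1L,
            all(is.finite(sigma_sq)), all(is.finite(tau)), all(tau > 0))
  if (any(sigma_sq < 0)) {
    if (min(sigma_sq) < -1e-12 * max(sum(sigma_sq), .Machine$double.eps)) {
      stop("negative variance contribution in noise spectrum", call. = FALSE)
    }
    sigma_sq <- pmax(sigma_sq, 0)
  }
  o <- order(-tau, -sigma_sq)
  out <- data.frame(sigma_sq = sigma_sq[o], tau = tau[o])
  structure(out, class = c("noise_spectrum", "data.frame"),
            n_channels = n_channels, p_open = p_open)
}

# Merge terms with numerically identical tau, drop negligible terms
# (sigma_sq < 1e-15 * total), keep canonical order.
canonicalize_spectrum <- function(sp, merge_tol = 1e-8, drop = TRUE) {
  tot <- sum(sp$sigma_sq)
  if (nrow(sp) > 1L) {
    keep_s <- numeric(0)
    keep_t <- numeric(0)
    for (i in seq_len(nrow(sp))) {
      j <- which(abs(keep_t - sp$tau[i]) <= merge_tol * sp$tau[i])
      if (length(j) == 1L) {
        keep_s[j] <- keep_s[j] + sp$sigma_sq[i]
      } else {
        keep_s <- c(keep_s, sp$sigma_sq[i])
        keep_t <- c(keep_t, sp$tau[i])
      }
    }
    sp <- noise_spectrum(keep_s, keep_t, attr(sp, "n_channels"),
                         attr(sp, "p_open"))
  }
  if (drop && tot > 0) {
    keep <- sp$sigma_sq >= 1e-15 * tot
    if (!all(keep) && any(keep)) {
      sp <- noise_spectrum(sp$sigma_sq[keep], sp$tau[keep],
                           attr(sp, "n_channels"), attr(sp, "p_open"))
    }
  }
  sp
}

#' Analytic open-fraction covariance spectrum of a scheme
#'
#' Derives the \eqn{\{\sigma_i^2, \tau_i\}} pairs of the stationary
#' autocovariance of the open fraction at a fixed gating point.
#'
#' For *composed* schemes the autocovariance of the conducting indicator is
#' the product of the per-subunit 2-state autocovariances,
#' \deqn{C(t) = \frac{1}{N}\Big[\prod_j \big(x_{\infty,j}^2 +
#'   x_{\infty,j}(1-x_{\infty,j}) e^{-t/\tau_j}\big)^{q_j} -
#'   \prod_j x_{\infty,j}^{2 q_j}\Big],}
#' which is expanded multinomially: each term is indexed by how many factors
#' \eqn{k_j \le q_j} of each subunit type contribute their exponential part,
#' giving
#' \deqn{\sigma_{(k)}^2 = \frac{1}{N} \prod_j \binom{q_j}{k_j}
#'   x_{\infty,j}^{2(q_j-k_j)}\,[x_{\infty,j}(1-x_{\infty,j})]^{k_j},
#'   \qquad 1/\tau_{(k)} = \sum_j k_j/\tau_j.}
#' The sodium `m^3 h` scheme yields 7 terms, the potassium `n^4` scheme 4
#' terms with time constants \eqn{\tau_n/\{1,2,3,4\}}.
#'
#' For *general* schemes the spectrum comes from the eigendecomposition of
#' the rate matrix `A`: with right eigenvectors `V` and stationary open
#' probability `p`, the conducting-state autocovariance is
#' \eqn{C(t) = \frac{p}{N}\sum_{\lambda_i \ne 0} V_{oi}(V^{-1})_{io}
#' e^{\lambda_i t}}, so \eqn{\tau_i = 1/|\lambda_i|} and
#' \eqn{\sigma_i^2 = p\,V_{oi}(V^{-1})_{io}/N}. Schemes with genuinely
#' complex eigenvalues (oscillatory relaxation) are rejected rather than
#' silently truncated.
#'
#' Both routes satisfy the conservation identity
#' \eqn{\sum_i \sigma_i^2 = p(1-p)/N} and agree term by term on composed
#' schemes.
#'
#' @param scheme a [channel_scheme()].
#' @param v gating-variable value.
#' @param n_channels population size N (>= 1).
#' @param prune drop terms with negligible variance (default `TRUE`).
#' @return a [noise_spectrum()].
#' @export
#' @examples
#' kn <- hh_potassium_scheme()
#' covariance_spectrum(kn, v = -40, n_channels = 100)
covariance_spectrum <- function(scheme, v, n_channels, prune = TRUE) {
  stopifnot(inherits(scheme, "channel_scheme"),
            is.numeric(n_channels), n_channels >= 1)
  if (scheme$kind == "composed") {
    covariance_spectrum_composed(scheme, v, n_channels, prune = prune)
  } else {
    covariance_spectrum_general(scheme, v, n_channels, prune = prune)
  }
}

#' @rdname covariance_spectrum
#' @export
covariance_spectrum_composed <- function(scheme, v, n_channels,
                                         prune = TRUE) {
  stopifnot(scheme$kind == "composed")
  ss <- lapply(scheme$subunits, function(s) subunit_steady_state(s$rates, v))
  x <- vapply(ss, `[[`, numeric(1), "x_inf")
  taux <- vapply(ss, `[[`, numeric(1), "tau")
  counts <- vapply(scheme$subunits, `[[`, integer(1), "count")
  grid <- as.matrix(expand.grid(lapply(counts, function(q) 0:q),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  sigma_sq <- apply(grid, 1L, function(k) {
    prod(choose(counts, k) * x^(2 * (counts - k)) * (x * (1 - x))^k)
  }) / n_channels
  tau <- 1 / as.numeric(grid %*% (1 / taux))
  sp <- noise_spectrum(sigma_sq, tau, n_channels, p_open = prod(x^counts))
  if (prune) canonicalize_spectrum(sp) else sp
}

#' @rdname covariance_spectrum
#' @export
covariance_spectrum_general <- function(scheme, v, n_channels,
                                        prune = TRUE) {
  scheme <- as_general_scheme(scheme)
  A <- transition_matrix(scheme, v)
  M <- nrow(A)
  o <- scheme$open_state
  P <- stationary_distribution(A)
  p <- P[o]
  e <- eigen(A)
  scale <- max(abs(Re(e$values)), .Machine$double.eps)
  if (any(abs(Im(e$values)) > 1e-8 * scale)) {
    stop("unsupported oscillatory scheme: rate matrix has complex ",
         "eigenvalues", call. = FALSE)
  }
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) {
    stop("defective rate matrix: not diagonalizable", call. = FALSE)
  })
  if (max(abs(V %*% Vi - diag(M))) > 1e-6) {
    stop("defective rate matrix: not diagonalizable", call. = FALSE)
  }
  lam <- Re(e$values)
  w <- Re(V[o, ] * Vi[, o])
  nonzero <- abs(lam) > 1e-10 * scale
  if (sum(!nonzero) != 1L) {
    stop("non-ergodic scheme: expected exactly one zero eigenvalue",
         call. = FALSE)
  }
  sigma_sq <- p * w[nonzero] / n_channels
  tau <- 1 / abs(lam[nonzero])
  sp <- noise_spectrum(sigma_sq, tau, n_channels, p_open = p)
  canonicalize_spectrum(sp, merge_tol = 1e-8, drop = prune)
}

#' Evaluate the summed exponential autocovariance of a spectrum
#'
#' @param spectrum a [noise_spectrum()].
#' @param t lag grid (ms).
#' @return numeric vector `sum_i sigma_i^2 exp(-t / tau_i)`.
#' @export
spectrum_acov <- function(spectrum, t) {
  stopifnot(inherits(spectrum, "noise_spectrum"))
  as.numeric(exp(-outer(t, 1 / spectrum$tau)) %*% spectrum$sigma_sq)
}

#' Collapse a multi-exponential noise spectrum to a single OU term
#'
#' For computational economy the sum of OU processes can be replaced by a
#' single one with the same total variance. Two ways to choose its time
#' constant:
#'
#' * `"taylor"`: match the value and first derivative of the summed
#'   autocovariance at lag 0, giving
#'   \eqn{\sigma^2 = \sum_i \sigma_i^2} and
#'   \eqn{\tau = \sum_i \sigma_i^2 / \sum_i (\sigma_i^2/\tau_i)};
#' * `"best_fit"`: least-squares fit of \eqn{\sigma^2 e^{-t/\tau}} to the
#'   summed autocovariance on a lag grid (amplitude profiled in closed form,
#'   `tau` optimised on a log scale).
#'
#' Either way the stationary variance is preserved approximately
#' (`"taylor"`: exactly); the shape of the autocovariance only approximately.
#'
#' @param spectrum a [noise_spectrum()].
#' @param method `"taylor"` or `"best_fit"`.
#' @param fit_grid lag grid (ms) for `"best_fit"`; default
#'   `seq(0, 5 * max(tau), length.out = 256)`.
#' @return list with fields `sigma_sq` and `tau`.
#' @export
reduce_to_single_term <- function(spectrum, method = c("taylor", "best_fit"),
                                  fit_grid = NULL) {
  stopifnot(inherits(spectrum, "noise_spectrum"), nrow(spectrum) >= 1L)
  method <- match.arg(method)
  tot <- sum(spectrum$sigma_sq)
  if (nrow(spectrum) == 1L) {
    return(list(sigma_sq = spectrum$sigma_sq[1], tau = spectrum$tau[1]))
  }
  if (tot <= 0) return(list(sigma_sq = 0, tau = max(spectrum$tau)))
  if (method == "taylor") {
    tau <- tot / sum(spectrum$sigma_sq / spectrum$tau)
    return(list(sigma_sq = tot, tau = tau))
  }
  if (is.null(fit_grid)) {
    fit_grid <- seq(0, 5 * max(spectrum$tau), length.out = 256L)
  }
  target <- spectrum_acov(spectrum, fit_grid)
  fit <- fit_single_exp_curve(fit_grid, target,
                              tau_range = c(min(spectrum$tau) / 5,
                                            max(spectrum$tau) * 5))
  list(sigma_sq = fit$amplitude, tau = fit$tau)
}

# Profile least squares of a * exp(-t/tau) against y(t); amplitude in closed
# form given tau, tau optimised on log scale.
fit_single_exp_curve <- function(t, y, tau_range) {
  rss <- function(log_tau) {
    e <- exp(-t / exp(log_tau))
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  opt <- optimize(rss, interval = log(tau_range))
  tau <- exp(opt$minimum)
  e <- exp(-t / tau)
  list(amplitude = sum(y * e) / sum(e * e), tau = tau,
       rss = opt$objective)
}
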