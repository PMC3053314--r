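# Small schemes and shared simulation cache used across test files.

# 2-state scheme with constant rates alpha, beta
two_state_scheme <- function(alpha = 1, beta = 1) {
  channel_scheme(subunit_spec("s", 1L,
                              rate_pair(rate_law("constant", alpha),
                                        rate_law("constant", beta))))
}

# 2-state scheme whose steady state crosses 1/2 at v = 0
sigmoid_two_state <- function() {
  channel_scheme(subunit_spec("s", 1L,
                              rate_pair(rate_law("sigmoid", 1, 0, 8),
                                        rate_law("sigmoid", 1, 0, -8))))
}

# n^4-style scheme with constant rates (n_inf = alpha / (alpha + beta))
constant_n4_scheme <- function(alpha = 1, beta = 1) {
  channel_scheme(subunit_spec("n", 4L,
                              rate_pair(rate_law("constant", alpha),
                                        rate_law("constant", beta))))
}

# session-level cache so expensive voltage-clamp runs are shared between
# test files (each entry is keyed by its full parameter set)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# voltage-clamp stationary statistics with analytic standard errors
# derived from the theoretical noise spectrum:
#   Var(mean)  ~ (2/T) * sum_i sigma_i^2 tau_i
#   Var(s^2)   ~ (2/T) * integral C(t)^2 dt (Gaussian approximation)
vclamp_se <- function(spectrum, duration_ms) {
  s2 <- spectrum$sigma_sq
  tau <- spectrum$tau
  se_mean <- sqrt(2 * sum(s2 * tau) / duration_ms)
  acc <- 0
  for (i in seq_along(s2)) {
    for (j in seq_along(s2)) {
      acc <- acc + s2[i] * s2[j] / (1 / tau[i] + 1 / tau[j])
    }
  }
  se_var <- sqrt(4 * acc / duration_ms)
  list(mean = se_mean, var = se_var)
}

hh_small_fixture <- function() {
  cached("hh_small_fixture",
         build_hh_fixture(list(diameter_um = 10, length_um = 10)))
}
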