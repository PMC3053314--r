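test_that("subunit steady state follows the alpha/(alpha+beta) closed form", {
  rp <- rate_pair(rate_law("constant", 1), rate_law("constant", 1))
  ss <- subunit_steady_state(rp, 0)
  expect_equal(ss$x_inf, 0.5)
  expect_equal(ss$tau, 0.5)

  rp <- rate_pair(rate_law("constant", 3), rate_law("constant", 1))
  ss <- subunit_steady_state(rp, 0)
  expect_equal(ss$x_inf, 0.75)
  expect_equal(ss$tau, 0.25)

  rp <- rate_pair(rate_law("constant", 0), rate_law("constant", 2))
  ss <- subunit_steady_state(rp, 0)
  expect_equal(ss$x_inf, 0)
  expect_equal(ss$tau, 0.5)

  rp <- rate_pair(rate_law("constant", 0), rate_law("constant", 0))
  expect_error(subunit_steady_state(rp, 0), "degenerate")
})

test_that("HH linexp rates are finite and continuous at the removable singularity", {
  am <- rate_law("linexp", a = 0.1, v_half = -40, k = 10)
  v <- c(-40 - 1e-9, -40, -40 + 1e-9)
  r <- eval_rate(am, v)
  expect_true(all(is.finite(r)))
  expect_equal(r[2], 0.1 * 10, tolerance = 1e-9) # analytic limit a*k
  expect_lt(max(abs(diff(r))), 1e-8)
})

test_that("transition matrix transcribes the 2-state scheme and conserves probability", {
  sch <- two_state_scheme(1, 2)
  A <- transition_matrix(sch, 0)
  expect_equal(A, matrix(c(-1, 1, 2, -2), 2, 2))
  for (v in c(-80, -40, 0, 20)) {
    for (sch2 in list(hh_sodium_scheme(), hh_potassium_scheme())) {
      expect_lt(max(abs(colSums(transition_matrix(sch2, v)))), 1e-12)
    }
  }
})

test_that("n^4 transition matrix is the 5-state ladder of independent gates", {
  kn <- hh_potassium_scheme()
  v <- -35
  a <- eval_rate(hh_rate_laws()$n$alpha, v)
  b <- eval_rate(hh_rate_laws()$n$beta, v)
  A <- transition_matrix(kn, v)
  # super-diagonal: k active gates lose one at rate k*beta (k = 1..4)
  expect_equal(A[cbind(1:4, 2:5)], (1:4) * b)
  # sub-diagonal: 4-k inactive gates activate at rate (4-k)*alpha
  expect_equal(A[cbind(2:5, 1:4)], (4:1) * a)
  off <- A
  diag(off) <- 0
  expect_equal(sum(off != 0), 8L) # nearest-neighbour ladder only
})

test_that("stationary distribution matches closed forms and a propagation oracle", {
  A <- transition_matrix(two_state_scheme(1, 3), 0)
  expect_equal(stationary_distribution(A), c(0.75, 0.25), tolerance = 1e-12)

  # n_inf = 0.5: conducting-state mass 0.5^4
  A4 <- transition_matrix(constant_n4_scheme(1, 1), 0)
  p4 <- stationary_distribution(A4)
  expect_equal(p4[5], 0.0625, tolerance = 1e-10)

  # m3h at a voltage: matrix-exponential long-time limit as oracle
  na <- hh_sodium_scheme()
  A8 <- transition_matrix(na, -40)
  p8 <- stationary_distribution(A8)
  prop <- as.numeric(Matrix::expm(A8 * 500) %*% c(1, rep(0, 7)))
  expect_equal(p8, prop, tolerance = 1e-8)
  expect_lt(max(abs(A8 %*% p8)), 1e-10)

  # disconnected state space is rejected
  Abad <- matrix(0, 4, 4)
  Abad[2, 1] <- Abad[1, 2] <- 1
  Abad[4, 3] <- Abad[3, 4] <- 1
  diag(Abad) <- -colSums(Abad)
  expect_error(stationary_distribution(Abad), "non-ergodic")
})

test_that("n^4 covariance spectrum matches the binomial expansion exactly", {
  # n_inf = 0.5, tau_n = 1 ms, N = 100: sigma_k^2 = C(4,k) 0.25^4 / N
  sp <- covariance_spectrum(constant_n4_scheme(0.5, 0.5), 0, 100)
  expect_equal(nrow(sp), 4L)
  expect_equal(sp$tau, c(1, 1 / 2, 1 / 3, 1 / 4), tolerance = 1e-12)
  expect_equal(sp$sigma_sq,
               c(1.5625e-4, 2.34375e-4, 1.5625e-4, 3.90625e-5),
               tolerance = 1e-12)
  expect_equal(sum(sp$sigma_sq), 5.859375e-4, tolerance = 1e-12)
  expect_equal(attr(sp, "p_open"), 0.0625)
})

test_that("spectrum reduces to the 2-state single term", {
  sp <- covariance_spectrum(two_state_scheme(1, 3), 0, 50)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$sigma_sq, 0.25 * 0.75 / 50)
  expect_equal(sp$tau, 1 / 4)
})

test_that("spectrum conservation holds for all fixtures across voltages", {
  for (v in seq(-80, 20, length.out = 9)) {
    for (sch in list(two_state_scheme(0.5, 2), hh_potassium_scheme(),
                     hh_sodium_scheme())) {
      for (path in list(covariance_spectrum_composed,
                        covariance_spectrum_general)) {
        sp <- path(sch, v, 1800)
        p <- attr(sp, "p_open")
        expect_equal(sum(sp$sigma_sq), p * (1 - p) / 1800,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("composed and general covariance paths agree term by term", {
  for (v in c(-80, -55, -40, -20, 0, 20)) {
    for (sch in list(hh_potassium_scheme(), hh_sodium_scheme())) {
      a <- covariance_spectrum_composed(sch, v, 360)
      b <- covariance_spectrum_general(sch, v, 360)
      expect_equal(nrow(a), nrow(b))
      expect_equal(a$tau, b$tau, tolerance = 1e-8)
      expect_equal(a$sigma_sq, b$sigma_sq, tolerance = 1e-8)
    }
  }
})

test_that("2-state variance peaks at the half-activation voltage", {
  sch <- sigmoid_two_state()
  v <- seq(-40, 40, by = 2)
  s2 <- vapply(v, function(vv) {
    sum(covariance_spectrum(sch, vv, 100)$sigma_sq)
  }, numeric(1))
  expect_equal(v[which.max(s2)], 0)
  x_half <- subunit_steady_state(sch$subunits[[1]]$rates, 0)$x_inf
  expect_equal(x_half, 0.5)
})

test_that("oscillatory general schemes are rejected, not truncated", {
  # unidirectional 3-cycle: complex relaxation eigenvalues
  cyc <- general_scheme(c("a", "b", "c"), function(v) {
    A <- matrix(0, 3, 3)
    A[2, 1] <- 1
    A[3, 2] <- 1
    A[1, 3] <- 1
    diag(A) <- -colSums(A)
    A
  }, open_state = 3L)
  expect_error(covariance_spectrum(cyc, 0, 10), "oscillatory")
})

test_that("single-term reduction: identity, harmonic-mean tau, best-fit beats tau_n", {
  one <- noise_spectrum(0.3, 2.5, 10)
  expect_equal(reduce_to_single_term(one, "taylor"),
               list(sigma_sq = 0.3, tau = 2.5))
  expect_equal(reduce_to_single_term(one, "best_fit"),
               list(sigma_sq = 0.3, tau = 2.5), tolerance = 1e-6)

  two <- noise_spectrum(c(0.1, 0.1), c(4, 1), 10)
  r <- reduce_to_single_term(two, "taylor")
  expect_equal(r$sigma_sq, 0.2)
  expect_equal(r$tau, 2 / (1 / 4 + 1 / 1)) # harmonic mean

  # on the n^4 spectrum, the free best-fit tau outperforms fixing tau_n
  sp <- covariance_spectrum(constant_n4_scheme(0.5, 0.5), 0, 100)
  grid <- seq(0, 5, length.out = 200)
  target <- spectrum_acov(sp, grid)
  bf <- reduce_to_single_term(sp, "best_fit", fit_grid = grid)
  rss_bf <- sum((target - bf$sigma_sq * exp(-grid / bf$tau))^2)
  e_n <- exp(-grid / 1) # tau fixed at the kinetic tau_n
  a_n <- sum(target * e_n) / sum(e_n^2)
  rss_n <- sum((target - a_n * e_n)^2)
  expect_lt(rss_bf, rss_n)
  expect_error(reduce_to_single_term(noise_spectrum(numeric(0),
                                                    numeric(0), 1)))
})

test_that("schemes load from declarative YAML configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "kind: composed",
    "subunits:",
    "  - name: \"n\"", # quoted: bare n is a YAML boolean
    "    count: 4",
    "    alpha: {type: linexp, a: 0.01, v_half: -55, k: 10}",
    "    beta:  {type: exponential, a: 0.125, v_half: -65, k: -80}"
  ), path)
  sch <- load_scheme(path)
  expect_equal(n_states(sch), 5L)
  expect_equal(transition_matrix(sch, -40),
               transition_matrix(hh_potassium_scheme(), -40))

  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "kind: general",
    "states: [closed, open]",
    "open_state: open",
    "transitions:",
    "  - {from: closed, to: open, type: constant, a: 1.0}",
    "  - {from: open, to: closed, type: constant, a: 2.0}"
  ), path2)
  g <- load_scheme(path2)
  expect_equal(transition_matrix(g, 0), matrix(c(-1, 1, 2, -2), 2, 2))
})
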