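#' Hodgkin-Huxley rate laws
#'
#' The canonical squid-axon rate expressions in the modern voltage
#' convention (resting potential near -65 mV), in 1/ms with `v` in mV:
#' \deqn{\alpha_m = 0.1\,(v+40)/(1 - e^{-(v+40)/10}), \quad
#'       \beta_m = 4\, e^{-(v+65)/18}}
#' \deqn{\alpha_h = 0.07\, e^{-(v+65)/20}, \quad
#'       \beta_h = 1/(1 + e^{-(v+35)/10})}
#' \deqn{\alpha_n = 0.01\,(v+55)/(1 - e^{-(v+55)/10}), \quad
#'       \beta_n = 0.125\, e^{-(v+65)/80}}
#'
#' @return named list of [rate_pair()] objects for the `m`, `h`, `n` gates.
#' @export
hh_rate_laws <- function() {
  list(
    m = rate_pair(rate_law("linexp", a = 0.1, v_half = -40, k = 10),
                  rate_law("exponential", a = 4, v_half = -65, k = -18)),
    h = rate_pair(rate_law("exponential", a = 0.07, v_half = -65, k = -20),
                  rate_law("sigmoid", a = 1, v_half = -35, k = 10)),
    n = rate_pair(rate_law("linexp", a = 0.01, v_half = -55, k = 10),
                  rate_law("exponential", a = 0.125, v_half = -65, k = -80))
  )
}

#' Canonical channel schemes of the Hodgkin-Huxley model
#'
#' The fast-inactivating sodium channel is composed of three identical
#' activation subunits (`m`) and one inactivation subunit (`h`) — an 8-state
#' ladder whose single conducting state has all four subunits active
#' (`m^3 h`). The delayed-rectifier potassium channel has four identical
#' activation subunits (`n^4`, a 5-state ladder).
#'
#' @return a [channel_scheme()].
#' @export
hh_sodium_scheme <- function() {
  r <- hh_rate_laws()
  channel_scheme(subunit_spec("m", 3L, r$m), subunit_spec("h", 1L, r$h))
}

#' @rdname hh_sodium_scheme
#' @export
hh_potassium_scheme <- function() {
  r <- hh_rate_laws()
  channel_scheme(subunit_spec("n", 4L, r$n))
}

#' Canonical stochastic Hodgkin-Huxley fixture
#'
#' Bundles the standard single-compartment HH model used throughout the
#' package: membrane parameters (C_m = 1 uF/cm^2, g_L = 0.3 mS/cm^2,
#' E_L = -54.387 mV, E_Na = 50 mV, E_K = -77 mV), a cylindrical geometry,
#' and sodium/potassium channel populations with densities 60 and 18 um^-2
#' and single-channel conductance 20 pS — so that the deterministic limits
#' of the maximal conductances are the classical 120 and 36 mS/cm^2.
#'
#' @param overrides named list of overrides. Recognised names:
#'   `length_um`, `diameter_um`, `gamma_na_ps`, `gamma_k_ps`,
#'   `density_na_um2`, `density_k_um2`, `c_m`, `g_leak`, `e_leak`, `e_na`,
#'   `e_k`.
#' @return object of class `hh_fixture`: a list with fields `membrane`
#'   ([membrane_params()]), `geometry` ([cylinder_geometry()]) and
#'   `populations` (list of [channel_population()] for `na` and `k`).
#' @export
#' @examples
#' fx <- build_hh_fixture(list(diameter_um = 10, length_um = 10))
#' fx$populations$na$n_channels
build_hh_fixture <- function(overrides = list()) {
  defaults <- list(length_um = 30, diameter_um = 30,
                   gamma_na_ps = 20, gamma_k_ps = 20,
                   density_na_um2 = 60, density_k_um2 = 18,
                   c_m = 1, g_leak = 0.3, e_leak = -54.387,
                   e_na = 50, e_k = -77)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown fixture override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- modifyList(defaults, overrides)
  geom <- cylinder_geometry(length_um = cfg$length_um,
                            diameter_um = cfg$diameter_um)
  pops <- list(
    na = channel_population(hh_sodium_scheme(),
                            density_um2 = cfg$density_na_um2,
                            area_um2 = geom$area_um2,
                            gamma_ps = cfg$gamma_na_ps,
                            e_rev = cfg$e_na, name = "na"),
    k = channel_population(hh_potassium_scheme(),
                           density_um2 = cfg$density_k_um2,
                           area_um2 = geom$area_um2,
                           gamma_ps = cfg$gamma_k_ps,
                           e_rev = cfg$e_k, name = "k")
  )
  structure(list(membrane = membrane_params(c_m = cfg$c_m,
                                            g_leak = cfg$g_leak,
                                            e_leak = cfg$e_leak),
                 geometry = geom, populations = pops, config = cfg),
            class = "hh_fixture")
}

#' Tabulate a scheme's noise-spectrum coefficients over a voltage grid
#'
#' Regenerates, for any scheme, the table of OU coefficients
#' \eqn{\{\sigma_i^2, \tau_i\}} that drive the effective model, one row per
#' (voltage, term).
#'
#' @param scheme a [channel_scheme()].
#' @param voltages voltage grid (mV).
#' @param n_channels population size for the 1/N scaling.
#' @return data frame with columns `v`, `term`, `sigma_sq`, `tau`,
#'   `p_open`.
#' @export
derive_coefficients <- function(scheme, voltages, n_channels = 1L) {
  rows <- lapply(voltages, function(v) {
    sp <- covariance_spectrum(scheme, v, n_channels)
    data.frame(v = v, term = seq_len(nrow(sp)), sigma_sq = sp$sigma_sq,
               tau = sp$tau, p_open = attr(sp, "p_open"))
  })
  do.call(rbind, rows)
}

#' Load a channel scheme from a declarative YAML document
#'
#' Two layouts are accepted.
#'
#' Composed scheme:
#' ```yaml
#' kind: composed
#' subunits:
#'   - name: "n"   # quote single-letter names: bare y/n are YAML booleans
#'     count: 4
#'     alpha: {type: linexp, a: 0.01, v_half: -55, k: 10}
#'     beta:  {type: exponential, a: 0.125, v_half: -65, k: -80}
#' ```
#'
#' General scheme (rates may only use the parametric rate-law families):
#' ```yaml
#' kind: general
#' states: [closed, open]
#' open_state: open
#' transitions:
#'   - {from: closed, to: open, type: constant, a: 1.0}
#'   - {from: open, to: closed, type: constant, a: 2.0}
#' ```
#'
#' @param path path to a YAML file.
#' @return a [channel_scheme()].
#' @export
load_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  kind <- doc$kind
  if (identical(kind, "composed")) {
    subs <- lapply(doc$subunits, function(s) {
      if (!is.character(s$name)) {
        stop("subunit name must be a string; quote single-letter names ",
             "like \"n\" (bare y/n are YAML booleans)", call. = FALSE)
      }
      subunit_spec(s$name, s$count,
                   rate_pair(rate_law_from_config(s$alpha),
                             rate_law_from_config(s$beta)))
    })
    return(channel_scheme(subs))
  }
  if (identical(kind, "general")) {
    states <- as.character(doc$states)
    trans <- lapply(doc$transitions, function(tr) {
      list(from = match(tr$from, states), to = match(tr$to, states),
           law = rate_law_from_config(tr))
    })
    if (any(vapply(trans, function(tr) {
      is.na(tr$from) || is.na(tr$to)
    }, logical(1)))) {
      stop("transition references an unknown state", call. = FALSE)
    }
    builder <- function(v) {
      A <- matrix(0, length(states), length(states))
      for (tr in trans) {
        A[tr$to, tr$from] <- A[tr$to, tr$from] + eval_rate(tr$law, v)
      }
      diag(A) <- diag(A) - colSums(A)
      A
    }
    return(general_scheme(states, builder, doc$open_state))
  }
  stop("scheme config must declare kind: composed or kind: general",
       call. = FALSE)
}

rate_law_from_config <- function(cfg) {
  stopifnot(!is.null(cfg$type), !is.null(cfg$a))
  rate_law(cfg$type, a = cfg$a,
           v_half = if (is.null(cfg$v_half)) 0 else cfg$v_half,
           k = if (is.null(cfg$k)) 1 else cfg$k)
}
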