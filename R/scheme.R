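#' Subunit specification of a composed channel scheme
#'
#' Many channel models are products of independent 2-state gating subunits:
#' the fast sodium channel opens when its three activation subunits (`m`) and
#' one inactivation subunit (`h`) are all active, the delayed-rectifier
#' potassium channel when its four `n` subunits are.
#'
#' @param name single-letter label of the subunit type (e.g. `"m"`).
#' @param count positive integer multiplicity (the exponent of the gating
#'   variable in the deterministic conductance).
#' @param rates a [rate_pair()] giving the subunit's opening/closing rates.
#' @return object of class `subunit_spec`.
#' @export
subunit_spec <- function(name, count, rates) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(count), length(count) == 1L, count >= 1,
            count == round(count), inherits(rates, "rate_pair"))
  structure(list(name = name, count = as.integer(count), rates = rates),
            class = "subunit_spec")
}

#' Markov kinetic scheme of a single channel
#'
#' A scheme is either *composed* of independent 2-state subunits (the usual
#' Hodgkin-Huxley structure; the full state space is the product ladder of
#' subunit activation counts, with a single conducting state in which every
#' subunit is active), or *general*: an arbitrary list of states with a
#' user-supplied rate-matrix builder and one designated conducting state.
#'
#' @param ... for `channel_scheme()`: one or more [subunit_spec()] objects.
#' @return object of class `channel_scheme` with fields `kind`
#'   (`"composed"` or `"general"`) and the structural data.
#' @seealso [general_scheme()], [transition_matrix()],
#'   [covariance_spectrum()]
#' @export
#' @examples
#' k <- channel_scheme(subunit_spec("n", 4,
#'   rate_pair(rate_law("linexp", 0.01, -55, 10),
#'             rate_law("exponential", 0.125, -65, -80))))
#' n_states(k) # 5
channel_scheme <- function(...) {
  subs <- list(...)
  if (length(subs) == 1L && is.list(subs[[1L]]) &&
      !inherits(subs[[1L]], "subunit_spec")) {
    subs <- subs[[1L]]
  }
  stopifnot(length(subs) >= 1L,
            all(vapply(subs, inherits, logical(1), "subunit_spec")))
  nm <- vapply(subs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate subunit names", call. = FALSE)
  structure(list(kind = "composed", subunits = subs), class = "channel_scheme")
}

#' @rdname channel_scheme
#' @param states character vector of state labels.
#' @param rate_matrix function of the gating variable returning the M x M
#'   transition-rate matrix (1/ms). Column `j` holds the rates leaving state
#'   `j`: entry `[i, j]` is the rate of the transition `j -> i`, so columns
#'   must sum to zero and off-diagonal entries must be non-negative.
#' @param open_state index (or label) of the single conducting state.
#' @export
general_scheme <- function(states, rate_matrix, open_state) {
  stopifnot(is.character(states), length(states) >= 2L,
            is.function(rate_matrix))
  if (is.character(open_state)) open_state <- match(open_state, states)
  stopifnot(is.numeric(open_state), length(open_state) == 1L,
            !is.na(open_state), open_state >= 1,
            open_state <= length(states))
  structure(list(kind = "general", states = states,
                 rate_matrix = rate_matrix,
                 open_state = as.integer(open_state)),
            class = "channel_scheme")
}

#' Number of states of a scheme
#'
#' For composed schemes the state space is the ladder of subunit activation
#' counts, with \eqn{\prod_j (q_j + 1)} states for multiplicities
#' \eqn{q_j}.
#'
#' @param scheme a [channel_scheme()].
#' @return integer number of states M.
#' @export
n_states <- function(scheme) {
  stopifnot(inherits(scheme, "channel_scheme"))
  if (scheme$kind == "composed") {
    prod(vapply(scheme$subunits, `[[`, integer(1), "count") + 1L)
  } else {
    length(scheme$states)
  }
}

# Enumerate composed-scheme states as rows of activation counts, in
# column-major ladder order; the conducting state is the last row.
scheme_state_grid <- function(scheme) {
  counts <- vapply(scheme$subunits, `[[`, integer(1), "count")
  g <- as.matrix(expand.grid(lapply(counts, function(q) 0:q),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- list(NULL, vapply(scheme$subunits, `[[`, character(1),
                                   "name"))
  g
}

# Index of the conducting state (all subunits fully active / user-declared).
open_state_index <- function(scheme) {
  if (scheme$kind == "general") return(scheme$open_state)
  n_states(scheme)
}

#' Transition-rate matrix of a scheme at a gating point
#'
#' Returns the M x M infinitesimal generator `A` in the column convention:
#' `A[i, j]` is the rate (1/ms) of the transition from state `j` to state
#' `i`; diagonal entries make every column sum to zero (probability
#' conservation), so the occupancy-probability vector `P` obeys
#' `dP/dt = A %*% P`. For composed schemes the matrix is the ladder implied
#' by independent subunits: a channel with `k` of `q` subunits of a type
#' active gains one at rate `(q - k) * alpha` and loses one at rate
#' `k * beta`.
#'
#' @param scheme a [channel_scheme()].
#' @param v gating-variable value (mV for voltage-gated schemes).
#' @return M x M numeric matrix.
#' @export
transition_matrix <- function(scheme, v) {
  stopifnot(inherits(scheme, "channel_scheme"), is.numeric(v),
            length(v) == 1L)
  if (scheme$kind == "general") {
    A <- scheme$rate_matrix(v)
    M <- length(scheme$states)
    if (!is.matrix(A) || !all(dim(A) == M)) {
      stop("rate_matrix must return an M x M matrix", call. = FALSE)
    }
    off <- A - diag(diag(A), M)
    if (any(off < 0)) stop("invalid rate: negative off-diagonal entry",
                           call. = FALSE)
    if (max(abs(colSums(A))) > 1e-10 * max(abs(A), 1)) {
      stop("invalid rate matrix: columns must sum to zero", call. = FALSE)
    }
    return(A)
  }
  grid <- scheme_state_grid(scheme)
  counts <- vapply(scheme$subunits, `[[`, integer(1), "count")
  al <- vapply(scheme$subunits, function(s) eval_rate(s$rates$alpha, v),
               numeric(1))
  be <- vapply(scheme$subunits, function(s) eval_rate(s$rates$beta, v),
               numeric(1))
  M <- nrow(grid)
  strides <- cumprod(c(1L, counts[-length(counts)] + 1L))
  A <- matrix(0, M, M)
  for (s in seq_len(M)) {
    k <- grid[s, ]
    for (j in seq_along(counts)) {
      up <- (counts[j] - k[j]) * al[j]
      if (up > 0) A[s + strides[j], s] <- A[s + strides[j], s] + up
      dn <- k[j] * be[j]
      if (dn > 0) A[s - strides[j], s] <- A[s - strides[j], s] + dn
    }
  }
  diag(A) <- -colSums(A)
  A
}

#' Stationary occupancy distribution of a rate matrix
#'
#' Solves `A %*% P = 0`, `sum(P) = 1` for the unique stationary
#' distribution. Schemes whose rate matrix has more than one null dimension
#' (disconnected state spaces) are rejected.
#'
#' @param A an M x M transition-rate matrix (columns summing to zero).
#' @return numeric probability vector of length M.
#' @export
stationary_distribution <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  M <- nrow(A)
  sv <- svd(A)
  scale <- max(sv$d[1], .Machine$double.eps)
  if (M >= 2L && sv$d[M - 1L] <= 1e-10 * scale) {
    stop("non-ergodic scheme: rate matrix has more than one stationary ",
         "direction", call. = FALSE)
  }
  p <- sv$v[, M]
  p <- p / sum(p)
  if (any(p < -1e-10)) {
    stop("non-ergodic scheme: stationary vector has negative entries",
         call. = FALSE)
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  if (max(abs(A %*% p)) > 1e-10 * max(scale, 1)) {
    stop("stationary distribution did not converge", call. = FALSE)
  }
  p
}

# Convert a composed scheme to its explicit general M-state form.
as_general_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "channel_scheme"))
  if (scheme$kind == "general") return(scheme)
  grid <- scheme_state_grid(scheme)
  labels <- apply(grid, 1L, function(k) {
    paste0(vapply(scheme$subunits, `[[`, character(1), "name"), k,
           collapse = "")
  })
  force(scheme)
  composed <- scheme
  general_scheme(labels,
                 function(v) transition_matrix(composed, v),
                 open_state = nrow(grid))
}
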