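#' Construct a kinetic rate network
#'
#' A `rate_network` describes a continuous-time Markov scheme over a small set
#' of conformational states. The workhorse topology is the linear three-state
#' chain C1 <-> C2 <-> C3 used to model hinge-bending dynamics; a cyclic
#' topology can be represented (e.g. to state that it was considered and
#' rejected) but is excluded from analytical inversion.
#'
#' Rates are first-order rate constants in 1/ms. `rates` is a tibble with
#' columns `from`, `to`, `rate`; states not mentioned are absorbing.
#'
#' @param states character vector of state labels, e.g. `c("C1","C2","C3")`.
#' @param rates tibble/data.frame with columns `from`, `to`, `rate` (1/ms).
#' @param temperature_K temperature used when deriving free energies.
#' @return An object of class `rate_network` with the rate matrix `K`
#'   (column j holds the outflow of state j; columns sum to zero).
#' @examples
#' net <- rate_network(c("C1", "C2", "C3"),
#'   linear_chain_rates(k12 = 1, k21 = 1, k23 = 1, k32 = 1))
#' relaxation_spectrum(net)
#' @export
rate_network <- function(states, rates, temperature_K = 293.15) {
  stopifnot(is.character(states), length(states) >= 1, !anyDuplicated(states))
  rates <- tibble::as_tibble(rates)
  stopifnot(all(c("from", "to", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) stop("rate constants must be >= 0")
  if (!all(rates$from %in% states) || !all(rates$to %in% states)) {
    stop("rates refer to undeclared states")
  }
  if (any(rates$from == rates$to)) stop("self-transitions are not allowed")
  n <- length(states)
  K <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(nrow(rates))) {
    K[rates$to[i], rates$from[i]] <- K[rates$to[i], rates$from[i]] + rates$rate[i]
  }
  diag(K) <- diag(K) - colSums(K)
  structure(
    list(states = states, rates = rates, K = K, temperature_K = temperature_K),
    class = "rate_network"
  )
}

#' Rate table for a linear three-state chain
#'
#' Convenience constructor for the chain C1 <-> C2 <-> C3.
#'
#' @param k12,k21,k23,k32 rate constants (1/ms); `k12` is C1 -> C2 etc.
#' @return tibble suitable for [rate_network()].
#' @export
linear_chain_rates <- function(k12, k21, k23, k32) {
  tibble::tibble(
    from = c("C1", "C2", "C2", "C3"),
    to   = c("C2", "C1", "C3", "C2"),
    rate = c(k12, k21, k23, k32)
  )
}

#' @export
print.rate_network <- function(x, ...) {
  cat("<rate_network> ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  print(x$rates)
  invisible(x)
}

is_linear_chain <- function(network) {
  r <- network$rates
  n <- length(network$states)
  if (n != 3L || nrow(r) != 4L) return(FALSE)
  want <- paste(c("C1", "C2", "C2", "C3"), c("C2", "C1", "C3", "C2"))
  setequal(paste(r$from, r$to), want) &&
    identical(sort(network$states), c("C1", "C2", "C3"))
}

#' Relaxation times and equilibrium fractions of a network
#'
#' The eigenvalues of the rate matrix K decompose the approach to equilibrium:
#' the zero eigenvalue carries the stationary state and every nonzero
#' eigenvalue lambda contributes an exponential relaxation with characteristic
#' time t_R = -1/lambda. For a two-state scheme this reduces to the familiar
#' t_R = 1/(k_f + k_b).
#'
#' @param network a [rate_network()].
#' @return list with `t_R` (ms, sorted ascending, fastest first) and
#'   `fractions` (named stationary probabilities).
#' @export
relaxation_spectrum <- function(network) {
  stopifnot(inherits(network, "rate_network"))
  K <- network$K
  ev <- eigen(K)
  lam <- ev$values
  if (max(abs(Im(lam))) > 1e-9 * max(abs(lam), 1)) {
    # linear (detailed-balance) networks have real spectra; complex pairs can
    # only arise from cycles broken numerically -- keep the real parts
    lam <- Re(lam)
  } else {
    lam <- Re(lam)
  }
  scale <- max(abs(lam), .Machine$double.eps)
  zero <- abs(lam) < 1e-10 * scale
  if (sum(zero) > 1L) {
    stop("network is disconnected: stationary state is not unique")
  }
  i0 <- which.min(abs(lam))
  v0 <- Re(ev$vectors[, i0])
  if (sum(v0) < 0) v0 <- -v0
  if (any(v0 < -1e-8 * max(abs(v0)))) v0 <- abs(v0)
  fractions <- v0 / sum(v0)
  names(fractions) <- network$states
  t_R <- sort(-1 / lam[-i0])
  list(t_R = t_R, fractions = fractions)
}

#' Invert a three-state linear scheme from relaxation times and fractions
#'
#' Given the two relaxation times measured by fFCS and the equilibrium species
#' fractions from decay analysis, reconstruct the rate constants of the chain
#' C1 <-> C2 <-> C3. With a = x2/x1 and b = x3/x2 detailed balance leaves two
#' unknowns (k21, k32) constrained by the eigenvalue sum and product,
#'   S = k21 (1 + a) + k32 (1 + b)      = 1/t_R1 + 1/t_R2
#'   P = k21 k32 (1 + a + a b)          = 1/(t_R1 t_R2),
#' a quadratic with up to two physical roots: the experimentally relevant
#' ambiguity of whether the fast relaxation belongs to the C1-C2 or the C2-C3
#' exchange. Both solutions are returned (fast-C1C2 first); each is verified
#' by a forward [relaxation_spectrum()] round trip.
#'
#' @param t_R1,t_R2 relaxation times (ms), `t_R1 < t_R2`.
#' @param x1,x2,x3 equilibrium fractions (positive, summing to 1).
#' @param temperature_K passed to the returned networks.
#' @return list of up to two [rate_network()] objects, attribute
#'   `"discriminant"` carries the quadratic discriminant.
#' @export
invert_three_state <- function(t_R1, t_R2, x1, x2, x3, temperature_K = 293.15) {
  stopifnot(t_R1 > 0, t_R2 > 0, t_R1 < t_R2)
  x <- c(x1, x2, x3)
  if (any(x <= 0)) stop("fractions must be positive")
  if (abs(sum(x) - 1) > 1e-6) stop("fractions must sum to 1")
  a <- x2 / x1
  b <- x3 / x2
  S <- 1 / t_R1 + 1 / t_R2
  P <- 1 / (t_R1 * t_R2)
  # u = k21 (1+a), v = k32 (1+b): u + v = S, u v = P (1+a)(1+b)/(1+a+ab)
  uv <- P * (1 + a) * (1 + b) / (1 + a + a * b)
  disc <- S^2 - 4 * uv
  if (disc < 0) {
    stop(sprintf(
      "no physical three-state solution: discriminant %.3e < 0 (margin %.3e)",
      disc, disc / S^2))
  }
  root <- sqrt(disc)
  sols <- unique(lapply(list(c((S + root) / 2, (S - root) / 2),
                             c((S - root) / 2, (S + root) / 2)),
                        function(z) z))
  nets <- lapply(sols, function(z) {
    k21 <- unname(z[1]) / (1 + a)
    k32 <- unname(z[2]) / (1 + b)
    if (k21 <= 0 || k32 <= 0) return(NULL)
    rate_network(c("C1", "C2", "C3"),
                 linear_chain_rates(a * k21, k21, b * k32, k32),
                 temperature_K = temperature_K)
  })
  nets <- nets[!vapply(nets, is.null, logical(1))]
  # merge degenerate double roots
  if (length(nets) == 2L) {
    r1 <- nets[[1]]$rates$rate
    r2 <- nets[[2]]$rates$rate
    if (max(abs(r1 - r2) / pmax(abs(r1), .Machine$double.eps)) < 1e-6) {
      nets <- nets[1]
    }
  }
  # order: solution with the faster C1-C2 exchange first
  if (length(nets) == 2L) {
    ex12 <- vapply(nets, function(n) {
      r <- n$rates
      sum(r$rate[(r$from == "C1" & r$to == "C2") | (r$from == "C2" & r$to == "C1")])
    }, numeric(1))
    nets <- nets[order(-ex12)]
  }
  # verify round trip
  for (n in nets) {
    sp <- relaxation_spectrum(n)
    rel <- abs(sort(sp$t_R) - sort(c(t_R1, t_R2))) / c(t_R1, t_R2)
    if (max(rel) > 1e-7) {
      warning("round-trip relaxation times deviate beyond tolerance")
    }
  }
  attr(nets, "discriminant") <- disc
  nets
}

#' Invert a kinetic network object from its own observables
#'
#' Convenience round-trip entry point: takes a [rate_network()], checks that
#' its topology is the linear chain C1 <-> C2 <-> C3 (the only scheme the
#' analytical inversion supports; cyclic schemes are representable but
#' deliberately excluded), computes its relaxation spectrum and re-inverts
#' it with [invert_three_state()].
#'
#' @param network a [rate_network()] with linear-chain topology.
#' @return list of candidate networks, as for [invert_three_state()].
#' @export
invert_network <- function(network) {
  stopifnot(inherits(network, "rate_network"))
  if (!is_linear_chain(network)) {
    stop("unsupported topology: analytical inversion covers only the ",
         "linear chain C1 <-> C2 <-> C3 (cyclic schemes are excluded)")
  }
  sp <- relaxation_spectrum(network)
  invert_three_state(sp$t_R[1], sp$t_R[2], sp$fractions[["C1"]],
                     sp$fractions[["C2"]], sp$fractions[["C3"]],
                     temperature_K = network$temperature_K)
}

#' Gibbs free-energy landscape of a network
#'
#' State-to-state free-energy differences follow from detailed balance; the
#' row for transition i -> j reports DeltaG0 = -kB T ln(k_ji / k_ij), i.e. the
#' free energy of state i relative to state j (positive when j lies lower),
#' and the activation barrier of the directed step,
#' DeltaG0+ = -kB T ln(k_ij / k0). k0 is an arbitrary reference pre-factor
#' that shifts all barriers uniformly; the default 1e3/ms places barriers
#' above any observed conformational rate.
#'
#' @param network a [rate_network()] with strictly positive rates.
#' @param k_0 reference pre-factor (1/ms), default 1e3.
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @return tibble with per-transition `dG0` and `dG_act` (barrier seen from
#'   `from`), in the requested units.
#' @export
energy_landscape <- function(network, k_0 = 1e3, units = c("kT", "kJ/mol")) {
  stopifnot(inherits(network, "rate_network"))
  units <- match.arg(units)
  if (k_0 <= 0) stop("k_0 must be > 0")
  r <- network$rates
  if (any(r$rate <= 0)) stop("all rates must be > 0 for an energy landscape")
  scale <- if (units == "kT") 1 else 8.31446e-3 * network$temperature_K
  key <- function(f, t) paste(f, t, sep = "->")
  rev_rate <- r$rate[match(key(r$to, r$from), key(r$from, r$to))]
  if (anyNA(rev_rate)) stop("every transition needs a reverse rate")
  tibble::tibble(
    from = r$from, to = r$to,
    rate = r$rate,
    dG0 = -scale * log(rev_rate / r$rate),
    dG_act = -scale * log(r$rate / k_0),
    units = units
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rate_network <- function(x, ...) {
  sp <- relaxation_spectrum(x)
  dplyr::mutate(x$rates,
                x_from = unname(sp$fractions[x$rates$from]),
                x_to = unname(sp$fractions[x$rates$to]))
}

#' @export
glance.rate_network <- function(x, ...) {
  sp <- relaxation_spectrum(x)
  out <- tibble::tibble(
    n_states = length(x$states),
    t_R1_ms = sp$t_R[1],
    t_R2_ms = if (length(sp$t_R) >= 2) sp$t_R[2] else NA_real_
  )
  for (s in x$states) out[[paste0("x_", s)]] <- unname(sp$fractions[s])
  out
}
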