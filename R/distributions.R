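#' Degree distributions for fountain codes
#'
#' A fountain code draws, for every packet, a *degree*: the number of source
#' chunks XORed into the packet. `ideal_soliton()` builds Luby's Ideal
#' Soliton distribution
#' \deqn{\rho(1) = 1/N, \qquad \rho(k) = \frac{1}{k(k-1)}, \; k = 2,\dots,N,}
#' which is optimal in expectation but fragile in practice.
#' `robust_soliton()` adds Luby's spike term
#' \deqn{\tau(i) = \frac{1}{iK} \; (i < K), \quad
#'       \tau(K) = \frac{\ln(R/\delta)}{K}, \quad
#'       \tau(i) = 0 \; (i > K), \qquad R = N/K,}
#' and normalizes \eqn{\mu(i) = (\rho(i)+\tau(i)) / \sum_j (\rho(j)+\tau(j))}.
#' `custom_distribution()` wraps a user-supplied probability mass function,
#' and `raptor_distribution()` selects the fixed, parameter-free Raptor
#' degree table (see [raptor_degree_lookup()]).
#'
#' @param N maximum degree (positive integer).
#' @param K spike position, `1 <= K < N` (robust distribution only).
#' @param delta expected failure probability in (0, 1) (robust only).
#' @param pmf numeric vector of probabilities for degrees `1..length(pmf)`
#'   (custom only); normalized internally.
#' @return an object of class `degree_distribution` with fields `kind`, `N`,
#'   `pmf` and `cdf` (plus `K`, `delta` and the unnormalized spike `tau` for
#'   the robust form).
#' @examples
#' d <- ideal_soliton(10)
#' d$pmf[2]                       # the mode, always 0.5
#' r <- robust_soliton(10, 5, 0.1)
#' sum(r$pmf)                     # 1
#' @seealso [sample_degree()], [raptor_degree_lookup()]
#' @export
ideal_soliton <- function(N) {
  if (!is_count(N, min = 1L)) stop_param("N must be a positive integer")
  N <- as.integer(N)
  pmf <- numeric(N)
  pmf[1L] <- 1 / N
  if (N >= 2L) {
    k <- 2:N
    pmf[k] <- 1 / (k * (k - 1))
  }
  new_distribution("ideal_soliton", N = N, pmf = pmf)
}

#' @rdname ideal_soliton
#' @export
robust_soliton <- function(N, K, delta) {
  if (!is_count(N, min = 1L)) stop_param("N must be a positive integer")
  if (!is_count(K, min = 1L) || K >= N) {
    stop_param("K must be a positive integer with K < N")
  }
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta >= 1) {
    stop_param("delta must lie strictly in (0, 1)")
  }
  N <- as.integer(N); K <- as.integer(K)
  rho <- ideal_soliton(N)$pmf
  R <- N / K
  tau <- numeric(N)
  if (K > 1L) {
    i <- 1:(K - 1L)
    tau[i] <- 1 / (i * K)
  }
  tau[K] <- log(R / delta) / K
  pmf <- (rho + tau) / sum(rho + tau)
  new_distribution("robust_soliton", N = N, pmf = pmf,
                   K = K, delta = delta, tau = tau)
}

#' @rdname ideal_soliton
#' @export
custom_distribution <- function(pmf) {
  if (!is.numeric(pmf) || !length(pmf) || anyNA(pmf) || any(pmf < 0) ||
      sum(pmf) <= 0) {
    stop_param("pmf must be a non-negative numeric vector with positive sum")
  }
  new_distribution("custom", N = length(pmf), pmf = pmf / sum(pmf))
}

#' @rdname ideal_soliton
#' @export
raptor_distribution <- function() {
  structure(list(kind = "raptor_fixed", N = 40L, pmf = NULL, cdf = NULL),
            class = "degree_distribution")
}

new_distribution <- function(kind, N, pmf, ...) {
  stopifnot(all(pmf >= 0), abs(sum(pmf) - 1) < 1e-12)
  structure(list(kind = kind, N = as.integer(N), pmf = pmf,
                 cdf = cumsum(pmf), ...),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution %s, N=%d>\n", x$kind, x$N))
  invisible(x)
}

# Thresholds of the fixed Raptor degree table: f(v) is piecewise constant on
# [0, 2^20) with jumps at these values.
RAPTOR_DEGREE_THRESHOLDS <- c(10241, 491582, 712794, 831695, 948446, 1032189)
RAPTOR_DEGREES <- c(1L, 2L, 3L, 4L, 10L, 11L, 40L)

#' Fixed Raptor degree table
#'
#' Maps a uniform value `v` in `[0, 2^20)` to a packet degree through the
#' fixed, parameter-free piecewise-constant table used by the Raptor inner
#' code: degree 1 below 10241, 2 below 491582, 3 below 712794, 4 below
#' 831695, 10 below 948446, 11 below 1032189, and 40 otherwise.
#'
#' @param v integer (or vector of integers) in `[0, 2^20)`.
#' @return the corresponding degree(s), each in `{1, 2, 3, 4, 10, 11, 40}`.
#' @examples
#' raptor_degree_lookup(0)        # 1
#' raptor_degree_lookup(500000)   # 3
#' raptor_degree_lookup(1048575)  # 40
#' @export
raptor_degree_lookup <- function(v) {
  if (!is.numeric(v) || !length(v) || anyNA(v) ||
      any(v < 0 | v >= 1048576 | v != floor(v))) {
    stop_param("v must be integer(s) in [0, 2^20)")
  }
  RAPTOR_DEGREES[findInterval(v, RAPTOR_DEGREE_THRESHOLDS) + 1L]
}

#' Sample a packet degree from a degree distribution
#'
#' Draws by inverse-CDF over the probability mass function in ascending
#' degree order; for the fixed Raptor table, a uniform integer in
#' `[0, 2^20)` is drawn and passed through [raptor_degree_lookup()].
#' Deterministic given the generator state.
#'
#' @param dist a [ideal_soliton()]-family `degree_distribution`.
#' @param rng an [rng_new()] generator, advanced in place.
#' @return a single degree.
#' @export
sample_degree <- function(dist, rng) {
  stopifnot(inherits(dist, "degree_distribution"),
            inherits(rng, "xorshift_rng"))
  if (dist$kind == "raptor_fixed") {
    return(raptor_degree_lookup(rng_int(rng, 1048576)))
  }
  u <- rng_unif(rng)
  d <- findInterval(u, dist$cdf, left.open = FALSE) + 1L
  min(d, dist$N)
}
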