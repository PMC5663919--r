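# Polylogarithm numerics for heavy-tailed generating functions.
#
# All heavy-tail evaluations reduce to Li_s(e^-u) with u >= 0 and real,
# non-integer order s.  Two regimes are used:
#   u > 0.5 : direct series  sum_{k>=1} e^{-k u} k^{-s}; terms decay at least
#             like e^{-k/2}, so ~90 terms reach full double precision.
#   u <= 0.5: the expansion about the singular point,
#             Li_s(e^-u) = Gamma(1-s) u^(s-1) + sum_{n>=0} zeta(s-n) (-u)^n / n!,
#             absolutely convergent for |u| < 2*pi; truncated at n = 40 the
#             neglected terms are below 1e-30 for u <= 0.5.
# Orders that sit on an integer are nudged by 1e-9 (the expansion has
# removable singularities there); the avalanche-shape theory only ever needs
# non-integer orders 2 < gamma < 3 and their first two downward shifts.

.nudge_noninteger <- function(s) {
  if (abs(s - round(s)) < 1e-9) s + 1e-9 else s
}

# Cache of zeta(s - n), n = 0..nmax, reused across many evaluations at the
# same order (the ODE solver calls f thousands of times).
.polylog_cache <- function(s, nmax = 40L) {
  s <- .nudge_noninteger(s)
  list(s = s, n = 0:nmax, zeta_sn = pracma::zeta(s - 0:nmax),
       gamma1s = gamma(1 - s), fact = factorial(0:nmax))
}

# Li_s(e^-u) for scalar u >= 0 given a cache built at order s.
.polylog_expu_1 <- function(cache, u) {
  if (u < 0) stop("polylog argument requires u >= 0")
  if (u == 0) {
    if (cache$s <= 1) return(Inf)
    return(cache$zeta_sn[1L])
  }
  if (u > 0.5) {
    k <- seq_len(ceiling(45 / u) + 2L)
    return(sum(exp(-k * u) * k^(-cache$s)))
  }
  cache$gamma1s * u^(cache$s - 1) +
    sum(cache$zeta_sn * (-u)^cache$n / cache$fact)
}

# Vectorized over u.
polylog_expu <- function(s, u, cache = NULL) {
  if (is.null(cache)) cache <- .polylog_cache(s)
  vapply(u, function(ui) .polylog_expu_1(cache, ui), numeric(1))
}

# Li_s(x) for x in [0, 1].
polylog <- function(s, x, cache = NULL) {
  stopifnot(all(x >= 0), all(x <= 1))
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- polylog_expu(s, -log(x[pos]), cache = cache)
  out
}
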