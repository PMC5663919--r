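#' Degree distributions for configuration-model networks
#'
#' A `degree_dist` holds the probability mass function of node degrees,
#' either for an undirected network (`kind = "undirected"`) or for a directed
#' network with independent in- and out-degrees (`kind = "directed"`, the
#' factorized joint distribution `p_jk = p_j^in p_k^out`).  The mean degree
#' `z` and tail metadata (exponent `alpha`, lower cutoff `k_min`) feed the
#' offspring-distribution construction.
#'
#' @param pmf numeric vector of probabilities, `pmf[i]` giving the
#'   probability of degree `i - 1` (support starts at degree 0).
#' @param kind `"undirected"` or `"directed"`.
#' @param alpha,k_min optional power-law tail metadata.
#' @return an object of class `degree_dist`.
#' @export
degree_dist <- function(pmf, kind = c("undirected", "directed"),
                        alpha = NULL, k_min = NULL) {
  kind <- match.arg(kind)
  if (any(pmf < -1e-12)) stop("degree pmf has negative entries")
  pmf <- pmax(pmf, 0)
  s <- sum(pmf)
  if (abs(s - 1) > 1e-6) stop("degree pmf sums to ", s, ", not 1")
  pmf <- pmf / s
  k <- seq_along(pmf) - 1
  z <- sum(k * pmf)
  structure(list(kind = kind, pmf = pmf, z = z,
                 alpha = alpha, k_min = k_min, k_max = length(pmf) - 1L),
            class = "degree_dist")
}

#' @export
print.degree_dist <- function(x, ...) {
  cat("<degree_dist>", x$kind, " z =", format(x$z, digits = 6),
      " support 0..", x$k_max, "\n")
  if (!is.null(x$alpha)) cat("  power-law tail alpha =", x$alpha,
                             " k_min =", x$k_min, "\n")
  invisible(x)
}

#' Power-law degree distribution `p_k` proportional to `k^-alpha`, `k >= k_min`
#'
#' @param alpha tail exponent (> 2 so the mean exists, unless `k_max` is a
#'   deliberate hard truncation).
#' @param k_min minimum degree.
#' @param k_max support truncation for the dense numerics; the truncated mass
#'   at the default is below 1e-9 for `alpha >= 2.3`.
#' @inheritParams degree_dist
#' @export
degree_powerlaw <- function(alpha, k_min = 1L, k_max = 1e6,
                            kind = c("undirected", "directed")) {
  if (alpha <= 2 && k_max > 1e7)
    stop("alpha <= 2 gives a divergent mean degree; supply a finite k_max")
  stopifnot(k_min >= 1)
  k <- 0:k_max
  w <- numeric(k_max + 1)
  w[k >= k_min] <- k[k >= k_min]^(-alpha)
  degree_dist(w / sum(w), kind = match.arg(kind),
              alpha = alpha, k_min = as.integer(k_min))
}

#' Analytic mean of the untruncated power-law degree distribution
#'
#' Mean of `p_k` proportional to `k^-alpha` on `k >= k_min`, computed with
#' Riemann zeta functions:
#' `(zeta(alpha-1) - sum_{k<k_min} k^(1-alpha)) / (zeta(alpha) - sum_{k<k_min} k^-alpha)`.
#'
#' @inheritParams degree_powerlaw
#' @export
powerlaw_mean <- function(alpha, k_min = 1L) {
  stopifnot(alpha > 2, k_min >= 1)
  kk <- seq_len(k_min - 1)
  num <- pracma::zeta(alpha - 1) - sum(kk^(1 - alpha))
  den <- pracma::zeta(alpha) - sum(kk^(-alpha))
  num / den
}

#' Poisson degree distribution with mean `z`
#' @param z mean degree.
#' @param k_max support truncation (defaults to the 1 - 1e-15 quantile).
#' @inheritParams degree_dist
#' @export
degree_poisson <- function(z, k_max = NULL, kind = c("undirected", "directed")) {
  stopifnot(z > 0)
  if (is.null(k_max)) k_max <- qpois(1 - 1e-15, z) + 5L
  degree_dist(dpois(0:k_max, z), kind = match.arg(kind))
}

#' Regular (delta) degree distribution: every node has degree `k`
#' @param k the common degree.
#' @inheritParams degree_dist
#' @export
degree_regular <- function(k, kind = c("undirected", "directed")) {
  stopifnot(k >= 1)
  pmf <- numeric(k + 1)
  pmf[k + 1] <- 1
  degree_dist(pmf, kind = match.arg(kind))
}

#' Factorized joint degree distribution of a directed network
#'
#' Combines an in-degree and an out-degree marginal into the factorized joint
#' `p_jk = p_j^in p_k^out`.  Balanced networks require equal in- and out-mean
#' degree.
#'
#' @param p_in,p_out `degree_dist` objects (their `pmf` fields are used).
#' @param tol tolerance on the in/out mean-degree balance.
#' @export
degree_directed <- function(p_in, p_out, tol = 1e-8) {
  stopifnot(inherits(p_in, "degree_dist"), inherits(p_out, "degree_dist"))
  if (abs(p_in$z - p_out$z) > tol * max(1, p_out$z))
    stop("in- and out-degree means differ (", p_in$z, " vs ", p_out$z,
         "): directed degree distributions must be balanced")
  structure(list(kind = "directed-factorized", p_in = p_in, p_out = p_out,
                 z = p_out$z, alpha = p_out$alpha, k_min = p_out$k_min,
                 k_max = p_out$k_max),
            class = c("degree_directed", "degree_dist"))
}

#' Second factorial moment `<k^2 - k>` of a degree distribution
#' @param deg a `degree_dist`.
#' @export
second_factorial_moment <- function(deg) {
  pmf <- if (inherits(deg, "degree_directed")) deg$p_in$pmf else deg$pmf
  k <- seq_along(pmf) - 1
  sum(k * (k - 1) * pmf)
}

#' Critical threshold bound for the Centola-Macy model
#'
#' With thresholds uniform on `(0, theta_max)` the cascade condition sits at
#' criticality when `theta_max = <k^2 - k> / z`.
#' @param deg a `degree_dist` (undirected).
#' @export
theta_max_critical <- function(deg) second_factorial_moment(deg) / deg$z

#' Critical coupling bound for the neuronal model
#'
#' Edge weights uniform on `(0, phi_max)` give mean transmission probability
#' `phi_max / 2`, so the branching number on a network of mean degree `z` is
#' `phi_max z / 2`; criticality requires `phi_max = 2 / z`.
#' @param z mean (out-)degree.
#' @export
phi_max_critical <- function(z) 2 / z
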