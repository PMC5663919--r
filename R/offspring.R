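#' Offspring distributions of the avalanche branching process
#'
#' An `offspring_dist` holds the probabilities `q_k` that an activation
#' triggers `k` further potential activations, together with the branching
#' number `xi = sum k q_k`, tail metadata (`gamma`, `kappa`), and an analytic
#' generating-function backend.  `xi = 1` is the critical point.
#'
#' Supported parametric families:
#' * `poisson`: `q_k = Pois(xi)`, pgf `exp(xi (s - 1))`.
#' * `power_law`: `q_k = C k^-gamma` for `k >= 1`; `C = xi / zeta(gamma - 1)`
#'   calibrates the branching number and the residual mass sits at `k = 0`
#'   (`q_0 = 1 - C zeta(gamma)`).  For `2 < gamma < 3` the second moment is
#'   infinite (`f''(1) = Inf`).
#' * `truncated_power_law`: `q_k = C k^-gamma exp(-k/kappa)` for `k >= 1`;
#'   `C = xi / Li_{gamma-1}(e^{-1/kappa})`, residual mass at `k = 0`.
#' * `binary_fission`: `q_0 = 1 - p`, `q_2 = p` (exactly solvable case).
#' * `regular`: deterministic `k` offspring.
#'
#' @param family the parametric family.
#' @param xi target branching number (poisson, power_law,
#'   truncated_power_law; default 1 for the power-law families).
#' @param gamma tail exponent (> 2 unless a cutoff is present).
#' @param kappa exponential cutoff of the truncated power law.
#' @param p fission probability (binary_fission).
#' @param k offspring count (regular).
#' @param k_head length of the dense head `q_0..q_{k_head}` kept for
#'   tabulation and sampling of the heavy-tailed families.
#' @return an object of class `offspring_dist`.
#' @export
make_offspring <- function(family = c("poisson", "power_law",
                                      "truncated_power_law",
                                      "binary_fission", "regular"),
                           xi = NULL, gamma = NULL, kappa = NULL,
                           p = NULL, k = NULL, k_head = 1e4) {
  family <- match.arg(family)
  switch(family,
    poisson = {
      if (is.null(xi) || xi <= 0) stop("poisson family needs xi > 0")
      kmax <- qpois(1 - 1e-16, xi) + 10L
      new_offspring("poisson", list(xi = xi), q = dpois(0:kmax, xi),
                    q_complete = TRUE, xi = xi, second_moment_finite = TRUE)
    },
    power_law = {
      if (is.null(gamma)) stop("power_law family needs gamma")
      if (gamma <= 2)
        stop("divergent mean: power-law offspring with gamma <= 2 has no ",
             "branching number; add an exponential cutoff")
      if (is.null(xi)) xi <- 1
      C <- xi / pracma::zeta(gamma - 1)
      tail_mass <- C * pracma::zeta(gamma)
      if (tail_mass > 1 + 1e-12)
        stop("infeasible calibration: C = xi/zeta(gamma-1) = ", signif(C, 6),
             " puts probability ", signif(tail_mass, 6), " > 1 on k >= 1")
      kk <- seq_len(k_head)
      q <- c(1 - tail_mass, C * kk^(-gamma))
      new_offspring("power_law", list(xi = xi, gamma = gamma, C = C),
                    q = q, q_complete = FALSE, xi = xi, gamma = gamma,
                    C = C, second_moment_finite = gamma > 3)
    },
    truncated_power_law = {
      if (is.null(gamma) || is.null(kappa))
        stop("truncated_power_law family needs gamma and kappa")
      if (is.null(xi)) xi <- 1
      x0 <- exp(-1 / kappa)
      C <- xi / polylog(gamma - 1, x0)
      tail_mass <- C * polylog(gamma, x0)
      if (tail_mass > 1 + 1e-12)
        stop("infeasible calibration: required C = ", signif(C, 6),
             " puts probability ", signif(tail_mass, 6), " > 1 on k >= 1")
      kk <- seq_len(k_head)
      q <- c(1 - tail_mass, C * kk^(-gamma) * exp(-kk / kappa))
      new_offspring("truncated_power_law",
                    list(xi = xi, gamma = gamma, kappa = kappa, C = C),
                    q = q, q_complete = kappa * 45 < k_head, xi = xi,
                    gamma = gamma, kappa = kappa, C = C,
                    second_moment_finite = TRUE)
    },
    binary_fission = {
      if (is.null(p) || p < 0 || p > 1) stop("binary_fission needs p in [0, 1]")
      new_offspring("binary_fission", list(p = p), q = c(1 - p, 0, p),
                    q_complete = TRUE, xi = 2 * p, second_moment_finite = TRUE)
    },
    regular = {
      if (is.null(k) || k < 0) stop("regular family needs k >= 0")
      q <- numeric(k + 1)
      q[k + 1] <- 1
      new_offspring("regular", list(k = k), q = q, q_complete = TRUE,
                    xi = k, second_moment_finite = TRUE)
    })
}

new_offspring <- function(family, params, q, q_complete, xi,
                          gamma = NULL, kappa = NULL, C = NULL,
                          second_moment_finite = TRUE, hat = NULL) {
  if (any(q < -1e-12)) stop("offspring probabilities must be nonnegative")
  q <- pmax(q, 0)
  obj <- list(family = family, params = params, q = q,
              q_complete = q_complete, xi = xi, gamma = gamma, kappa = kappa,
              C = C, second_moment_finite = second_moment_finite, hat = hat)
  # polylog caches for the heavy-tail generating function and derivatives
  if (family %in% c("power_law", "truncated_power_law")) {
    obj$cache0 <- .polylog_cache(gamma)
    obj$cache1 <- .polylog_cache(gamma - 1)
    obj$cache2 <- .polylog_cache(gamma - 2)
  }
  structure(obj, class = "offspring_dist")
}

#' @export
print.offspring_dist <- function(x, ...) {
  cat("<offspring_dist>", x$family, " xi =", format(x$xi, digits = 8), "\n")
  if (!is.null(x$gamma)) cat("  tail gamma =", x$gamma,
                             if (!is.null(x$kappa)) paste(" kappa =", x$kappa),
                             " C =", signif(x$C, 6), "\n")
  invisible(x)
}

#' Degree-side hat distribution of the branching process
#'
#' Combines a degree distribution and a vulnerability model into the
#' quantities `qhat_k`: for an undirected network
#' `qhat_k = ((k+1)/z) p_{k+1} v_{k+1}` (probability that a random edge leads
#' to a vulnerable node with `k` further neighbors); for a directed network
#' `qhat_k = sum_j (j/z) p_jk v_jk` with the factorized joint
#' `p_jk = p_j^in p_k^out`.  The total `r = sum_k qhat_k` is the probability
#' that an edge-reached node is vulnerable, and
#' `xi = sum_k k qhat_k` equals the branching number of the offspring
#' distribution derived by [offspring_from_qhat()].
#'
#' @param deg a [degree_dist()] (use [degree_directed()] for directed nets).
#' @param vul a [vulnerability()] of matching directedness.
#' @return an object of class `qhat_dist` with fields `qk` (dense vector from
#'   `k = 0`), `r`, `xi`, `z`.
#' @export
qhat <- function(deg, vul) {
  stopifnot(inherits(deg, "degree_dist"), inherits(vul, "vulnerability"))
  directed <- inherits(deg, "degree_directed") || deg$kind != "undirected"
  if (directed != vul$directed)
    stop("degree distribution is ", if (directed) "directed" else "undirected",
         " but the vulnerability model is not")
  if (deg$z <= 0) stop("mean degree z = 0: no spreading is possible")
  if (!directed) {
    pmf <- deg$pmf
    K <- length(pmf) - 1L           # max degree
    k <- 0:(K - 1L)                 # remaining-degree support
    vv <- vul$v(k + 1)
    .check_v(vv)
    qk <- (k + 1) / deg$z * pmf[k + 2L] * vv
  } else {
    if (!inherits(deg, "degree_directed"))
      stop("directed qhat needs a factorized joint built with degree_directed()")
    p_out <- deg$p_out$pmf
    p_in <- deg$p_in$pmf
    k <- seq_along(p_out) - 1L
    w <- numeric(length(p_out))
    for (j in which(p_in > 0) - 1L) {
      if (j == 0) next                       # j/z factor vanishes
      vv <- vul$v(rep(j, length(k)), k)
      .check_v(vv)
      w <- w + (j / deg$z) * p_in[j + 1L] * vv
    }
    qk <- p_out * w
  }
  r <- sum(qk)
  if (r > 1 + 1e-10) stop("r = sum qhat_k = ", r, " exceeds 1")
  structure(list(qk = qk, r = r, xi = sum((seq_along(qk) - 1) * qk),
                 z = deg$z, deg = deg, vul = vul),
            class = "qhat_dist")
}

.check_v <- function(v) {
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("vulnerability values outside [0, 1]")
}

#' @export
print.qhat_dist <- function(x, ...) {
  cat("<qhat_dist> r =", format(x$r, digits = 8),
      " xi =", format(x$xi, digits = 8), "\n")
  invisible(x)
}

#' Offspring distribution from a hat distribution by binomial thinning
#'
#' The generating-function relation
#' `f(s) = (1/r) sum_k qhat_k (1 - r + r s)^k` is equivalent to
#' `q_k = (1/r) sum_{m >= k} qhat_m C(m, k) r^k (1 - r)^(m - k)`:
#' each of the `m` onward neighbors of an edge-reached vulnerable node is
#' itself vulnerable independently with probability `r`.  The branching
#' number is preserved: `sum k q_k = sum k qhat_k`.
#'
#' @param hat a [qhat()] result.
#' @param k_head for large supports, only the head `q_0..q_{k_head}` is
#'   tabulated (the generating function remains exact).
#' @export
offspring_from_qhat <- function(hat, k_head = NULL) {
  stopifnot(inherits(hat, "qhat_dist"))
  r <- hat$r
  if (r <= 0)
    stop("degenerate process: r = 0, no node reached along an edge is vulnerable")
  K <- length(hat$qk) - 1L
  complete <- K <= 4000
  if (is.null(k_head)) k_head <- if (complete) K else 1000L
  kmax <- if (complete) K else min(k_head, K)
  q <- vapply(0:kmax, function(k) {
    m <- k:K
    # restrict to the binomial bulk: dbinom(k, m, r) is negligible beyond it
    if (!complete && length(m) > 1) {
      hi <- ceiling((k + 1) / r + 200 + 50 * sqrt((k + 1) / max(r, 1e-6)))
      m <- m[m <= hi]
    }
    sum(hat$qk[m + 1L] * dbinom(k, m, r)) / r
  }, numeric(1))
  new_offspring("from_qhat", list(r = r), q = q, q_complete = complete,
                xi = hat$xi, second_moment_finite = TRUE, hat = hat)
}

#' Probability generating function of an offspring distribution
#'
#' Evaluates `f(s) = sum_k q_k s^k` (`order = 0`), `f'(s)` (`order = 1`) or
#' `f''(s)` (`order = 2`).  Heavy-tailed families use the analytic
#' polylogarithm form (exact to near machine precision); `f''(1)` returns
#' `Inf` for `2 < gamma < 3` without a cutoff, the infinite-variance case
#' responsible for nonsymmetric avalanche shapes.
#'
#' @param q an `offspring_dist`.
#' @param s evaluation points in `[0, 1]` (vectorized).
#' @param order 0, 1 or 2.
#' @export
gf <- function(q, s, order = 0) {
  stopifnot(inherits(q, "offspring_dist"))
  if (any(s < -1e-12) || any(s > 1 + 1e-12))
    stop("generating function argument s must lie in [0, 1]")
  s <- pmin(pmax(s, 0), 1)
  switch(q$family,
    poisson = {
      xi <- q$xi
      f <- exp(xi * (s - 1))
      switch(as.character(order), "0" = f, "1" = xi * f, "2" = xi^2 * f)
    },
    binary_fission = {
      p <- q$params$p
      switch(as.character(order),
             "0" = (1 - p) + p * s^2, "1" = 2 * p * s,
             "2" = rep(2 * p, length(s)))
    },
    regular = {
      k <- q$params$k
      switch(as.character(order),
             "0" = s^k, "1" = k * s^pmax(k - 1, 0),
             "2" = k * (k - 1) * s^pmax(k - 2, 0))
    },
    power_law = .gf_heavy(q, s, order, cutoff = FALSE),
    truncated_power_law = .gf_heavy(q, s, order, cutoff = TRUE),
    from_qhat = {
      y <- 1 - q$params$r + q$params$r * s
      hatk <- q$hat$qk
      kk <- seq_along(hatk) - 1
      vapply(seq_along(s), function(i) {
        switch(as.character(order),
               "0" = sum(hatk * y[i]^kk) / q$params$r,
               "1" = sum(hatk * kk * y[i]^pmax(kk - 1, 0)),
               "2" = q$params$r *
                 sum(hatk * kk * (kk - 1) * y[i]^pmax(kk - 2, 0)))
      }, numeric(1))
    },
    { # empirical dense
      kk <- seq_along(q$q) - 1
      vapply(s, function(si) switch(as.character(order),
        "0" = sum(q$q * si^kk),
        "1" = sum(q$q * kk * si^pmax(kk - 1, 0)),
        "2" = sum(q$q * kk * (kk - 1) * si^pmax(kk - 2, 0))), numeric(1))
    })
}

# Heavy-tail pgf via polylogarithms: f(s) = q0 + C Li_g(s x0), x0 = e^{-1/kappa}
.gf_heavy <- function(q, s, order, cutoff) {
  C <- q$C
  g <- q$gamma
  x0 <- if (cutoff) exp(-1 / q$kappa) else 1
  q0 <- q$q[1]
  if (order == 0)
    return(q0 + C * polylog(g, s * x0, cache = q$cache0))
  if (order == 1) {
    out <- numeric(length(s))
    pos <- s > 0
    out[pos] <- C * polylog(g - 1, s[pos] * x0, cache = q$cache1) / s[pos]
    out[!pos] <- q$q[2]                      # f'(0) = q_1
    return(out)
  }
  # order 2
  out <- numeric(length(s))
  at1 <- s >= 1 - 1e-300
  if (!cutoff && g < 3 && any(at1)) out[at1] <- Inf
  else if (any(at1))
    out[at1] <- C * (polylog(g - 2, x0, cache = q$cache2) -
                     polylog(g - 1, x0, cache = q$cache1))
  pos <- !at1 & s > 0
  out[pos] <- C * (polylog(g - 2, s[pos] * x0, cache = q$cache2) -
                   polylog(g - 1, s[pos] * x0, cache = q$cache1)) / s[pos]^2
  out[s <= 0] <- 2 * q$q[3]
  out
}

# f(s) - s with cancellation-safe forms where a closed form exists.
gf_minus_s <- function(q, s) {
  switch(q$family,
    poisson = {
      u <- 1 - s
      expm1(-q$xi * u) + u
    },
    binary_fission = (1 - s) * (1 - q$params$p * (1 + s)),
    gf(q, s, 0) - s)
}

#' Branching number and criticality regime
#'
#' `xi = sum_k k q_k = sum_k k qhat_k`; `xi = 1` separates subcritical from
#' supercritical avalanche dynamics.
#'
#' @param x an `offspring_dist`, a `qhat_dist`, or a bare pmf vector indexed
#'   from `k = 0`.
#' @param tol half-width of the "critical" band around 1.
#' @return the branching number with attribute `regime` in
#'   `c("subcritical", "critical", "supercritical")`.
#' @export
branching_number <- function(x, tol = 1e-9) {
  xi <- if (inherits(x, "offspring_dist") || inherits(x, "qhat_dist")) x$xi
        else sum((seq_along(x) - 1) * x)
  if (!is.finite(xi)) stop("divergent mean: branching number does not exist")
  regime <- if (abs(xi - 1) < tol) "critical"
            else if (xi < 1) "subcritical" else "supercritical"
  structure(xi, regime = regime)
}

#' Offspring tail exponent from network and dynamics exponents
#'
#' For degree tail `p_k ~ k^-alpha` and vulnerability decay `v_k ~ k^-nu`,
#' the offspring distribution tail is `q_k ~ k^-gamma` with
#' `gamma = alpha + nu - 1` (undirected) or `gamma = alpha + nu` (directed).
#' Nonsymmetric (left-skewed) average avalanche shapes arise at criticality
#' when `2 < gamma < 3`.
#'
#' @param alpha degree-distribution tail exponent (> 1).
#' @param nu vulnerability decay exponent.
#' @param mode `"undirected"` or `"directed"`.
#' @return list with `gamma` and logical `nonsymmetric`.
#' @export
offspring_exponent <- function(alpha, nu, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 1)
  gamma <- if (mode == "undirected") alpha + nu - 1 else alpha + nu
  list(gamma = gamma, nonsymmetric = gamma > 2 && gamma < 3)
}
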