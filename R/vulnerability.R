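#' Vulnerability models for cascade dynamics
#'
#' The vulnerability `v_k` (undirected) or `v_jk` (directed) is the
#' probability that a node of degree `k` (in-degree `j`, out-degree `k`)
#' activates when exactly one of its (in-)neighbors is active.  It is the
#' dynamics-specific ingredient of the offspring-distribution construction:
#'
#' * `watts`: threshold on the active *fraction* of neighbors, so
#'   `v_k = F(1/k)` with `F` the threshold CDF.  With thresholds uniform on
#'   `(0, theta_max)` the large-`k` decay exponent is `nu = 1`.
#' * `centola_macy`: threshold on the active *count*, so `v_k = F(1)`
#'   independent of degree (`nu = 0`).
#' * `neuronal`: edge weights uniform on `(0, phi_max)` give
#'   `v_jk = phi_max / 2` (`nu = 0`).
#' * `meme`: a screen holding the focal meme is retweeted before being
#'   overwritten with probability `v_jk ~ (1 - mu) / j` (`nu = 0` in the
#'   weighted in-degree sum).
#' * `custom`: any callable, with a declared decay exponent `nu`.
#'
#' @param model one of `"watts"`, `"centola_macy"`, `"neuronal"`, `"meme"`,
#'   `"custom"`.
#' @param theta_max upper bound of the uniform threshold distribution
#'   (threshold models).
#' @param F threshold CDF as a function (optional alternative to
#'   `theta_max`; requires `nu` for `watts`).
#' @param phi_max neuronal weight bound.
#' @param mu meme innovation probability.
#' @param v custom callable `v(k)` (undirected) or `v(j, k)` (directed).
#' @param nu declared large-`k` decay exponent of the vulnerability.
#' @param directed whether the callable is `v(j, k)` (custom only).
#' @return an object of class `vulnerability` with fields `model`, `v`,
#'   `nu`, `directed`, `params`.
#' @export
vulnerability <- function(model = c("watts", "centola_macy", "neuronal",
                                    "meme", "custom"),
                          theta_max = NULL, F = NULL, phi_max = NULL,
                          mu = NULL, v = NULL, nu = NULL, directed = NULL) {
  model <- match.arg(model)
  params <- list(theta_max = theta_max, phi_max = phi_max, mu = mu)
  out <- switch(model,
    watts = {
      if (is.null(F)) {
        if (is.null(theta_max)) stop("watts model needs `theta_max` or `F`")
        F <- function(x) pmin(1, pmax(0, x / theta_max))
        nu <- 1
      } else if (is.null(nu)) {
        stop("watts model with a custom CDF needs a declared `nu`")
      }
      list(v = function(k) F(1 / k), nu = nu, directed = FALSE, F = F)
    },
    centola_macy = {
      if (is.null(F)) {
        if (is.null(theta_max)) stop("centola_macy model needs `theta_max` or `F`")
        F <- function(x) pmin(1, pmax(0, x / theta_max))
      }
      v1 <- F(1)
      list(v = function(k) rep(v1, length(k)), nu = 0, directed = FALSE, F = F)
    },
    neuronal = {
      if (is.null(phi_max)) stop("neuronal model needs `phi_max`")
      if (phi_max < 0 || phi_max > 2) stop("phi_max must lie in [0, 2]")
      vv <- min(1, phi_max / 2)
      list(v = function(j, k) rep(vv, length(k)), nu = 0, directed = TRUE)
    },
    meme = {
      if (is.null(mu)) stop("meme model needs `mu`")
      if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
      list(v = function(j, k) {
             out <- ifelse(j >= 1, pmin(1, (1 - mu) / pmax(j, 1)), 0)
             rep_len(out, max(length(j), length(k)))
           }, nu = 0, directed = TRUE)
    },
    custom = {
      if (is.null(v) || is.null(nu) || is.null(directed))
        stop("custom model needs `v`, `nu` and `directed`")
      list(v = v, nu = nu, directed = directed)
    })
  structure(c(list(model = model, params = params), out),
            class = "vulnerability")
}

#' @export
print.vulnerability <- function(x, ...) {
  cat("<vulnerability>", x$model,
      if (x$directed) "(directed)" else "(undirected)",
      " nu =", x$nu, "\n")
  invisible(x)
}

#' Measured decay exponent of a vulnerability profile
#'
#' Least-squares log-log slope of `v_k` (at a reference in-degree for
#' directed models) over a degree window, used to verify the declared `nu`.
#'
#' @param vul a [vulnerability()].
#' @param k_range degree window, default `c(100, 10000)`.
#' @param j reference in-degree for directed callables.
#' @export
vul_decay_exponent <- function(vul, k_range = c(100, 10000), j = 10) {
  k <- unique(round(exp(seq(log(k_range[1]), log(k_range[2]), length.out = 60))))
  vv <- if (vul$directed) vul$v(rep(j, length(k)), k) else vul$v(k)
  if (any(vv <= 0)) return(0)  # flat-zero profiles have no decay to measure
  if (diff(range(log(vv))) < 1e-12) return(0)
  -unname(coef(lm(log(vv) ~ log(k)))[2])
}
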