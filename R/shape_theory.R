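#' Solve the extinction-probability equation
#'
#' The fraction `Q(t)` of continuous-time avalanches extinct by time `t`
#' satisfies `dQ/dt = f(Q) - Q` with `Q(0) = 0`, where `f` is the offspring
#' generating function.  The solution underlies every average-shape formula.
#' Lifetimes are unit-rate exponentials; a different rate only rescales the
#' time axis.
#'
#' @param q an [make_offspring()] / [offspring_from_qhat()] distribution.
#' @param t_max integrate up to this time.
#' @param tol relative and absolute solver tolerance.
#' @return an object of class `extinction_curve` with the time grid, `Q`
#'   values, a monotone-cubic interpolant, and the smallest root `q_ext` of
#'   `f(s) = s` (the ultimate extinction probability).
#' @export
solve_extinction <- function(q, t_max = 1000, tol = 1e-10) {
  stopifnot(inherits(q, "offspring_dist"), t_max > 0)
  if (q$q_complete && abs(sum(q$q) - 1) > 1e-8)
    stop("offspring distribution is not normalized")
  # dense linear grid early (Q varies fastest), geometric later
  lin_end <- min(20, t_max)
  times <- seq(0, lin_end, by = 0.01)
  if (t_max > lin_end) {
    n_geo <- max(20, ceiling(log(t_max / lin_end) / log(1.01)))
    geo <- lin_end * exp(seq(log(1.01), log(t_max / lin_end),
                             length.out = n_geo))
    times <- c(times, geo)
    # near-duplicate knots destroy cubic interpolation accuracy
    times <- times[c(TRUE, diff(times) > 1e-6)]
    if (t_max - times[length(times)] > 1e-6) times <- c(times, t_max)
    else times[length(times)] <- t_max
  }
  rhs <- function(t, y, parms) list(gf_minus_s(q, min(max(y[1], 0), 1)))
  # integrate two orders tighter than the advertised tolerance so the
  # delivered curve (including interpolation) honors `tol`
  sol <- deSolve::ode(c(Q = 0), times, rhs, NULL, rtol = tol / 100,
                      atol = tol / 100, method = "lsoda")
  Q <- pmin(pmax(cummax(sol[, 2]), 0), 1)
  q_ext <- .extinction_root(q)
  structure(list(times = sol[, 1], Q = Q,
                 Qfun = splinefun(sol[, 1], Q, method = "hyman"),
                 offspring = q, tol = tol, t_max = t_max, q_ext = q_ext),
            class = "extinction_curve")
}

# smallest root of f(s) = s on [0, 1]
.extinction_root <- function(q) {
  if (q$xi <= 1 + 1e-12) return(1)
  g <- function(s) gf_minus_s(q, s)
  if (g(0) <= 0) return(0)
  uniroot(g, c(0, 1 - 1e-9), tol = 1e-14)$root
}

#' Evaluate an extinction curve
#' @param curve an [solve_extinction()] result.
#' @param t times within `[0, t_max]`.
#' @export
extinction_at <- function(curve, t) {
  stopifnot(inherits(curve, "extinction_curve"))
  if (any(t < -1e-9) || any(t > curve$t_max + 1e-9))
    stop("time outside the solved range [0, ", curve$t_max, "]")
  pmin(pmax(curve$Qfun(pmax(t, 0)), 0), 1)
}

#' @export
print.extinction_curve <- function(x, ...) {
  cat("<extinction_curve> t in [0,", x$t_max, "]  Q(t_max) =",
      format(x$Q[length(x$Q)], digits = 8), " q_ext =",
      format(x$q_ext, digits = 8), "\n")
  invisible(x)
}

# Interpolation-contract check: re-integrate the ODE with output at the
# grid midpoints and compare against the stored interpolant.
extinction_residual <- function(curve) {
  tm <- (head(curve$times, -1) + tail(curve$times, -1)) / 2
  q <- curve$offspring
  rhs <- function(t, y, parms) list(gf_minus_s(q, min(max(y[1], 0), 1)))
  sol <- deSolve::ode(c(Q = 0), sort(c(0, tm)), rhs, NULL,
                      rtol = curve$tol / 100, atol = curve$tol / 100,
                      method = "lsoda")
  max(abs(curve$Qfun(sol[, 1]) - sol[, 2]))
}

.new_shape <- function(t, value, T, kind, timescale, rescaled = FALSE) {
  structure(list(t = t, value = value, T = T, kind = kind,
                 timescale = timescale, rescaled = rescaled),
            class = "shape_curve")
}

#' @export
print.shape_curve <- function(x, ...) {
  cat("<shape_curve>", x$kind, x$timescale, " T =", x$T,
      " peak =", format(max(x$value), digits = 6),
      " at t/T =", format(x$t[which.max(x$value)] / max(x$T, 1), digits = 4),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.shape_curve <- function(x, ...) {
  data.frame(t = x$t, t_over_T = if (x$T > 0) x$t / x$T else x$t,
             value = x$value,
             value_rescaled = if (max(x$value) > 0) x$value / max(x$value)
                              else x$value,
             kind = x$kind, T = x$T)
}

#' Average avalanche shape, continuous time
#'
#' For avalanches of duration `T`, the average event profile is
#' `A(t) = Q(T-t) [f'(Q(T)) - f'(Q(T-t))] / [f(Q(T-t)) - Q(T-t)]`,
#' evaluated pointwise from the extinction curve.  Both endpoints vanish
#' exactly and are returned as exact zeros.  Conditioning is on termination
#' at `T`, so the formula applies to super- as well as subcritical processes.
#'
#' Note `A(t)` equals `E[Z_t | duration = T] - 1`, the mean number of
#' concurrently active individuals minus the surviving line; simulation
#' estimators based on alive counts are compared against `1 + A(t)`.
#'
#' @inheritParams solve_extinction
#' @param T avalanche duration.
#' @param n_points number of evaluation points on `[0, T]`.
#' @param curve optionally a pre-solved [solve_extinction()] covering `T`.
#' @return a `shape_curve`.
#' @export
avalanche_shape_ct <- function(q, T, n_points = 201, curve = NULL) {
  stopifnot(T > 0)
  if (is.null(curve)) curve <- solve_extinction(q, t_max = max(2 * T, 1000))
  if (T > curve$t_max) stop("T exceeds the solved extinction-curve range")
  q <- curve$offspring
  t <- seq(0, T, length.out = n_points)
  QT <- extinction_at(curve, T)
  QTt <- extinction_at(curve, T - t)
  fpT <- gf(q, QT, 1)
  A <- QTt * (fpT - gf(q, QTt, 1)) / gf_minus_s(q, QTt)
  A[1] <- 0
  A[n_points] <- 0
  A[!is.finite(A) | A < 0] <- 0
  .new_shape(t, A, T, "terminating", "continuous")
}

#' Average avalanche shape, discrete time
#'
#' For the Galton-Watson chain `Q_{n+1} = f(Q_n)`, `Q_0 = 0`, the average
#' per-step count of avalanches with duration exactly `T` (last nonzero
#' generation at step `T`) is
#' `A(t) = (E[Z_t 1\{ext by T+1\}] - E[Z_t 1\{ext by T\}]) / (Q_{T+1} - Q_T)`
#' with `E[Z_t 1\{ext by u\}] = Q_{u-t} prod_{m=u-t}^{u-1} f'(Q_m)` from the
#' composition rule of iterated generating functions.  `A(0) = 1` exactly
#' (the seed).
#'
#' @inheritParams avalanche_shape_ct
#' @param T integer duration (>= 1).
#' @export
avalanche_shape_dt <- function(q, T) {
  stopifnot(inherits(q, "offspring_dist"), T >= 1, T == round(T))
  T <- as.integer(T)
  Qs <- numeric(T + 2)                     # Qs[n+1] = Q_n
  for (n in seq_len(T + 1)) Qs[n + 1] <- gf(q, Qs[n], 0)
  dQ <- Qs[T + 2] - Qs[T + 1]
  if (dQ <= 0)
    stop("empty conditioning: no avalanche has duration exactly T = ", T)
  fp <- gf(q, Qs, 1)                       # f'(Q_m), m = 0..T+1
  Ezu <- function(u) {                     # E[Z_t 1{ext by u}] for t = 0..T
    vapply(0:T, function(t) {
      pr <- if (t == 0) 1 else prod(fp[seq.int(u - t, u - 1) + 1])
      Qs[u - t + 1] * pr
    }, numeric(1))
  }
  A <- (Ezu(T + 1L) - Ezu(T)) / dQ
  .new_shape(0:T, A, T, "terminating", "discrete")
}

#' Average shape of avalanches still alive at an observation time
#'
#' The mean number of active individuals at `t <= T` among avalanches that
#' have not terminated by `T`:
#' `A_nt(t) = (m_t - Q(T-t) [f(Q(T)) - Q(T)] / [f(Q(T-t)) - Q(T-t)]) / (1 - Q(T))`
#' with `m_t = exp((xi - 1) t)` the unconditional mean.  `A_nt(0) = 1`
#' exactly; at criticality the rescaled curves collapse onto a half-parabola
#' when `f''(1)` is finite.
#'
#' @inheritParams avalanche_shape_ct
#' @param T observation time.
#' @export
nonterminating_shape <- function(q, T, n_points = 201, curve = NULL) {
  stopifnot(T > 0)
  if (is.null(curve)) curve <- solve_extinction(q, t_max = max(2 * T, 1000))
  q <- curve$offspring
  QT <- extinction_at(curve, T)
  if (1 - QT <= 1e-12)
    stop("survival probability at T = ", T, " is numerically zero")
  t <- seq(0, T, length.out = n_points)
  QTt <- extinction_at(curve, T - t)
  m_t <- exp((q$xi - 1) * t)
  A <- (m_t - QTt * gf_minus_s(q, QT) / gf_minus_s(q, QTt)) / (1 - QT)
  A[1] <- 1
  .new_shape(t, A, T, "nonterminating", "continuous")
}

#' Mean number of events per unit time, unconditioned
#'
#' `exp((xi - 1) t)` in continuous time (unit rate), `xi^t` per step in
#' discrete time: decaying when subcritical, constant at criticality,
#' growing when supercritical — the simplest criticality diagnostic.
#'
#' @inheritParams avalanche_shape_ct
#' @param t times (vectorized), `t >= 0`.
#' @param timescale `"continuous"` or `"discrete"`.
#' @export
mean_events <- function(q, t, timescale = c("continuous", "discrete")) {
  timescale <- match.arg(timescale)
  stopifnot(all(t >= 0))
  if (timescale == "continuous") exp((q$xi - 1) * t) else q$xi^t
}

#' Asymptotic critical avalanche shape (up to the prefactor)
#'
#' In the large-`T` critical limit the shape is `C (t/T) (T - t)` when
#' `f''(1)` is finite (parabolic, peak at `T/2`) and
#' `C (t/T) (T - t)^{1/(gamma-2)}` for a power-law offspring tail with
#' `2 < gamma < 3` (left-skewed, peak at `(gamma-2) T / (gamma-1)`).
#'
#' @param tail `"finite_second_moment"` or `"power_law"`.
#' @param T duration.
#' @param t evaluation times (default a 201-point grid).
#' @param gamma tail exponent for the power-law branch.
#' @export
asymptotic_shape <- function(tail = c("finite_second_moment", "power_law"),
                             T, t = NULL, gamma = NULL) {
  tail <- match.arg(tail)
  if (is.null(t)) t <- seq(0, T, length.out = 201)
  stopifnot(all(t >= 0), all(t <= T))
  if (tail == "finite_second_moment") {
    v <- t / T * (T - t)
  } else {
    if (is.null(gamma) || gamma <= 2 || gamma >= 3)
      stop("power-law branch requires 2 < gamma < 3")
    v <- t / T * (T - t)^(1 / (gamma - 2))
  }
  .new_shape(t, v, T, "asymptotic", "continuous")
}

#' Peak location of the asymptotic critical shape, as a fraction of `T`
#'
#' `1/2` for finite second moment; `(gamma - 2)/(gamma - 1)` for a power-law
#' offspring tail with `2 < gamma < 3` (continuous at `gamma -> 3`).
#'
#' @param gamma `NULL` for the finite-second-moment branch.
#' @export
peak_location <- function(gamma = NULL) {
  if (is.null(gamma)) return(0.5)
  stopifnot(gamma > 2, gamma <= 3)
  (gamma - 2) / (gamma - 1)
}

#' Asymptotic coefficient of variation of the avalanche shape
#'
#' At criticality and large `T`, the CV of the set of profiles at rescaled
#' time `x = t/T` is `1/sqrt(2)` (independent of `x`) when `f''(1)` is
#' finite, and `sqrt((3 - gamma + (gamma-2) x) / ((gamma-1) x))` for a
#' power-law tail with `2 < gamma < 3`; the latter diverges like
#' `1/sqrt(t)` as `t -> 0` (returned as `Inf` at `x = 0`).
#'
#' @param x rescaled times `t/T` in `(0, 1]` (vectorized; `x = 0` allowed
#'   only as the divergence sentinel of the power-law branch).
#' @param gamma `NULL` for the finite-second-moment branch.
#' @export
cv_asymptotic <- function(x, gamma = NULL) {
  if (is.null(gamma)) {
    stopifnot(all(x >= 0), all(x <= 1))
    return(rep(1 / sqrt(2), length(x)))
  }
  stopifnot(gamma > 2, gamma < 3, all(x >= 0), all(x <= 1))
  out <- rep(Inf, length(x))
  pos <- x > 0
  out[pos] <- sqrt((3 - gamma + (gamma - 2) * x[pos]) / ((gamma - 1) * x[pos]))
  out
}

#' Rescale a shape curve to collapse coordinates
#'
#' Maps time to `t/T` and divides heights by the maximum, the rescaling used
#' to exhibit shape collapse across durations at criticality.
#' @param sc a `shape_curve`.
#' @export
rescale_shape <- function(sc) {
  stopifnot(inherits(sc, "shape_curve"))
  mx <- max(sc$value)
  if (mx <= 0) stop("cannot rescale a zero-height shape curve")
  .new_shape(sc$t / sc$T, sc$value / mx, 1, sc$kind, sc$timescale,
             rescaled = TRUE)
}
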