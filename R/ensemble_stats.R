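# Internal: combine one ensemble or a replica list into a list of ensembles.
.as_replicas <- function(ensembles) {
  if (inherits(ensembles, "avalanche_ensemble")) return(list(ensembles))
  stopifnot(is.list(ensembles), length(ensembles) >= 1,
            all(vapply(ensembles, inherits, logical(1), "avalanche_ensemble")))
  ensembles
}

# Per-position mean/variance of zero-padded selected profiles.
.profile_moments <- function(ens, idx, nb) {
  mom <- profile_moments_cpp(ens$profiles, as.integer(idx), as.integer(nb))
  n <- mom$n
  mean <- mom$sum / n
  varr <- if (n > 1) (mom$sumsq - n * mean^2) / (n - 1) else rep(NA_real_, nb)
  list(mean = mean, var = pmax(varr, 0), n = n)
}

.profile_grid <- function(ens, T) {
  if (ens$timescale == "discrete") {
    nb <- as.integer(T) + 1L
    list(t = 0:(nb - 1L), nb = nb, scale = 1)
  } else {
    nb <- as.integer(floor(T / ens$bin + 0.5))
    scale <- if (ens$observable == "events") 1 / ens$bin else 1
    list(t = (seq_len(nb) - 0.5) * ens$bin, nb = nb, scale = scale)
  }
}

.select_duration <- function(ens, T) {
  if (ens$timescale == "discrete") which(ens$terminated & ens$durations == T)
  else which(ens$terminated & ens$durations > T - ens$bin &
               ens$durations <= T)
}

.new_estimate <- function(t, value, replica_sd, n, T, kind, ens) {
  structure(list(t = t, value = value, replica_sd = replica_sd, n = n,
                 T = T, kind = kind, timescale = ens$timescale,
                 observable = ens$observable, bin = ens$bin,
                 model = ens$model),
            class = c("shape_estimate", "shape_curve"))
}

#' Average avalanche shape from simulated ensembles
#'
#' Averages the profiles `V_a(t)` of all avalanches in the duration bin
#' `(T - bin, T]` (continuous time) or with duration exactly `T` (discrete
#' time), within each replica, then across replicas.  Continuous-time event
#' counts are divided by the bin width (rate per unit time).  Error bars
#' are the across-replica standard deviation, the convention used for
#' replica experiments.
#'
#' @param ensembles an `avalanche_ensemble` or a list of them (replicas).
#' @param T target duration.
#' @return a `shape_estimate` with fields `t`, `value`, `replica_sd`, `n`.
#' @export
average_shape <- function(ensembles, T) {
  reps <- .as_replicas(ensembles)
  g <- .profile_grid(reps[[1]], T)
  per <- lapply(reps, function(ens) {
    idx <- .select_duration(ens, T)
    if (length(idx) == 0) return(NULL)
    m <- .profile_moments(ens, idx, g$nb)
    list(value = m$mean * g$scale, n = m$n)
  })
  keep <- !vapply(per, is.null, logical(1))
  if (!any(keep))
    stop("empty duration bin: no avalanche terminates in (",
         T - reps[[1]]$bin, ", ", T, "]")
  vals <- vapply(per[keep], `[[`, numeric(g$nb), "value")
  vals <- matrix(vals, nrow = g$nb)
  value <- rowMeans(vals)
  rsd <- if (sum(keep) > 1) apply(vals, 1, sd) else rep(NA_real_, g$nb)
  .new_estimate(g$t, value, rsd, sum(vapply(per[keep], `[[`, numeric(1), "n")),
                T, "terminating", reps[[1]])
}

#' Average shape of avalanches not yet terminated at an observation time
#'
#' Averages `V_a(t)` for `t` in `[0, T_obs]` over all avalanches whose
#' duration exceeds `T_obs` (censored records included).  At criticality
#' with finite `f''(1)` the rescaled curve approaches the half-parabola
#' `(t/T)(2 - t/T)`.
#'
#' @inheritParams average_shape
#' @param T_obs observation time.
#' @export
nonterminating_average <- function(ensembles, T_obs) {
  reps <- .as_replicas(ensembles)
  g <- .profile_grid(reps[[1]], T_obs)
  per <- lapply(reps, function(ens) {
    idx <- which(ens$durations > T_obs)
    if (length(idx) == 0) return(NULL)
    m <- .profile_moments(ens, idx, g$nb)
    list(value = m$mean * g$scale, n = m$n)
  })
  keep <- !vapply(per, is.null, logical(1))
  if (!any(keep)) stop("no avalanche is alive at T_obs = ", T_obs)
  vals <- matrix(vapply(per[keep], `[[`, numeric(g$nb), "value"), nrow = g$nb)
  value <- rowMeans(vals)
  rsd <- if (sum(keep) > 1) apply(vals, 1, sd) else rep(NA_real_, g$nb)
  .new_estimate(g$t, value, rsd, sum(vapply(per[keep], `[[`, numeric(1), "n")),
                T_obs, "nonterminating", reps[[1]])
}

#' Average number of events per unit time, over all avalanches
#'
#' Unconditional average of `V_a(t)` including terminated avalanches as
#' zero: decaying for subcritical, flat for critical, growing for
#' supercritical dynamics.  Also reports the late-time mean (average over
#' the second half of the time range), the constant plotted as the
#' reference line in events-per-time diagnostics.
#'
#' @inheritParams average_shape
#' @param t_max diagnostic horizon (default the ensemble `t_cap`).
#' @export
events_per_time <- function(ensembles, t_max = NULL) {
  reps <- .as_replicas(ensembles)
  if (is.null(t_max)) t_max <- reps[[1]]$t_cap
  g <- .profile_grid(reps[[1]], t_max)
  per <- vapply(reps, function(ens) {
    m <- .profile_moments(ens, seq_len(ens$n_A), g$nb)
    m$mean * g$scale
  }, numeric(g$nb))
  per <- matrix(per, nrow = g$nb)
  value <- rowMeans(per)
  rsd <- if (length(reps) > 1) apply(per, 1, sd) else rep(NA_real_, g$nb)
  est <- .new_estimate(g$t, value, rsd, sum(vapply(reps, `[[`, numeric(1),
                                                   "n_A")),
                       t_max, "events_per_time", reps[[1]])
  est$late_time_mean <- mean(value[g$t > t_max / 2])
  est
}

#' Variance and coefficient of variation of the avalanche shape
#'
#' Per-time-point sample variance of the set `{V_a(t) : a in S_T}` of
#' profiles with duration in the bin at `T` (pooled across replicas), and
#' the coefficient of variation `sqrt(variance)/mean`.  Points whose mean
#' count falls below `min_mean_count / n` are reported as `NA` to avoid
#' division blow-ups; the threshold is recorded on the result.
#'
#' @inheritParams average_shape
#' @param min_mean_count reliability threshold for the CV denominator.
#' @export
shape_variance <- function(ensembles, T, min_mean_count = 5) {
  reps <- .as_replicas(ensembles)
  g <- .profile_grid(reps[[1]], T)
  sums <- rep(0, g$nb); sumsq <- rep(0, g$nb); n <- 0
  for (ens in reps) {
    idx <- .select_duration(ens, T)
    if (length(idx) == 0) next
    mom <- profile_moments_cpp(ens$profiles, as.integer(idx),
                               as.integer(g$nb))
    sums <- sums + mom$sum * g$scale
    sumsq <- sumsq + mom$sumsq * g$scale^2
    n <- n + mom$n
  }
  if (n < 2) stop("need at least two avalanches in the duration bin at T = ", T)
  mean <- sums / n
  varr <- pmax((sumsq - n * mean^2) / (n - 1), 0)
  cv <- rep(NA_real_, g$nb)
  ok <- mean > min_mean_count / n
  cv[ok] <- sqrt(varr[ok]) / mean[ok]
  out <- .new_estimate(g$t, varr, rep(NA_real_, g$nb), n, T, "cv", reps[[1]])
  out$mean <- mean
  out$cv <- cv
  out$min_mean_count <- min_mean_count
  out
}

#' Rescaled shape collapse across durations
#'
#' Maps each curve to rescaled time `t/T` on a common grid (linear
#' interpolation), divides by its maximum, and reports pairwise
#' sup-distances — the collapse statistic whose smallness across durations
#' is the signature of criticality.
#'
#' @param curves list of `shape_curve` / `shape_estimate` objects (>= 2).
#' @param n_grid number of points of the common `t/T` grid.
#' @param metric `"sup"` (default) or `"l2"`.
#' @return list with the grid `x`, the matrix of rescaled curves, the
#'   pairwise distance matrix and the collapse statistic `stat` (max over
#'   pairs).
#' @export
rescale_collapse <- function(curves, n_grid = 101, metric = c("sup", "l2")) {
  metric <- match.arg(metric)
  stopifnot(is.list(curves), length(curves) >= 2)
  x <- seq(0, 1, length.out = n_grid)
  mat <- vapply(curves, function(cc) {
    stopifnot(inherits(cc, "shape_curve"))
    if (max(cc$value) <= 0) stop("cannot rescale a zero-height curve")
    y <- approx(cc$t / cc$T, cc$value, xout = x, rule = 2)$y
    y / max(y)
  }, numeric(n_grid))
  m <- length(curves)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    diff <- mat[, i] - mat[, j]
    d[i, j] <- d[j, i] <- if (metric == "sup") max(abs(diff))
                          else sqrt(mean(diff^2))
  }
  list(x = x, curves = mat, pairwise = d, stat = max(d))
}

#' Least-squares log-log slope of a positive curve
#'
#' Fitted exponent of `value ~ t^slope` over a window, used for
#' survival-function and offspring-tail exponent checks.
#'
#' @param x times/abscissa (or a `shape_curve`, in which case `y` is taken
#'   from it).
#' @param y values.
#' @param t_lo,t_hi fit window (a decade or more is recommended).
#' @export
loglog_slope <- function(x, y = NULL, t_lo, t_hi) {
  if (inherits(x, "shape_curve")) { y <- x$value; x <- x$t }
  sel <- x >= t_lo & x <= t_hi
  if (!any(sel)) stop("empty fit window")
  if (any(y[sel] <= 0)) stop("non-positive values inside the fit window")
  unname(coef(lm(log(y[sel]) ~ log(x[sel])))[2])
}

#' @export
print.shape_estimate <- function(x, ...) {
  cat("<shape_estimate>", x$kind, x$timescale, " T =", x$T,
      " n =", x$n, " points =", length(x$t), "\n")
  invisible(x)
}

#' @export
as.data.frame.shape_estimate <- function(x, ...) {
  data.frame(t = x$t, value = x$value, replica_sd = x$replica_sd,
             n_contributing = x$n)
}
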