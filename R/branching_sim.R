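# Sampling representation of an offspring distribution for the C++ engines:
# a cdf over the dense head (renormalized; the missing tail mass of the
# heavy-tailed families is below ~1e-7 at the default head length), or the
# exact Poisson sampler.
.offspring_sampler <- function(q) {
  if (q$family == "poisson")
    return(list(cdf = numeric(0), pois = 1L, xi = q$xi))
  miss <- 1 - sum(q$q)
  if (miss > 1e-6)
    warning("offspring head misses probability ", signif(miss, 3),
            "; sampling truncates there (increase k_head)")
  cdf <- cumsum(q$q) / sum(q$q)
  cdf[length(cdf)] <- 1
  list(cdf = cdf, pois = 0L, xi = q$xi)
}

#' Simulate a single discrete Galton-Watson avalanche
#'
#' Generation sizes `Z_0 = 1`, `Z_{t+1} = ` sum of `Z_t` offspring draws.
#' The per-step counts are the avalanche profile; duration is the last step
#' with `Z_t > 0`; size is the total number of individuals.
#'
#' @param q an `offspring_dist`.
#' @param t_cap censoring step count.
#' @return an `avalanche_record` with `counts`, `duration`, `size`,
#'   `terminated`.
#' @export
simulate_gw <- function(q, t_cap = 100) {
  s <- .offspring_sampler(q)
  sim <- gw_ensemble_cpp(s$cdf, s$pois, s$xi, 1L, as.integer(t_cap))
  structure(list(counts = sim$profiles[[1]], duration = sim$durations[1],
                 size = sim$sizes[1], terminated = sim$terminated[1],
                 timescale = "discrete"),
            class = "avalanche_record")
}

#' Simulate a single continuous-time Markov branching avalanche
#'
#' Every alive individual carries an independent exponential clock with the
#' given rate; at its event it dies and produces `k ~ q_k` children.
#' Implemented as a global next-event draw (exponential with rate
#' `rate * alive`, uniformly attributed), which is distributionally
#' equivalent.  Event (branching) times are recorded; the duration is the
#' time of the last event.
#'
#' @param q an `offspring_dist`.
#' @param rate branching rate per individual.
#' @param t_cap censoring time.
#' @export
simulate_markov_ct <- function(q, rate = 1, t_cap = 100) {
  stopifnot(rate > 0)
  s <- .offspring_sampler(q)
  sim <- ct_single_cpp(s$cdf, s$pois, s$xi, rate, t_cap)
  structure(list(event_times = sim$event_times, duration = sim$duration,
                 size = max(1L, length(sim$event_times)),
                 terminated = sim$terminated, timescale = "continuous"),
            class = "avalanche_record")
}

#' @export
print.avalanche_record <- function(x, ...) {
  cat("<avalanche_record>", x$timescale, " duration =", x$duration,
      " size =", x$size, if (!x$terminated) " (censored)", "\n")
  invisible(x)
}

#' Run replicated avalanche ensembles
#'
#' Simulates `n_A` avalanches per replica, `n_R` replicas, with independent
#' per-replica RNG sub-streams derived deterministically from one master
#' seed, so a run is exactly reproducible.  Randomization follows the
#' simulation protocol of the cascade models: a fresh seed node per
#' avalanche, and edge weights (neuronal) or thresholds (threshold models)
#' redrawn per avalanche.
#'
#' @param model a list describing the model:
#'   `list(type = "ct", offspring = q, rate = 1)`,
#'   `list(type = "gw", offspring = q)`,
#'   `list(type = "meme", net = net, mu = 0)`,
#'   `list(type = "neuronal", net = net, phi_max = ...)`, or
#'   `list(type = "watts"/"centola_macy", net = net, theta_max = ...)`.
#' @param n_A avalanches per replica.
#' @param n_R number of replicas.
#' @param seed master seed (integer).
#' @param bin profile bin width for continuous-time models.
#' @param t_cap censoring time (steps for discrete models).
#' @param replica_seeds optional explicit per-replica seeds (overrides the
#'   derived sub-streams; e.g. identical seeds give identical replicas).
#' @return a list of `avalanche_ensemble` objects, one per replica.
#' @export
run_ensemble <- function(model, n_A, n_R = 1, seed = 1, bin = 0.5,
                         t_cap = NULL, replica_seeds = NULL) {
  stopifnot(n_A >= 1, n_R >= 1)
  if (is.null(replica_seeds)) {
    set.seed(seed)
    replica_seeds <- sample.int(.Machine$integer.max - 1, n_R)
  }
  stopifnot(length(replica_seeds) == n_R)
  lapply(seq_len(n_R), function(r) {
    set.seed(replica_seeds[r])
    ens <- .run_one_ensemble(model, n_A, bin, t_cap)
    ens$replica <- r
    ens$seed <- replica_seeds[r]
    ens
  })
}

.run_one_ensemble <- function(model, n_A, bin, t_cap) {
  type <- model$type
  if (type %in% c("ct", "gw")) {
    q <- model$offspring
    stopifnot(inherits(q, "offspring_dist"))
    s <- .offspring_sampler(q)
    if (type == "gw") {
      if (is.null(t_cap)) t_cap <- 100
      sim <- gw_ensemble_cpp(s$cdf, s$pois, s$xi, as.integer(n_A),
                             as.integer(t_cap))
      return(.new_ensemble(sim, model, 1, t_cap, "discrete", "events"))
    }
    rate <- if (is.null(model$rate)) 1 else model$rate
    if (is.null(t_cap)) t_cap <- 100
    sim <- ct_ensemble_cpp(s$cdf, s$pois, s$xi, rate, as.integer(n_A),
                           t_cap, bin)
    return(.new_ensemble(sim, model, bin, t_cap, "continuous", "activity"))
  }
  if (is.null(t_cap)) t_cap <- 50
  switch(type,
    meme = run_meme_model(model$net, model$mu, n_A, t_cap = t_cap, bin = bin),
    neuronal = run_neuronal_model(model$net, model$phi_max, n_A,
                                  t_cap = t_cap),
    watts = ,
    centola_macy = run_threshold_model(model$net, type, model$theta_max,
                                       n_A, t_cap = t_cap),
    stop("unknown model type: ", type))
}
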