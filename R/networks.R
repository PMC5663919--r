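#' Sample degrees from a truncated power-law distribution
#'
#' I.i.d. draws from `p_k` proportional to `k^-alpha` for `k >= k_min`
#' (zero below `k_min`), the degree law used for the scale-free cascade
#' substrates.
#'
#' @param n number of draws.
#' @param alpha tail exponent (> 2 unless `k_max` truncates deliberately).
#' @param k_min minimum degree.
#' @param k_max support truncation.
#' @return integer vector with attribute `mean_analytic` (the untruncated
#'   zeta-function mean from [powerlaw_mean()]).
#' @export
sample_powerlaw_degrees <- function(n, alpha, k_min = 1L, k_max = 1e6) {
  if (alpha <= 2 && k_max > 1e7)
    stop("alpha <= 2 has infinite mean; supply a finite k_max")
  k <- k_min:k_max
  cdf <- cumsum(k^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  d <- k_min + findInterval(runif(n), cdf)
  attr(d, "mean_analytic") <- if (alpha > 2) powerlaw_mean(alpha, k_min) else NA
  d
}

.new_net <- function(N, offs, targ, directed, meta = list()) {
  structure(list(N = as.integer(N), offs = as.integer(offs),
                 targ = as.integer(targ), directed = directed, meta = meta),
            class = "cascade_net")
}

#' @export
print.cascade_net <- function(x, ...) {
  cat("<cascade_net>", if (x$directed) "directed" else "undirected",
      " N =", x$N, " edges =", length(x$targ),
      if (!x$directed) "(stored once per direction)", "\n")
  invisible(x)
}

#' Out-degrees of a network
#' @param net a `cascade_net`.
#' @export
out_degrees <- function(net) diff(net$offs)

#' In-degrees of a directed network
#' @param net a `cascade_net`.
#' @export
in_degrees <- function(net) {
  stopifnot(net$directed)
  tabulate(net$targ + 1L, nbins = net$N)
}

# transpose CSR (in-adjacency), cached on the object by callers
.transpose_csr <- function(net) {
  o <- order(net$targ)
  ioffs <- c(0L, cumsum(tabulate(net$targ + 1L, nbins = net$N)))
  src <- rep.int(seq_len(net$N) - 1L, diff(net$offs))
  list(ioffs = as.integer(ioffs), itarg = as.integer(src[o]))
}

#' Directed network with prescribed out-degrees and uniform targets
#'
#' Every node's followers are chosen uniformly at random without
#' replacement from the other nodes, so in- and out-degrees are
#' independent and the in-degree distribution is asymptotically
#' Poisson with the same mean.
#'
#' @param out_deg integer vector of out-degrees (each `< N`).
#' @export
net_directed <- function(out_deg) {
  N <- length(out_deg)
  if (any(out_deg >= N)) stop("out-degree must be smaller than N")
  targ <- vector("list", N)
  for (i in seq_len(N)) {
    k <- out_deg[i]
    if (k == 0) { targ[[i]] <- integer(0); next }
    tt <- sample.int(N - 1L, k)           # uniform, no self, no duplicates
    tt[tt >= i] <- tt[tt >= i] + 1L
    targ[[i]] <- tt - 1L
  }
  .new_net(N, c(0L, cumsum(out_deg)), unlist(targ), TRUE,
           meta = list(kind = "directed-uniform-targets"))
}

#' z-regular directed network (every node has exactly `z` followers)
#' @param N number of nodes.
#' @param z common out-degree.
#' @export
net_zregular_directed <- function(N, z) net_directed(rep.int(z, N))

#' Undirected configuration-model network
#'
#' Simple graph with the prescribed degree sequence, built with the
#' Viger-Latapy sampler (connected simple realization) and falling back to
#' degree-preserving edge switching of a stub-matching start when the
#' sequence is not suitable for it.
#'
#' @param degrees integer degree sequence (even sum).
#' @export
net_undirected_config <- function(degrees) {
  if (sum(degrees) %% 2 != 0) stop("degree sequence has odd stub total")
  # vl warns (harmlessly) on sequences with a unique realization
  g <- tryCatch(suppressWarnings(igraph::sample_degseq(degrees, method = "vl")),
                error = function(e)
                  igraph::sample_degseq(degrees, method = "fast.heur.simple"))
  .igraph_to_net(g, directed = FALSE,
                 meta = list(kind = "undirected-configuration"))
}

.igraph_to_net <- function(g, directed, meta = list()) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  N <- igraph::vcount(g)
  if (!directed) el <- rbind(el, el[, 2:1, drop = FALSE])
  o <- order(el[, 1], el[, 2])
  src <- el[o, 1]
  offs <- c(0L, cumsum(tabulate(src + 1L, nbins = N)))
  .new_net(N, offs, el[o, 2], directed, meta = meta)
}

.net_to_igraph <- function(net) {
  src <- rep.int(seq_len(net$N) - 1L, diff(net$offs))
  el <- cbind(src, net$targ)
  if (!net$directed) {
    keep <- el[, 1] < el[, 2]
    el <- el[keep, , drop = FALSE]
  }
  igraph::graph_from_edgelist(el + 1L, directed = net$directed)
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Randomizes the network while keeping every node's in- and out-degree
#' exactly, rejecting swaps that would create self-loops or duplicate
#' edges.  Used as the null model that isolates degree-distribution effects
#' from higher-order structure (e.g. reciprocity, clustering).
#'
#' @param net a `cascade_net`.
#' @param n_swaps number of attempted swaps (`0` returns the input).
#' @export
rewire_degree_preserving <- function(net, n_swaps) {
  stopifnot(n_swaps >= 0)
  if (n_swaps == 0) return(net)
  g <- .net_to_igraph(net)
  g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                niter = n_swaps))
  .igraph_to_net(g, net$directed, meta = c(net$meta, list(rewired = n_swaps)))
}

#' Fraction of reciprocated directed edges
#' @param net a directed `cascade_net`.
#' @export
reciprocity_fraction <- function(net) {
  stopifnot(net$directed)
  igraph::reciprocity(.net_to_igraph(net))
}

.new_ensemble <- function(sim, model, bin, t_cap, timescale, observable,
                          replica = 1L, seed = NA) {
  structure(list(durations = sim$durations, sizes = sim$sizes,
                 profiles = sim$profiles, terminated = sim$terminated,
                 offspring_counts = sim$offspring_counts,
                 n_A = length(sim$durations), bin = bin, t_cap = t_cap,
                 timescale = timescale, observable = observable,
                 model = model, replica = replica, seed = seed),
            class = "avalanche_ensemble")
}

#' @export
print.avalanche_ensemble <- function(x, ...) {
  cat("<avalanche_ensemble>", x$model$type, " n_A =", x$n_A,
      " bin =", x$bin, " t_cap =", x$t_cap,
      " censored =", sum(!x$terminated), "\n")
  invisible(x)
}

#' Simulate meme-propagation avalanches (focal-meme reduction)
#'
#' Continuous-time meme dynamics on a directed follower network: in each
#' elementary step (`dt = 1/N`) a uniformly chosen node either innovates
#' (probability `mu`) or retweets the meme on its screen.  Only the focal
#' meme's screen set is simulated, which is exactly equivalent to the full
#' multi-meme dynamics because other memes interact with the focal one only
#' by overwriting screens.  Each avalanche is seeded by one forced focal
#' tweet from a uniformly random node at `t = 0` and terminates when no
#' screen holds the focal meme.  Profiles are binned focal-tweet counts.
#'
#' @param net a directed `cascade_net`.
#' @param mu innovation probability (`mu = 0` is critical).
#' @param n_A number of avalanches.
#' @param t_cap censoring time.
#' @param bin profile bin width (time units).
#' @return an `avalanche_ensemble`.
#' @export
run_meme_model <- function(net, mu, n_A, t_cap = 50, bin = 0.5) {
  stopifnot(net$directed, mu >= 0, mu <= 1, n_A >= 1)
  tr <- .transpose_csr(net)
  sim <- meme_ensemble_cpp(net$offs, net$targ, tr$ioffs, tr$itarg, net$N,
                           mu, as.integer(n_A), t_cap, bin)
  .new_ensemble(sim, list(type = "meme", mu = mu, N = net$N), bin, t_cap,
                "continuous", "events")
}

#' Simulate neuronal avalanches
#'
#' Binary-state integrate-and-fire caricature on a weighted directed
#' network: a firing neuron activates each follower in the next synchronous
#' step with probability equal to the edge weight, drawn uniformly on
#' `(0, phi_max)` and redrawn for every avalanche; neurons return to the
#' inactive state after firing.  `phi_max = 2/z` is critical.  Profiles are
#' newly activated counts per step (the seed is step 0).
#'
#' @param net a directed `cascade_net`.
#' @param phi_max edge-weight bound.
#' @param n_A number of avalanches.
#' @param t_cap censoring step count.
#' @param record_step optionally record per-parent children counts for
#'   parents active at this step (for offspring-distribution checks).
#' @export
run_neuronal_model <- function(net, phi_max, n_A, t_cap = 50,
                               record_step = -1) {
  stopifnot(net$directed, phi_max >= 0, n_A >= 1)
  sim <- neuronal_ensemble_cpp(net$offs, net$targ, net$N, phi_max,
                               as.integer(n_A), as.integer(t_cap),
                               as.integer(record_step))
  .new_ensemble(sim, list(type = "neuronal", phi_max = phi_max, N = net$N),
                1, t_cap, "discrete", "events")
}

#' Simulate threshold-model cascades
#'
#' Monotone threshold dynamics on an undirected network with synchronous
#' updating and per-avalanche thresholds `R_i ~ U(0, theta_max)`.  In the
#' Watts variant a node activates when the active *fraction* of its
#' neighbors reaches `R_i`; in the Centola-Macy variant when the active
#' *count* does.  Profiles are newly activated counts per step.
#'
#' @param net an undirected `cascade_net`.
#' @param kind `"watts"` or `"centola_macy"`.
#' @param theta_max threshold upper bound.
#' @param n_A number of avalanches.
#' @param t_cap censoring step count.
#' @param record_step see [run_neuronal_model()].
#' @export
run_threshold_model <- function(net, kind = c("watts", "centola_macy"),
                                theta_max, n_A, t_cap = 50,
                                record_step = -1) {
  kind <- match.arg(kind)
  stopifnot(!net$directed, theta_max > 0, n_A >= 1)
  sim <- threshold_ensemble_cpp(net$offs, net$targ, net$N,
                                as.integer(kind == "watts"), theta_max,
                                as.integer(n_A), as.integer(t_cap),
                                as.integer(record_step))
  .new_ensemble(sim, list(type = kind, theta_max = theta_max, N = net$N),
                1, t_cap, "discrete", "events")
}
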