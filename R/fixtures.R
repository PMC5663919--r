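#' Generate a named network substrate
#'
#' Convenience generator for the network kinds used throughout the tests
#' and documentation.
#'
#' @param kind one of `powerlaw_directed`, `zregular_directed`,
#'   `powerlaw_undirected`, `zregular_undirected`, `reciprocal_rich`.
#' @param N number of nodes.
#' @param z regular degree (regular kinds).
#' @param alpha,k_min power-law parameters (power-law kinds).
#' @export
gen_network <- function(kind = c("powerlaw_directed", "zregular_directed",
                                 "powerlaw_undirected",
                                 "zregular_undirected", "reciprocal_rich"),
                        N = 1e4, z = 10, alpha = 2.5, k_min = 4) {
  kind <- match.arg(kind)
  switch(kind,
    powerlaw_directed = {
      d <- pmin(sample_powerlaw_degrees(N, alpha, k_min), N - 1)
      net <- net_directed(d)
      net$meta$alpha <- alpha; net$meta$k_min <- k_min
      net
    },
    zregular_directed = net_zregular_directed(N, z),
    powerlaw_undirected = {
      d <- pmin(sample_powerlaw_degrees(N, alpha, k_min), round(sqrt(N)))
      if (sum(d) %% 2 == 1) d[1] <- d[1] + 1
      net <- net_undirected_config(d)
      net$meta$alpha <- alpha; net$meta$k_min <- k_min
      net
    },
    zregular_undirected = net_undirected_config(rep.int(z, N)),
    reciprocal_rich = {
      # directed net where ~30% of edges get a reverse partner, emulating
      # the ~48% reciprocated-link fraction of empirical follower networks
      net <- net_zregular_directed(N, z)
      src <- rep.int(seq_len(net$N) - 1L, diff(net$offs))
      el <- cbind(src, net$targ)
      add <- el[runif(nrow(el)) < 0.3, c(2, 1), drop = FALSE]
      el <- unique(rbind(el, add))
      el <- el[el[, 1] != el[, 2], , drop = FALSE]
      o <- order(el[, 1], el[, 2])
      offs <- c(0L, cumsum(tabulate(el[o, 1] + 1L, nbins = N)))
      .new_net(N, offs, el[o, 2], TRUE, meta = list(kind = "reciprocal_rich"))
    })
}

#' Generate small plain-text network fixtures with sidecar metadata
#'
#' Writes an edge list plus a YAML sidecar recording the analytic
#' properties a test or example needs (mean degree, second factorial
#' moment, reciprocity).  All instances are reproducible from the seed.
#'
#' @inheritParams gen_network
#' @param size number of nodes.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return (invisibly) list with `edgelist` and `sidecar` paths and the
#'   network object.
#' @export
generate_fixtures <- function(kind, size = 1000, seed = 1,
                              dir = tempdir(), z = 10, alpha = 2.5,
                              k_min = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  net <- gen_network(kind, N = size, z = z, alpha = alpha, k_min = k_min)
  base <- file.path(dir, paste0(kind, "_N", size, "_seed", seed))
  ef <- paste0(base, ".edges")
  write_edgelist(net, ef, comment = paste("synthetic", kind, "network"))
  kd <- out_degrees(net)
  meta <- list(kind = kind, N = net$N, seed = seed,
               directed = net$directed,
               mean_out_degree = mean(kd),
               mean_degree_analytic =
                 if (grepl("powerlaw", kind)) powerlaw_mean(alpha, k_min)
                 else z,
               second_factorial_moment = mean(kd * (kd - 1)))
  if (net$directed) meta$reciprocity <- reciprocity_fraction(net)
  sf <- paste0(base, ".yaml")
  yaml::write_yaml(meta, sf)
  invisible(list(edgelist = ef, sidecar = sf, net = net))
}
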