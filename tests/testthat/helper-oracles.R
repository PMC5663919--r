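# Independent oracles used across the test files.  These deliberately avoid
# the package's own polylog/generating-function code paths.

# Direct partial zeta sum with integral tail correction (independent of
# pracma): sum_{k>=1} k^-s
zeta_direct <- function(s, kmax = 2e6) {
  k <- seq_len(kmax)
  sum(k^(-s)) + kmax^(1 - s) / (s - 1)
}

# Brute-force double sum for the directed hat distribution
qhat_brute_directed <- function(p_in, p_out, v, z) {
  J <- length(p_in) - 1
  K <- length(p_out) - 1
  qk <- numeric(K + 1)
  for (k in 0:K) {
    acc <- 0
    for (j in 0:J) {
      if (j == 0 || p_in[j + 1] == 0) next
      acc <- acc + (j / z) * p_in[j + 1] * p_out[k + 1] * v(j, k)
    }
    qk[k + 1] <- acc
  }
  qk
}

# Exact distribution of the generation-size path of a Galton-Watson chain
# with small offspring support, by convolution dynamic programming;
# returns E[Z_t * 1{duration == T}] for t = 0..T and P(duration == T).
# Population capped at `cap` (choose so the truncated mass is negligible).
gw_dt_shape_brute <- function(q, T, cap = 120) {
  # transition matrix P(Z' = m | Z = n) via repeated convolution
  conv_pow <- list(c(1, rep(0, cap)))           # q^{*0}
  for (n in seq_len(cap)) {
    prev <- conv_pow[[n]]
    cur <- numeric(cap + 1)
    for (i in 0:cap) {
      if (prev[i + 1] == 0) next
      jmax <- min(length(q) - 1, cap - i)
      cur[i + (0:jmax) + 1] <- cur[i + (0:jmax) + 1] +
        prev[i + 1] * q[1 + 0:jmax]
    }
    conv_pow[[n + 1]] <- cur
  }
  P <- do.call(rbind, conv_pow)                  # P[n+1, m+1]
  # joint distribution over paths with Z_t recorded
  # dist[n+1] = P(Z_t = n, no extinction before t is not required --
  # extinction means absorbed at 0; duration = last t with Z_t > 0)
  EZ <- numeric(T + 1)
  # forward distribution of Z_t
  dist <- matrix(0, T + 2, cap + 1)
  dist[1, 2] <- 1                                # Z_0 = 1
  for (t in seq_len(T + 1))
    dist[t + 1, ] <- dist[t, ] %*% P
  # P(duration == T) = P(Z_T > 0, Z_{T+1} = 0)
  pdur <- sum(dist[T + 1, -1] * P[-1, 1])
  for (t in 0:T) {
    # E[Z_t ; Z_T > 0, Z_{T+1} = 0]: propagate with Z_t weight
    w <- dist[t + 1, ] * (0:cap)
    for (s in seq_len(T - t)) w <- w %*% P
    EZ[t + 1] <- sum(w[-1] * P[-1, 1])
  }
  list(A = EZ / pdur, p_duration = pdur)
}

# cached expensive fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

critical_poisson <- function() fixture("crit_pois", function() {
  make_offspring("poisson", xi = 1)
})

poisson_curve <- function() fixture("crit_pois_curve", function() {
  solve_extinction(critical_poisson(), t_max = 1000)
})
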