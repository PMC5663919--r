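test_that("parametric offspring families are calibrated correctly", {
  # Poisson
  p <- make_offspring("poisson", xi = 1)
  expect_equal(p$q[1], exp(-1), tolerance = 1e-12)
  expect_equal(unclass(branching_number(p)), 1, ignore_attr = TRUE)

  # power law gamma = 2.5, xi = 1: C = 1 / zeta(1.5), q0 = 1 - C zeta(2.5),
  # checked against a direct partial-sum zeta oracle
  pl <- make_offspring("power_law", gamma = 2.5, xi = 1)
  expect_equal(pl$C, 1 / zeta_direct(1.5), tolerance = 1e-8)
  expect_equal(pl$q[1], 1 - zeta_direct(2.5) / zeta_direct(1.5),
               tolerance = 1e-8)
  expect_equal(pl$C, 0.38279, tolerance = 1e-4)
  expect_equal(pl$q[1], 0.4865, tolerance = 1e-4)
  # head follows C k^-gamma exactly
  kk <- 10:100
  expect_equal(pl$q[kk + 1], pl$C * kk^(-2.5), tolerance = 1e-14)

  # binary fission
  bf <- make_offspring("binary_fission", p = 0.5)
  expect_equal(bf$xi, 1)
  expect_equal(bf$q, c(0.5, 0, 0.5))

  # truncated power law: normalization and branching number by direct sum
  tp <- make_offspring("truncated_power_law", gamma = 2.3, kappa = 50,
                       xi = 1, k_head = 1e4)
  expect_lt(abs(sum(tp$q) - 1), 1e-10)
  kk <- seq_along(tp$q) - 1
  expect_lt(abs(sum(kk * tp$q) - 1), 1e-8)

  # errors
  expect_error(make_offspring("power_law", gamma = 1.8),
               "divergent mean")
  expect_error(make_offspring("power_law", gamma = 2.5, xi = 3),
               "infeasible calibration")
})

test_that("generating functions match closed forms and series oracles", {
  p <- make_offspring("poisson", xi = 1)
  expect_equal(gf(p, 1), 1, tolerance = 1e-12)
  expect_equal(gf(p, 0.5), exp(-0.5), tolerance = 1e-12)

  bf <- make_offspring("binary_fission", p = 0.5)
  s <- seq(0, 1, 0.1)
  expect_equal(gf(bf, s), (1 + s^2) / 2, tolerance = 1e-14)
  expect_equal(gf(bf, s, order = 1), s, tolerance = 1e-14)

  # heavy tail: polylog evaluation vs direct dense series
  pl <- make_offspring("power_law", gamma = 2.5, xi = 1)
  kk <- 1:2e6
  for (s in c(0.3, 0.9, 0.999)) {
    direct <- pl$q[1] + sum(pl$C * kk^(-2.5) * s^kk)
    expect_equal(gf(pl, s), direct, tolerance = 1e-10)
    expect_equal(gf(pl, s, 1), sum(pl$C * kk^(-1.5) * s^(kk - 1)),
                 tolerance = 1e-10)
  }
  expect_equal(gf(pl, 1, 1), 1, tolerance = 1e-10)     # f'(1) = xi
  expect_identical(gf(pl, 1, 2), Inf)                  # infinite variance

  tp <- make_offspring("truncated_power_law", gamma = 2.3, kappa = 1e3)
  expect_true(is.finite(gf(tp, 1, 2)))                 # cutoff restores f''
  expect_equal(gf(tp, 1, 1), 1, tolerance = 1e-10)

  expect_error(gf(p, 1.5), "\\[0, 1\\]")
})

test_that("hat distributions follow the edge-reaching construction", {
  # undirected 3-regular with constant vulnerability 0.4
  h <- qhat(degree_regular(3),
            vulnerability("custom", v = function(k) rep(0.4, length(k)),
                          nu = 0, directed = FALSE))
  expect_equal(h$qk[3], 0.4)
  expect_equal(sum(h$qk), 0.4)
  expect_equal(h$xi, 0.8)

  # directed: brute-force double-sum oracle on a random factorized joint
  set.seed(42)
  for (rep in 1:5) {
    pout <- runif(10); pout[1] <- 0; pout <- pout / sum(pout)
    zout <- sum((0:9) * pout)
    # two-point in-degree pmf with exactly the out mean (balanced joint)
    a <- floor(zout); w <- zout - a
    pin2 <- numeric(a + 2); pin2[a + 1] <- 1 - w; pin2[a + 2] <- w
    deg <- degree_directed(degree_dist(pin2, "directed"),
                           degree_dist(pout, "directed"))
    vfun <- function(j, k) 1 / (1 + j + 0.1 * k)
    vul <- vulnerability("custom", v = vfun, nu = 0, directed = TRUE)
    h <- qhat(deg, vul)
    brute <- qhat_brute_directed(pin2, pout, function(j, k) 1 / (1 + j + 0.1 * k),
                                 deg$z)
    expect_equal(h$qk, brute, tolerance = 1e-12)
  }
  expect_error(qhat(degree_dist(c(1)), vulnerability("neuronal",
                                                     phi_max = 0.2)),
               "directed|spreading")
})

test_that("dynamics-specific criticality identities hold via Eqs of q-hat", {
  # meme: xi = 1 - mu exactly, on in-degree pmfs supported on j >= 1
  outs <- list(degree_powerlaw(2.5, 4, k_max = 2e5, kind = "directed"),
               degree_regular(10, kind = "directed"),
               degree_poisson(7, kind = "directed"))
  for (pout in outs) for (mu in c(0, 0.1, 0.5)) {
    a <- floor(pout$z); w <- pout$z - a
    pin <- numeric(a + 2); pin[a + 1] <- 1 - w; pin[a + 2] <- w
    deg <- degree_directed(degree_dist(pin, "directed"), pout)
    h <- qhat(deg, vulnerability("meme", mu = mu))
    expect_lt(abs(h$xi - (1 - mu)), 1e-8)
  }

  # neuronal: xi = phi_max * z / 2; critical at phi_max = 2/z
  for (pout in outs[1:2]) {
    a <- floor(pout$z); w <- pout$z - a
    pin <- numeric(a + 2); pin[a + 1] <- 1 - w; pin[a + 2] <- w
    deg <- degree_directed(degree_dist(pin, "directed"), pout)
    h <- qhat(deg, vulnerability("neuronal", phi_max = phi_max_critical(deg$z)))
    expect_lt(abs(h$xi - 1), 1e-8)
    h2 <- qhat(deg, vulnerability("neuronal", phi_max = 1 / deg$z))
    expect_lt(abs(h2$xi - 0.5), 1e-8)
  }

  # Centola-Macy: xi = 1 at theta_max = <k^2 - k>/z (uniform thresholds)
  deg <- degree_powerlaw(3.3, 2, k_max = 1e5)
  h <- qhat(deg, vulnerability("centola_macy",
                               theta_max = theta_max_critical(deg)))
  expect_lt(abs(h$xi - 1), 1e-8)

  # Watts on 3-regular with U(0,1) thresholds: v = 1/3, xi = 2/3
  h <- qhat(degree_regular(3), vulnerability("watts", theta_max = 1))
  expect_lt(abs(h$xi - 2 / 3), 1e-10)
})

test_that("binomial thinning connects q-hat and the offspring distribution", {
  # r = 1 leaves the distribution unchanged
  h <- qhat(degree_regular(3),
            vulnerability("custom", v = function(k) rep(1, length(k)),
                          nu = 0, directed = FALSE))
  expect_equal(h$r, 1)
  q <- offspring_from_qhat(h)
  expect_equal(q$q, h$qk, tolerance = 1e-12)

  # hand example: qhat = {1: 0.5} -> q = {0: 0.5, 1: 0.5}
  h2 <- qhat(degree_regular(2),
             vulnerability("custom", v = function(k) rep(0.5, length(k)),
                           nu = 0, directed = FALSE))
  expect_equal(h2$qk[2], 0.5)
  q2 <- offspring_from_qhat(h2)
  expect_equal(q2$q[1:2], c(0.5, 0.5), tolerance = 1e-12)

  # xi identity and normalization on 100 random degree/vulnerability pairs
  set.seed(7)
  for (i in 1:100) {
    K <- sample(3:25, 1)
    pmf <- runif(K + 1); pmf <- pmf / sum(pmf)
    if (sum((0:K) * pmf) == 0) next
    vv <- runif(K + 1)
    deg <- degree_dist(pmf)
    vul <- vulnerability("custom", v = function(k) vv[pmin(k, K) + 1],
                         nu = 0, directed = FALSE)
    h <- qhat(deg, vul)
    if (h$r == 0) next
    q <- offspring_from_qhat(h)
    expect_lt(abs(sum(q$q) - 1), 1e-10)
    kk <- seq_along(q$q) - 1
    expect_lt(abs(sum(kk * q$q) - h$xi), 1e-8)
    expect_lt(abs(gf(q, 1, 1) - h$xi), 1e-8)
  }

  # degenerate r = 0
  h0 <- qhat(degree_regular(3),
             vulnerability("custom", v = function(k) rep(0, length(k)),
                           nu = 0, directed = FALSE))
  expect_error(offspring_from_qhat(h0), "degenerate")
})

test_that("branching number classifies criticality regimes", {
  expect_identical(attr(branching_number(make_offspring("poisson", xi = 0.8)),
                        "regime"), "subcritical")
  expect_identical(attr(branching_number(make_offspring("poisson", xi = 1)),
                        "regime"), "critical")
  expect_identical(attr(branching_number(make_offspring("poisson", xi = 1.2)),
                        "regime"), "supercritical")
  expect_equal(unclass(branching_number(c(0.2, 0.3, 0.5))), 1.3,
               ignore_attr = TRUE)
})

test_that("offspring tail exponents follow the degree/vulnerability calculus", {
  expect_equal(offspring_exponent(3.3, 0, "undirected")$gamma, 2.3)
  expect_true(offspring_exponent(3.3, 0, "undirected")$nonsymmetric)
  expect_equal(offspring_exponent(2.5, 1, "undirected")$gamma, 2.5)
  expect_equal(offspring_exponent(2.5, 0, "directed")$gamma, 2.5)
  expect_false(offspring_exponent(3.5, 1, "undirected")$nonsymmetric)

  # declared nu matches the measured decay of the vulnerability callable
  expect_lt(abs(vul_decay_exponent(vulnerability("watts", theta_max = 1)) - 1),
            0.1)
  expect_lt(abs(vul_decay_exponent(vulnerability("centola_macy",
                                                 theta_max = 5))), 0.1)

  # tail calculus on the hat distribution itself (log-log slope of qhat_k)
  # watts, alpha = 2.5 undirected -> gamma = 2.5
  dw <- degree_powerlaw(2.5, 4, k_max = 1e6)
  hw <- qhat(dw, vulnerability("watts", theta_max = 1))
  k <- seq_along(hw$qk) - 1
  expect_lt(abs(loglog_slope(k[-1], hw$qk[-1], 1e2, 1e4) + 2.5), 0.1)

  # centola-macy, alpha = 3.3 -> gamma = 2.3
  dc <- degree_powerlaw(3.3, 2, k_max = 1e6)
  hc <- qhat(dc, vulnerability("centola_macy",
                               theta_max = theta_max_critical(dc)))
  expect_lt(abs(loglog_slope(k[-1], hc$qk[-1], 1e2, 1e4) + 2.3), 0.1)

  # neuronal, alpha = 2.5 directed -> gamma = 2.5
  pout <- degree_powerlaw(2.5, 4, k_max = 1e6, kind = "directed")
  a <- floor(pout$z); w <- pout$z - a
  pin <- numeric(a + 2); pin[a + 1] <- 1 - w; pin[a + 2] <- w
  dn <- degree_directed(degree_dist(pin, "directed"), pout)
  hn <- qhat(dn, vulnerability("neuronal", phi_max = 2 / dn$z))
  kn <- seq_along(hn$qk) - 1
  expect_lt(abs(loglog_slope(kn[-1], hn$qk[-1], 1e2, 1e4) + 2.5), 0.1)
})

test_that("distributions round-trip through the two-column table format", {
  q <- make_offspring("binary_fission", p = 0.3)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_distribution(q, f)
  q2 <- read_distribution(f, "offspring")
  expect_equal(q2$q, q$q, tolerance = 1e-9)
  expect_equal(q2$xi, q$xi, tolerance = 1e-9)
})
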