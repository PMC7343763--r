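test_that("entropy functional matches closed forms", {
  point <- ddl_dist(P0 = c(1, 0, 0), P1 = rep(0, 3), provenance = "cme")
  expect_equal(ddl_entropy(point), 0)
  two <- ddl_dist(P0 = c(0.5, 0), P1 = c(0.5, 0), provenance = "cme")
  expect_equal(ddl_entropy(two), -log(2))
  for (N in c(4, 10)) {
    u <- rep(1 / N, N / 2)
    unif <- ddl_dist(P0 = u, P1 = u, provenance = "cme")
    expect_equal(ddl_entropy(unif), -log(N))
  }
})

test_that("detailed-balance parameter sets produce zero entropy production", {
  set.seed(2026)
  for (i in 1:5) {
    kon <- runif(1, 0.2, 3); koff <- runif(1, 0.2, 3)
    # decoupled limit k1 = k2 = 0
    p <- ddl_params(k1 = 0, k2 = 0, k3 = 2, k4 = 1, kon = kon, koff = koff, a = 1.5)
    ts <- transition_system(p)
    d <- stationary_solve(ts)
    expect_lt(abs(ep_ness(d, ts)), 1e-10)
    expect_lt(abs(ddl_ep(d, p)), 1e-10)
    expect_lt(abs(entropy_production_rate(d, ts)), 1e-10)
    # no signal: point mass at m = 0 times an equilibrium two-state switch
    p0 <- ddl_params(k1 = 2, k2 = 1, k3 = 5, k4 = 1, kon = kon, koff = koff, a = 0)
    d0 <- stationary_distribution(p0)
    ts0 <- transition_system(p0, ddl_state_space(d0$m_max))
    expect_lt(abs(ep_ness(d0, ts0)), 1e-10)
    expect_lt(abs(ddl_ep(d0, p0)), 1e-10)
  }
})

test_that("closed-form EP equals the generic NESS sum and the pairwise form", {
  for (i in seq_len(nrow(fixture_grid()))) {
    g <- fixture_grid()[i, ]
    p <- ddl_fixture_params(a = g$a, k3 = g$k3)
    sp <- ddl_state_space(choose_truncation(p))
    ts <- transition_system(p, sp)
    d <- stationary_distribution(p, sp)
    ep8 <- ddl_ep(d, p)
    expect_lt(abs(ep8 - ep_ness(d, ts)), 1e-10)
    expect_lt(abs(ep8 - entropy_production_rate(d, ts)), 1e-10)
    expect_gt(ep8, -1e-10)  # non-negative at stationarity
  }
})

test_that("EP is stable under truncation growth", {
  p <- ddl_fixture_params(a = 1, k3 = 5)
  M <- choose_truncation(p, 1e-12)
  d1 <- stationary_distribution(p, ddl_state_space(M))
  d2 <- stationary_distribution(p, ddl_state_space(M + 20L))
  expect_lt(abs(ddl_ep(d1, p) - ddl_ep(d2, p)), 1e-8)
})

test_that("decomposition identities hold under both log conventions", {
  for (i in seq_len(nrow(fixture_grid()))) {
    g <- fixture_grid()[i, ]
    p <- ddl_fixture_params(a = g$a, k3 = g$k3)
    d <- stationary_distribution(p)
    ep <- ddl_ep(d, p)
    bf <- ep_decomposition(d, p, log_weights = "fluxes")
    br <- ep_decomposition(d, p, log_weights = "rates")
    expect_lt(abs(bf$EP1 + bf$EP2 + bf$EP3 - ep), 1e-10)
    expect_lt(abs(br$EP1 + br$EP2 + br$EP3 - ep), 1e-10)
    # flux grouping: every class is individually non-negative dissipation
    expect_true(all(c(bf$EP1, bf$EP2, bf$EP3) >= 0))
    # rate grouping: the Poisson marginal cancels the two
    # synthesis-degradation classes identically (EP1 = -EP2)
    expect_lt(abs(br$EPm), 1e-12)
  }
})

test_that("decomposition vanishes termwise at detailed balance", {
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 2, k4 = 1, kon = 1, koff = 2, a = 1)
  d <- stationary_solve(transition_system(p))
  b <- ep_decomposition(d, p)
  expect_lt(max(abs(c(b$EP1, b$EP2, b$EP3))), 1e-10)
})

test_that("ep_ness enforces stationarity per the strict flag", {
  p <- ddl_fixture_params(a = 1, k3 = 1.5)
  sp <- ddl_state_space(choose_truncation(p))
  ts <- transition_system(p, sp)
  skew <- ddl_dist(P0 = c(1, rep(0, sp$m_max)), P1 = rep(0, sp$m_max + 1),
                   provenance = "cme")
  expect_error(ep_ness(skew, ts), "not stationary")
  expect_warning(ep_ness(skew, ts, strict = FALSE), "not stationary")
})

test_that("signal sweep: synthesis-degradation share grows with the signal", {
  for (k3 in FIXTURE_K3) {
    base <- ddl_fixture_params(k3 = k3)
    prof <- ep_vs_a_profile(base, FIXTURE_A)
    expect_identical(prof$a, sort(prof$a))
    expect_true(all(diff(prof$fraction_m) >= 0))
    expect_true(all(prof$fraction_m > 0.6))
    expect_lt(max(abs(prof$EPm + prof$EP3 - prof$EP)), 1e-10)
  }
})
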