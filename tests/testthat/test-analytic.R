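test_that("pochhammer is the rising factorial", {
  expect_equal(pochhammer(7.3, 0), 1)
  expect_equal(pochhammer(3, 4), 360)
  expect_equal(pochhammer(0.5, 3), 0.5 * 1.5 * 2.5)  # 1.875
  expect_equal(pochhammer(-2, 4), 0)                 # hits zero factor
  # log-space branch agrees with the direct product where both are finite
  expect_equal(pochhammer(1.2, 151), prod(1.2 + 0:150), tolerance = 1e-12)
  expect_error(pochhammer(1, -1), "non-negative")
})

test_that("kummer_m matches closed forms and the series oracle", {
  for (al in c(0.3, 1, 2.7)) {
    expect_equal(kummer_m(al, al, 1.3), exp(1.3), tolerance = 1e-12)
    expect_equal(kummer_m(al, al, -2.1), exp(-2.1), tolerance = 1e-12)
  }
  expect_equal(kummer_m(1, 2, 1), exp(1) - 1, tolerance = 1e-12)
  # negative argument: Kummer transformation vs direct summation of the
  # transformed (positive-argument) series
  oracle <- exp(-4) * kummer_series_oracle(3.5 - 2.5, 3.5, 4)
  expect_equal(kummer_m(2.5, 3.5, -4), oracle, tolerance = 1e-12)
  expect_error(kummer_m(1, -2, 1), "non-positive")
})

test_that("analytic coefficients obey their defining formulas", {
  p <- ddl_fixture_params(a = 1, k3 = 5)   # k1=2.1, k2=1, kon=koff=1
  cf <- analytic_coefficients(p)
  expect_equal(cf$alpha, 5 / 4 + 4.1 / 2)  # 3.3, by hand
  expect_equal(cf$beta, cf$alpha + 1)
  expect_equal(cf$omega2, -1.25)
  expect_equal(cf$omega1, 1.25)

  p2 <- ddl_params(k1 = 2, k2 = 0, k3 = 5, k4 = 1, kon = 1, koff = 2, a = 1.5)
  cf2 <- analytic_coefficients(p2)
  expect_equal(cf2$omega1, 0)
  expect_equal(cf2$omega2, 0)
  expect_equal(cf2$alpha, p2$kon + p2$koff + p2$a * p2$k1)

  p3 <- ddl_params(k1 = 2, k2 = 3, k3 = 5, k4 = 1, kon = 1, koff = 2, a = 0)
  cf3 <- analytic_coefficients(p3)
  expect_equal(cf3$omega1, 0)
  expect_equal(cf3$omega2, 0)
  expect_equal(cf3$alpha, (p3$kon + p3$koff) / (p3$k2 + 1))
})

test_that("A0 normalises the series (brute-force renormalisation oracle)", {
  for (i in seq_len(nrow(fixture_grid()))) {
    g <- fixture_grid()[i, ]
    p <- ddl_fixture_params(a = g$a, k3 = g$k3)
    M <- choose_truncation(p, 1e-14)
    mass <- sum(stationary_p0(p, 0:M)) + sum(stationary_p1(p, 0:M))
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  # decoupled limit: closed two-state x Poisson normalisation
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 3, k4 = 1, kon = 2, koff = 1, a = 1)
  expect_equal(normalization_A0(p),
               p$kon / (p$kon + p$koff) * exp(-p$a * p$k3),
               tolerance = 1e-12)
  expect_error(
    normalization_A0(ddl_params(k1 = 1, k2 = 1, k3 = 2, k4 = 1,
                                kon = 0, koff = 1, a = 0)),
    "kon")
})

test_that("strand distributions match product form and the CME oracle", {
  # decoupled limit: P1 = [kon/(kon+koff)] Poisson, P0 its complement
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 4, k4 = 1, kon = 1.5, koff = 0.5, a = 1)
  m <- 0:12
  expect_equal(stationary_p1(p, m),
               p$kon / (p$kon + p$koff) * dpois(m, p$a * p$k3),
               tolerance = 1e-12)
  expect_equal(stationary_p0(p, m),
               p$koff / (p$kon + p$koff) * dpois(m, p$a * p$k3),
               tolerance = 1e-12)

  # zero synthesis: no mass above m = 0 on the on strand
  p0 <- ddl_params(k1 = 1, k2 = 1, k3 = 5, k4 = 1, kon = 1, koff = 1, a = 0)
  expect_equal(stationary_p1(p0, 1:5), rep(0, 5))

  # fixture point values against the null-space oracle
  p <- ddl_fixture_params(a = 1, k3 = 5)
  sp <- ddl_state_space(choose_truncation(p))
  oracle <- stationary_solve(transition_system(p, sp))
  expect_equal(stationary_p1(p, 5), oracle$P1[6], tolerance = 1e-8)
  expect_equal(stationary_p0(p, 5), oracle$P0[6], tolerance = 1e-8)
  expect_equal(stationary_p0(p, 0), oracle$P0[1], tolerance = 1e-8)
})

test_that("assembled stationary distribution satisfies its invariants", {
  for (i in seq_len(nrow(fixture_grid()))) {
    g <- fixture_grid()[i, ]
    p <- ddl_fixture_params(a = g$a, k3 = g$k3)
    sp <- ddl_state_space(choose_truncation(p))
    d <- stationary_distribution(p, sp)
    expect_identical(d$provenance, "analytic")
    expect_equal(sum(d$P0) + sum(d$P1), 1, tolerance = 1e-6)

    # marginal identity: P0 + P1 is the Poisson law of the copy number
    expect_lt(max(abs(d$P0 + d$P1 - marginal_poisson(p, 0:sp$m_max))), 1e-8)

    # oracle equivalence
    oracle <- stationary_solve(transition_system(p, sp))
    expect_lt(tv_distance(d, oracle), 1e-8)

    # mode of the marginal sits at the Poisson mode floor(a k3)
    lambda <- g$a * g$k3
    tot <- d$P0 + d$P1
    expect_true((which.max(tot) - 1L) %in%
                  c(floor(lambda), ceiling(lambda) - 1L))
  }
})

test_that("degenerate Poisson at a = 0 concentrates at m = 0", {
  p <- ddl_params(k1 = 2, k2 = 1, k3 = 5, k4 = 1, kon = 1, koff = 2, a = 0)
  d <- stationary_distribution(p)
  expect_equal(d$P0[1] + d$P1[1], 1, tolerance = 1e-12)
  # two-state balance: mass_on / mass_off = kon / koff (no signal boost)
  expect_equal(sum(d$P1) / sum(d$P0), p$kon / p$koff, tolerance = 1e-10)
})
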