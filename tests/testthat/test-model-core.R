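test_that("parameters are normalised by the degradation rate", {
  p <- ddl_params(k1 = 4.2, k2 = 2, k3 = 10, k4 = 2, kon = 2, koff = 2, a = 1)
  expect_equal(p$k1, 2.1)
  expect_equal(p$k2, 1)
  expect_equal(p$k3, 5)
  expect_equal(p$kon, 1)
  expect_equal(p$koff, 1)
  expect_equal(p$k4, 1)
  expect_equal(p$k4_raw, 2)

  # already-normalised input is the identity
  q <- ddl_params(k1 = 2.1, k2 = 1, k3 = 5, k4 = 1, kon = 1, koff = 1, a = 1)
  expect_equal(q[c("k1", "k2", "k3", "kon", "koff")],
               p[c("k1", "k2", "k3", "kon", "koff")])

  expect_error(ddl_params(k1 = 1, k2 = 1, k3 = 1, k4 = 0, kon = 1, koff = 1, a = 1),
               "degradation rate must be positive")
  expect_error(ddl_params(k1 = -1, k2 = 1, k3 = 1, k4 = 1, kon = 1, koff = 1, a = 1),
               "negative rate")
})

test_that("truncation covers the Poisson tail and never drops below 10", {
  p0 <- ddl_params(k1 = 1, k2 = 1, k3 = 5, k4 = 1, kon = 1, koff = 1, a = 0)
  expect_identical(choose_truncation(p0, 0.5), 10L)

  # brute-force cumulative-sum oracle at lambda = 5, tol = 1e-12
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 5, k4 = 1, kon = 1, koff = 1, a = 1)
  lambda <- 5
  pmf <- exp(-lambda + (0:200) * log(lambda) - lfactorial(0:200))
  tails <- 1 - cumsum(pmf)
  oracle <- max(10L, which(tails < 1e-12)[1] - 1L)
  expect_identical(choose_truncation(p, 1e-12), oracle)

  # smaller tolerance never shrinks the truncation
  tols <- 10^seq(-2, -14, by = -2)
  ms <- vapply(tols, function(tt) choose_truncation(p, tt), 0L)
  expect_true(all(diff(ms) >= 0L))

  expect_error(choose_truncation(p, 0), "tail_tol")
})

test_that("state enumeration is a bijection with flat index 2m + gene", {
  sp <- ddl_state_space(17)
  expect_equal(sp$n_states, 36L)
  idx <- state_index(sp, sp$m, sp$gene)
  expect_identical(idx, seq_len(sp$n_states))
  expect_identical(sp$m[state_index(sp, 3, 1)], 3L)
  expect_identical(sp$gene[state_index(sp, 3, 1)], 1L)
  expect_error(state_index(sp, 18, 0), "outside")
  expect_error(state_index(sp, 1, 2), "gene")
})

test_that("generator rows sum to zero and carry only the six jump classes", {
  for (i in seq_len(nrow(fixture_grid()))) {
    g <- fixture_grid()[i, ]
    p <- ddl_fixture_params(a = g$a, k3 = g$k3)
    ts <- transition_system(p, ddl_state_space(25))
    expect_lt(max(abs(Matrix::rowSums(ts$Q))), 1e-12)
    expect_true(all(ts$edges$rate > 0))
    expect_setequal(unique(ts$edges$class),
                    c("birth_off", "birth_on", "death_off", "death_on",
                      "switch_on", "switch_off"))
  }
})

test_that("out-rate of a state sums its jump-class propensities", {
  p <- ddl_fixture_params(a = 1, k3 = 5)  # k2 = 1, koff = 1
  sp <- ddl_state_space(20)
  ts <- transition_system(p, sp)
  i <- state_index(sp, 3, 1)  # (m = 3, on)
  out <- sum(ts$edges$rate[ts$edges$from == i])
  expect_equal(out, p$a * p$k3 + 3 + (p$koff + 3 * p$k2))
  expect_equal(-as.matrix(ts$Q)[i, i], out)
})

test_that("a = 0 removes every synthesis transition", {
  p <- ddl_params(k1 = 2, k2 = 1, k3 = 5, k4 = 1, kon = 1, koff = 1, a = 0)
  ts <- transition_system(p, ddl_state_space(12))
  expect_false(any(grepl("^birth", ts$edges$class)))
})

test_that("k1 = k2 = 0 decouples into switch x birth-death product form", {
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 4, k4 = 1, kon = 1.3, koff = 0.6, a = 1)
  sp <- ddl_state_space(choose_truncation(p))
  d <- stationary_solve(transition_system(p, sp))
  prod <- product_form_dist(p$kon, p$koff, p$a * p$k3, sp$m_max)
  expect_lt(tv_distance(d, prod), 1e-12)
})

test_that("all switching rates zero leaves a reducible chain, flagged", {
  p <- ddl_params(k1 = 0, k2 = 0, k3 = 5, k4 = 1, kon = 0, koff = 0, a = 1)
  ts <- transition_system(p, ddl_state_space(15))
  expect_error(stationary_solve(ts), "not unique")
})
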