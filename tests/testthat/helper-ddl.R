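# shared fixtures and independent oracles for the test suite

# canonical fixture grid: signal strengths x synthesis rates
FIXTURE_A <- c(0.5, 1, 2, 4)
FIXTURE_K3 <- c(1.5, 5)

fixture_grid <- function() expand.grid(a = FIXTURE_A, k3 = FIXTURE_K3)

# decoupled limit k1 = k2 = 0: gene switch and birth-death chain are
# independent, so the stationary law is the exact product
# (two-state occupancy) x (truncated, renormalised Poisson)
product_form_dist <- function(kon, koff, lambda, m_max) {
  pois <- dpois(0:m_max, lambda)
  pois <- pois / sum(pois)
  ddl_dist(P0 = koff / (kon + koff) * pois,
           P1 = kon / (kon + koff) * pois,
           provenance = "cme")
}

# rebuild a parameter set at a phase-plane node
point_params_test <- function(base, a, k3) {
  ddl_params(k1 = base$k1, k2 = base$k2, k3 = k3, k4 = 1,
             kon = base$kon, koff = base$koff, a = a)
}

# brute-force series oracle for Kummer's M(a, b, z), z >= 0: direct
# term-by-term summation, independent of the package's implementation
kummer_series_oracle <- function(a, b, z, n_terms = 150) {
  n <- 0:n_terms
  terms <- vapply(n, function(k) {
    num <- if (k == 0) 1 else prod(a + 0:(k - 1))
    den <- if (k == 0) 1 else prod(b + 0:(k - 1))
    num / den * z^k / factorial(k)
  }, 0)
  sum(terms)
}
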