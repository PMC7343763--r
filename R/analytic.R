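#' Coefficients of the closed-form stationary solution
#'
#' The stationary distribution of the double-deck loop is expressible
#' through Kummer functions with parameters
#' \deqn{\alpha = \frac{a k_2 k_3}{(k_2+1)^2} + \frac{k_{on} + k_{off} + a k_1}{k_2+1},
#'       \quad \beta = \alpha + 1,}
#' \deqn{\omega_2 = -\frac{a k_2 k_3}{(k_2+1)^2}, \quad
#'       \omega_1 = \frac{a k_2 k_3}{k_2+1} - \frac{a k_2 k_3}{(k_2+1)^2}.}
#'
#' @param params a \code{\link{ddl_params}} object (k4-normalised).
#' @return List with fields \code{alpha}, \code{beta}, \code{omega1},
#'   \code{omega2}, plus the recurring factor \code{u = a*k3/(k2+1)}.
#' @export
analytic_coefficients <- function(params) {
  stopifnot(inherits(params, "ddl_params"))
  with(params, {
    g <- a * k2 * k3
    alpha <- g / (k2 + 1)^2 + (kon + koff + a * k1) / (k2 + 1)
    list(
      alpha = alpha,
      beta = alpha + 1,
      omega2 = -g / (k2 + 1)^2,
      omega1 = g / (k2 + 1) - g / (k2 + 1)^2,
      u = a * k3 / (k2 + 1)
    )
  })
}

# Unnormalised series S_shift(m) = (1/m!) u^m  sum_{l=0}^m k2^l C(m,l)
#   (alpha+shift)_l / (beta+shift)_l  M(alpha+shift+l, beta+shift+l; omega2),
# the building block of both strands.  Fvals/rvals can be precomputed for a
# whole lattice; weights are assembled in log space.
series_S <- function(params, cf, m, shift, Fvals = NULL, rvals = NULL) {
  if (m < 0L) return(0)
  u <- cf$u
  if (u == 0) {                      # a*k3 = 0: only m = 0 carries mass
    if (m > 0L) return(0)
    return(kummer_m(cf$alpha + shift, cf$beta + shift, cf$omega2))
  }
  ls <- if (params$k2 == 0) 0L else 0:m
  if (is.null(Fvals)) {
    Fvals <- vapply(ls, function(l)
      kummer_m(cf$alpha + shift + l, cf$beta + shift + l, cf$omega2), 0)
  }
  if (is.null(rvals)) {
    # (alpha+shift)_l / (beta+shift)_l, built incrementally (stays in (0,1])
    rvals <- cumprod(c(1, (cf$alpha + shift + ls[-length(ls)]) /
                          (cf$beta + shift + ls[-length(ls)])))
  }
  logw <- m * log(u) + ifelse(ls == 0, 0, ls * log(params$k2)) -
    lfactorial(ls) - lfactorial(m - ls)
  sum(exp(logw) * rvals[ls + 1L] * Fvals[ls + 1L])
}

# prefactors of the off-strand expression; third-term form validated against
# the CME null-space oracle (see the methods vignette on typography of the
# flattened closed form)
p0_prefactors <- function(params, cf) {
  with(params, {
    denom <- kon + a * k1
    if (denom <= 0) stop("kon + a*k1 must be positive for the off strand")
    ab <- cf$alpha / cf$beta
    list(
      c1 = (a * k2 * k3 / (k2 + 1) + koff) / denom,
      c2 = (a * k2 * k3 / (k2 + 1)) * ab / denom,
      c3 = (a * k2 * k3) * ab / denom
    )
  })
}

#' Normalisation constant of the closed-form stationary solution
#'
#' The constant \eqn{A_0} that makes the two strand distributions sum to 1.
#' In closed form,
#' \deqn{A_0^{-1} = e^{u} \left[(c_1 + 1) M(\alpha,\beta;\omega_1) +
#'       (c_3 - c_2) M(\alpha+1,\beta+1;\omega_1)\right]}
#' with \eqn{u = a k_3/(k_2+1)} and the prefactors of the off-strand
#' expression.  Requires \eqn{k_{on} + a k_1 > 0}.
#'
#' @param params a \code{\link{ddl_params}} object.
#' @return The normalisation constant \eqn{A_0}.
#' @export
normalization_A0 <- function(params) {
  cf <- analytic_coefficients(params)
  pf <- p0_prefactors(params, cf)
  Ma <- kummer_m(cf$alpha, cf$beta, cf$omega1)
  Mb <- kummer_m(cf$alpha + 1, cf$beta + 1, cf$omega1)
  inv <- exp(cf$u) * ((pf$c1 + 1) * Ma + (pf$c3 - pf$c2) * Mb)
  1 / inv
}

#' Closed-form stationary probability of the on strand
#'
#' \eqn{P_1(m) = A_0 \frac{1}{m!} \left(\frac{a k_3}{k_2+1}\right)^m
#' \sum_{l=0}^m k_2^l \binom{m}{l} \frac{(\alpha)_l}{(\beta)_l}
#' M(\alpha+l, \beta+l; \omega_2)}.
#'
#' @param params a \code{\link{ddl_params}} object.
#' @param m repressor copy number (non-negative integer, vectorised).
#' @return P1(m), the stationary probability of (gene on, m).
#' @export
stationary_p1 <- function(params, m) {
  cf <- analytic_coefficients(params)
  A0 <- normalization_A0(params)
  vapply(as.integer(m), function(mi) {
    if (mi < 0L) stop("m must be non-negative")
    A0 * series_S(params, cf, mi, 0)
  }, 0)
}

#' Closed-form stationary probability of the off strand
#'
#' Three-term Kummer-series expression; the third term (index m - 1) is
#' absent at m = 0.  Requires \eqn{k_{on} + a k_1 > 0}.
#'
#' @inheritParams stationary_p1
#' @return P0(m), the stationary probability of (gene off, m).
#' @export
stationary_p0 <- function(params, m) {
  cf <- analytic_coefficients(params)
  pf <- p0_prefactors(params, cf)
  A0 <- normalization_A0(params)
  vapply(as.integer(m), function(mi) {
    if (mi < 0L) stop("m must be non-negative")
    A0 * (pf$c1 * series_S(params, cf, mi, 0) -
          pf$c2 * series_S(params, cf, mi, 1) +
          pf$c3 * series_S(params, cf, mi - 1L, 1))
  }, 0)
}

#' Poisson marginal of the repressor copy number
#'
#' Summed over the gene state, the stationary copy-number distribution is
#' exactly Poisson with mean \eqn{a k_3} -- the birth-death statistics of
#' the repressor are unaffected by which strand carries them.
#'
#' @inheritParams stationary_p1
#' @return Poisson pmf values with mean \code{a * k3}.
#' @export
marginal_poisson <- function(params, m) {
  stopifnot(inherits(params, "ddl_params"))
  if (any(m < 0)) stop("m must be non-negative")
  stats::dpois(m, params$a * params$k3)
}

#' Closed-form stationary distribution on a truncated lattice
#'
#' Evaluates the analytic stationary solution for every m on the lattice,
#' with the Kummer-function values shared across m for speed.  The total
#' mass must come out within 1e-6 of 1 (it falls short only by the Poisson
#' tail beyond m_max); a larger deficit signals an inadequate truncation
#' and raises an error.
#'
#' @param params a \code{\link{ddl_params}} object.
#' @param space a \code{\link{ddl_state_space}}; default chooses the
#'   truncation via \code{\link{choose_truncation}}.
#' @return A \code{\link{ddl_dist}} with provenance \code{"analytic"}.
#' @export
stationary_distribution <- function(params, space = NULL) {
  stopifnot(inherits(params, "ddl_params"))
  if (is.null(space)) space <- ddl_state_space(choose_truncation(params))
  M <- space$m_max
  cf <- analytic_coefficients(params)
  pf <- p0_prefactors(params, cf)
  A0 <- normalization_A0(params)

  L <- if (params$k2 == 0) 0L else M
  F0 <- vapply(0:L, function(l)
    kummer_m(cf$alpha + l, cf$beta + l, cf$omega2), 0)
  F1 <- vapply(0:L, function(l)
    kummer_m(cf$alpha + 1 + l, cf$beta + 1 + l, cf$omega2), 0)
  r0 <- cumprod(c(1, (cf$alpha + 0:(L - 1) + 0)[seq_len(L)] /
                     (cf$beta + 0:(L - 1))[seq_len(L)]))
  r1 <- cumprod(c(1, (cf$alpha + 1 + 0:(L - 1))[seq_len(L)] /
                     (cf$beta + 1 + 0:(L - 1))[seq_len(L)]))

  S0 <- vapply(0:M, function(mi) {
    k <- min(mi, L)
    series_S(params, cf, mi, 0, Fvals = F0[seq_len(k + 1)], rvals = r0)
  }, 0)
  S1 <- vapply(0:M, function(mi) {
    k <- min(mi, L)
    series_S(params, cf, mi, 1, Fvals = F1[seq_len(k + 1)], rvals = r1)
  }, 0)

  P1 <- A0 * S0
  P0 <- A0 * (pf$c1 * S0 - pf$c2 * S1 + pf$c3 * c(0, S1[seq_len(M)]))
  mass <- sum(P0) + sum(P1)
  if (abs(mass - 1) > 1e-6) {
    stop(sprintf(paste("stationary mass %.8f deviates from 1 beyond 1e-6;",
                       "truncation m_max = %d is suspect"), mass, M))
  }
  ddl_dist(P0, P1, provenance = "analytic", params = params)
}
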