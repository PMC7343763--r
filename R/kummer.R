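#' Pochhammer symbol (rising factorial)
#'
#' \eqn{(\gamma)_l = \Gamma(\gamma + l)/\Gamma(\gamma) =
#' \gamma(\gamma+1)\cdots(\gamma+l-1)}, with \eqn{(\gamma)_0 = 1}.
#' Computed as a direct product for moderate \eqn{l}, switching to
#' log-gamma when the product would overflow.
#'
#' @param gamma base (real, scalar).
#' @param l non-negative integer order.
#' @return The rising factorial as a double.
#' @export
pochhammer <- function(gamma, l) {
  l <- as.integer(l)
  if (is.na(l) || l < 0L) stop("l must be a non-negative integer")
  if (l == 0L) return(1)
  f <- gamma + seq_len(l) - 1
  if (any(f == 0)) return(0)
  if (gamma > 0 && l > 150L) {
    # all factors positive: log-space avoids overflow
    return(exp(lgamma(gamma + l) - lgamma(gamma)))
  }
  prod(f)
}

#' Kummer's confluent hypergeometric function M(a, b, z)
#'
#' Evaluates \eqn{{}_1F_1(a; b; z) = \sum_n (a)_n z^n / ((b)_n n!)}.
#' For \eqn{z < 0} the Kummer transformation
#' \eqn{M(a, b, z) = e^z M(b - a, b, -z)} is applied first, so that the
#' series is summed with a positive argument and (for the parameter ranges
#' arising here, \eqn{b > a > 0}) positive terms -- no cancellation, and
#' double precision delivers ~1e-15 relative accuracy.
#'
#' @param a numerator parameter.
#' @param b denominator parameter; must not be a non-positive integer.
#' @param z argument (real scalar).
#' @param max_terms series length cap before aborting.
#' @return M(a, b, z) as a double.
#' @export
kummer_m <- function(a, b, z, max_terms = 10000L) {
  if (b <= 0 && b == round(b)) stop("b must not be a non-positive integer")
  if (z < 0) return(exp(z) * kummer_m(b - a, b, -z, max_terms))
  term <- 1
  s <- 1
  n <- 0
  while (n < max_terms) {
    term <- term * (a + n) / (b + n) * z / (n + 1)
    s <- s + term
    n <- n + 1
    if (abs(term) <= .Machine$double.eps * abs(s)) return(s)
  }
  stop("kummer_m: series failed to converge within ", max_terms, " terms")
}
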