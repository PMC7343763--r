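#' Stationary distribution pair container
#'
#' Holds the joint distribution over the (gene, m) lattice as the two
#' strand-wise vectors P0(m) (gene off) and P1(m) (gene on), m = 0..m_max,
#' together with the provenance of the numbers (\code{"analytic"},
#' \code{"cme"} or \code{"ssa"}).
#'
#' @param P0,P1 numeric vectors of length m_max + 1, non-negative.
#' @param provenance one of "analytic", "cme", "ssa".
#' @param params optionally, the \code{\link{ddl_params}} that produced it.
#' @param overflow probability mass observed beyond m_max (SSA estimates
#'   bin it here so truncation mismatch is visible); default 0.
#' @return An object of class \code{ddl_dist}.
#' @export
ddl_dist <- function(P0, P1, provenance = c("analytic", "cme", "ssa"),
                     params = NULL, overflow = 0) {
  provenance <- match.arg(provenance)
  if (length(P0) != length(P1)) stop("P0 and P1 must have equal length")
  if (any(!is.finite(P0)) || any(!is.finite(P1))) stop("non-finite probabilities")
  if (min(P0, P1) < -1e-10) stop("negative probabilities beyond tolerance")
  P0 <- pmax(P0, 0); P1 <- pmax(P1, 0)
  structure(list(
    m_max = length(P0) - 1L, P0 = P0, P1 = P1,
    provenance = provenance, params = params, overflow = overflow
  ), class = "ddl_dist")
}

#' @export
print.ddl_dist <- function(x, ...) {
  cat(sprintf("ddl_dist (%s): m = 0..%d, mass off = %.6f, on = %.6f",
              x$provenance, x$m_max, sum(x$P0), sum(x$P1)))
  if (x$overflow > 0) cat(sprintf(", overflow = %.3g", x$overflow))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ddl_dist <- function(x, ...) {
  data.frame(m = 0:x$m_max, P0 = x$P0, P1 = x$P1, P_total = x$P0 + x$P1)
}

# flat probability vector in state-index order (2*m + gene)
dist_vector <- function(dist) {
  as.vector(rbind(dist$P0, dist$P1))
}

vector_to_dist <- function(p, provenance, params = NULL) {
  n <- length(p)
  stopifnot(n %% 2L == 0L)
  gene <- (seq_len(n) - 1L) %% 2L
  ddl_dist(P0 = p[gene == 0L], P1 = p[gene == 1L],
           provenance = provenance, params = params)
}

#' Total-variation distance between two distribution pairs
#'
#' @param d1,d2 \code{ddl_dist} objects; shorter lattices are zero-padded.
#' @return Total-variation distance in [0, 1].
#' @export
tv_distance <- function(d1, d2) {
  M <- max(d1$m_max, d2$m_max)
  pad <- function(v, M) c(v, rep(0, M + 1L - length(v)))
  0.5 * (sum(abs(pad(d1$P0, M) - pad(d2$P0, M))) +
         sum(abs(pad(d1$P1, M) - pad(d2$P1, M))) +
         abs(d1$overflow - d2$overflow))
}
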