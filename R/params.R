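#' Model parameters for the double-deck-loop gene switch
#'
#' Construct the parameter set of the two-strand gene-switch model: a gene
#' toggling between "off" and "on" states while a repressor protein (ROCK,
#' copy number \eqn{m}) is synthesised and degraded on both strands.  The six
#' reaction channels are
#' \itemize{
#'   \item synthesis \eqn{m \to m+1} at rate \eqn{a k_3} (both strands),
#'   \item degradation \eqn{m \to m-1} at rate \eqn{m k_4},
#'   \item activation off \eqn{\to} on at rate \eqn{k_{on} + a k_1},
#'   \item repression on \eqn{\to} off at rate \eqn{k_{off} + m k_2},
#' }
#' where \eqn{a} is the concentration of the activated signal species
#' (RhoA*).  All rates are normalised by the degradation rate \eqn{k_4}, so
#' internally the degradation rate is exactly 1 and time is measured in units
#' of \eqn{1/k_4}; the raw \eqn{k_4} is retained for unit conversion on
#' output.
#'
#' @param k1 activation rate per unit signal (raw units).
#' @param k2 repression rate per repressor copy (raw units).
#' @param k3 repressor synthesis rate per unit signal (raw units).
#' @param k4 repressor degradation rate; sets the time unit. Must be > 0.
#' @param kon basal off-to-on switching rate (raw units).
#' @param koff basal on-to-off switching rate (raw units).
#' @param a signal (RhoA*) concentration, dimensionless.
#' @return An object of class \code{ddl_params}: a list with the normalised
#'   rates \code{k1, k2, k3, kon, koff}, the signal \code{a}, the normalised
#'   degradation rate \code{k4 = 1} and the raw rate \code{k4_raw}.
#' @examples
#' p <- ddl_params(k1 = 4.2, k2 = 2, k3 = 10, k4 = 2, kon = 2, koff = 2, a = 1)
#' p$k1  # 2.1, normalised by k4
#' @export
ddl_params <- function(k1, k2, k3, k4 = 1, kon, koff, a) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, kon = kon, koff = koff, a = a)
  if (any(!is.finite(vals))) stop("all parameters must be finite numbers")
  if (k4 <= 0) stop("degradation rate must be positive")
  if (any(vals < 0)) {
    stop("negative rate: ", paste(names(vals)[vals < 0], collapse = ", "))
  }
  structure(list(
    k1 = k1 / k4, k2 = k2 / k4, k3 = k3 / k4,
    kon = kon / k4, koff = koff / k4,
    a = a, k4 = 1, k4_raw = k4
  ), class = "ddl_params")
}

#' @export
print.ddl_params <- function(x, ...) {
  cat("Double-deck-loop parameters (k4-normalised):\n")
  cat(sprintf("  k1 = %g, k2 = %g, k3 = %g, kon = %g, koff = %g, a = %g\n",
              x$k1, x$k2, x$k3, x$kon, x$koff, x$a))
  cat(sprintf("  time unit 1/k4 with raw k4 = %g; steady-state mean m_s = a*k3 = %g\n",
              x$k4_raw, x$a * x$k3))
  invisible(x)
}

#' Reference parameter set for worked examples
#'
#' A packaged default parameter set (kon = koff = 1, k1 = 2.1, k2 = 1,
#' k4 = 1) with the signal strength \code{a} and synthesis rate \code{k3}
#' free.  This is a synthetic reconstruction chosen so that the model shows
#' its characteristic structure -- off-dominated stationary state (Mode I)
#' at k3 = 5, on-dominated (Mode II) at k3 = 1.5, and a near-horizontal
#' Mode boundary in the (a, k3) plane -- not a parameter table taken from
#' any external source.
#'
#' @param a signal strength (default 1).
#' @param k3 repressor synthesis rate (default 5).
#' @return A \code{\link{ddl_params}} object.
#' @export
ddl_fixture_params <- function(a = 1, k3 = 5) {
  ddl_params(k1 = 2.1, k2 = 1, k3 = k3, k4 = 1, kon = 1, koff = 1, a = a)
}

#' Choose the copy-number truncation level
#'
#' The marginal stationary distribution of the repressor copy number is
#' Poisson with mean \eqn{a k_3}, so the lattice can be truncated where the
#' Poisson upper tail drops below a tolerance.  Returns the smallest
#' \code{m_max} whose upper-tail mass beyond it is below \code{tail_tol},
#' never less than 10.
#'
#' @param params a \code{\link{ddl_params}} object.
#' @param tail_tol upper-tail mass tolerance, in (0, 1).
#' @return Integer truncation level \code{m_max}.
#' @export
choose_truncation <- function(params, tail_tol = 1e-12) {
  stopifnot(inherits(params, "ddl_params"))
  if (!is.numeric(tail_tol) || tail_tol <= 0 || tail_tol >= 1) {
    stop("tail_tol must lie in (0, 1)")
  }
  lambda <- params$a * params$k3
  m <- 10L
  while (stats::ppois(m, lambda, lower.tail = FALSE) >= tail_tol) {
    m <- m + 1L
  }
  m
}

#' State lattice for the truncated model
#'
#' The state space is the lattice (gene, m) with gene in \{off = 0, on = 1\}
#' and m in 0..m_max.  States are enumerated by the flat index
#' \code{2*m + gene} (0-based; R vectors use \code{2*m + gene + 1}), giving
#' the generator a banded structure.
#'
#' @param m_max truncation level (integer >= 1).
#' @return An object of class \code{ddl_state_space} with fields
#'   \code{m_max}, \code{n_states}, and vectors \code{gene}, \code{m}
#'   mapping flat index to state.
#' @export
ddl_state_space <- function(m_max) {
  m_max <- as.integer(m_max)
  if (is.na(m_max) || m_max < 1L) stop("m_max must be an integer >= 1")
  n <- 2L * (m_max + 1L)
  idx <- seq_len(n) - 1L
  structure(list(
    m_max = m_max,
    n_states = n,
    gene = idx %% 2L,
    m = idx %/% 2L
  ), class = "ddl_state_space")
}

#' Flat index of a state
#'
#' @param space a \code{\link{ddl_state_space}}.
#' @param m repressor copy number(s).
#' @param gene gene state(s), 0 = off, 1 = on.
#' @return 1-based flat index/indices into the state enumeration.
#' @export
state_index <- function(space, m, gene) {
  stopifnot(inherits(space, "ddl_state_space"))
  if (any(m < 0L) || any(m > space$m_max)) stop("m outside the lattice")
  if (!all(gene %in% c(0L, 1L))) stop("gene must be 0 (off) or 1 (on)")
  2L * as.integer(m) + as.integer(gene) + 1L
}

#' Markov transition system of the gene switch
#'
#' Assemble the jump transitions of the model on the truncated lattice and
#' the corresponding sparse generator matrix Q (rows = source states,
#' off-diagonal entries the jump rates, diagonal set so each row sums to
#' zero).  The truncation is reflecting: the synthesis jump out of
#' \code{m = m_max} is dropped, so probability is conserved exactly.
#'
#' The six jump classes (k4-normalised rates) are: synthesis
#' \eqn{(m, g) \to (m+1, g)} at \eqn{a k_3}; degradation
#' \eqn{(m, g) \to (m-1, g)} at \eqn{m}; activation
#' \eqn{(m, off) \to (m, on)} at \eqn{k_{on} + a k_1}; repression
#' \eqn{(m, on) \to (m, off)} at \eqn{k_{off} + m k_2}.
#'
#' @param params a \code{\link{ddl_params}} object.
#' @param space a \code{\link{ddl_state_space}}; defaults to the truncation
#'   chosen by \code{\link{choose_truncation}}.
#' @return An object of class \code{ddl_transitions}: list with the
#'   \code{space}, the edge table \code{edges} (data frame with columns
#'   \code{from}, \code{to}, \code{rate}, \code{class}) and the sparse
#'   generator \code{Q} (a \code{dgCMatrix}).
#' @export
transition_system <- function(params, space = NULL) {
  stopifnot(inherits(params, "ddl_params"))
  if (is.null(space)) space <- ddl_state_space(choose_truncation(params))
  stopifnot(inherits(space, "ddl_state_space"))
  M <- space$m_max
  birth <- params$a * params$k3

  from <- integer(0); to <- integer(0); rate <- numeric(0); cls <- character(0)
  add <- function(f, t, r, c) {
    keep <- r > 0
    from <<- c(from, f[keep]); to <<- c(to, t[keep])
    rate <<- c(rate, r[keep]); cls <<- c(cls, rep(c, sum(keep)))
  }
  m_all <- 0:M
  for (g in 0:1) {
    # synthesis m -> m+1 (dropped at the reflecting boundary m = M)
    mm <- 0:(M - 1)
    add(state_index(space, mm, g), state_index(space, mm + 1L, g),
        rep(birth, M), if (g == 0) "birth_off" else "birth_on")
    # degradation m -> m-1 at rate m (k4 = 1)
    mm <- 1:M
    add(state_index(space, mm, g), state_index(space, mm - 1L, g),
        as.numeric(mm), if (g == 0) "death_off" else "death_on")
  }
  add(state_index(space, m_all, 0L), state_index(space, m_all, 1L),
      rep(params$kon + params$a * params$k1, M + 1L), "switch_on")
  add(state_index(space, m_all, 1L), state_index(space, m_all, 0L),
      params$koff + m_all * params$k2, "switch_off")

  n <- space$n_states
  out_rate <- numeric(n)
  agg <- tapply(rate, from, sum)
  out_rate[as.integer(names(agg))] <- agg
  Q <- Matrix::sparseMatrix(
    i = c(from, seq_len(n)), j = c(to, seq_len(n)),
    x = c(rate, -out_rate), dims = c(n, n)
  )
  structure(list(
    space = space,
    edges = data.frame(from = from, to = to, rate = rate, class = cls),
    Q = Q,
    params = params
  ), class = "ddl_transitions")
}

#' @export
print.ddl_transitions <- function(x, ...) {
  cat(sprintf("ddl_transitions: %d states (m_max = %d), %d positive-rate jumps\n",
              x$space$n_states, x$space$m_max, nrow(x$edges)))
  invisible(x)
}

# Strong connectivity of the positive-rate jump graph (BFS both ways).
# The chain is reducible iff some state cannot both reach and be reached
# from state 1; happens only in degenerate corners (e.g. all switching
# rates zero leaves the two gene strands disconnected).
is_irreducible <- function(ts) {
  n <- ts$space$n_states
  reach <- function(adj) {
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  fwd <- split(ts$edges$to, factor(ts$edges$from, levels = seq_len(n)))
  bwd <- split(ts$edges$from, factor(ts$edges$to, levels = seq_len(n)))
  all(reach(fwd)) && all(reach(bwd))
}
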