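#' Classify the gene-state mode of a stationary distribution
#'
#' Mode I: the total off-state mass \eqn{\sum_m P_0(m)} exceeds the
#' on-state mass; Mode II: the on-state mass dominates; within
#' \code{tie_tol} of each other the point is labelled \code{"boundary"}
#' rather than broken arbitrarily.
#'
#' @param dist a \code{\link{ddl_dist}}.
#' @param tie_tol tie tolerance on the mass difference.
#' @return One of \code{"I"}, \code{"II"}, \code{"boundary"}.
#' @export
classify_mode <- function(dist, tie_tol = 1e-9) {
  stopifnot(inherits(dist, "ddl_dist"))
  d <- sum(dist$P0) - sum(dist$P1)
  if (d > tie_tol) "I" else if (d < -tie_tol) "II" else "boundary"
}

#' Gene-state dominance factor
#'
#' \eqn{\delta = |P_{0,max} - P_{1,max}| / P_{1,max}} where
#' \eqn{P_{i,max} = \max_m P_i(m)} are the peak heights of the two strand
#' distributions.  Note this compares peak heights, not the total masses
#' that define the modes; the two orderings can disagree, which is why
#' phase scans report both.
#'
#' @param dist a \code{\link{ddl_dist}}.
#' @return \eqn{\delta \ge 0}.
#' @export
dominance_delta <- function(dist) {
  stopifnot(inherits(dist, "ddl_dist"))
  p1max <- max(dist$P1)
  if (p1max <= 0) stop("max P1 = 0: dominance factor undefined")
  abs(max(dist$P0) - p1max) / p1max
}

# stationary distribution at (a, k3) with other rates from base
point_params <- function(base, a, k3) {
  ddl_params(k1 = base$k1, k2 = base$k2, k3 = k3, k4 = 1,
             kon = base$kon, koff = base$koff, a = a)
}

#' Scan the (a, k3) phase plane
#'
#' Evaluates the stationary distribution (closed form; the master-equation
#' null space as a fallback if the series normalisation fails at a node) at
#' every node of the grid and records mode, dominance factor, strand masses
#' and optionally the entropy-production decomposition.  Nodes where both
#' routes fail are flagged (\code{ok = FALSE}) and the scan continues.
#'
#' @param base a \code{\link{ddl_params}} supplying k1, k2, kon, koff.
#' @param a_grid,k3_grid strictly increasing positive grids.
#' @param with_ep also compute the EP decomposition at each node.
#' @return Object of class \code{ddl_phase_map}: list with \code{grid}
#'   (long-format data frame: a, k3, mode, delta, mass_off, mass_on, ok,
#'   and EP columns when requested) and \code{boundary} (per-a boundary
#'   k3, NA where not bracketed by the k3 grid).
#' @export
scan_plane <- function(base, a_grid, k3_grid, with_ep = FALSE) {
  stopifnot(inherits(base, "ddl_params"))
  chk <- function(g) length(g) >= 1 && all(g > 0) && !is.unsorted(g, strictly = TRUE)
  if (!chk(a_grid) || !chk(k3_grid)) {
    stop("grids must be strictly increasing and positive")
  }
  rows <- list()
  for (a in a_grid) for (k3 in k3_grid) {
    p <- point_params(base, a, k3)
    d <- tryCatch(stationary_distribution(p),
                  error = function(e) tryCatch(
                    stationary_solve(transition_system(p)),
                    error = function(e2) NULL))
    row <- data.frame(a = a, k3 = k3, mode = NA_character_,
                      delta = NA_real_, mass_off = NA_real_,
                      mass_on = NA_real_, ok = FALSE)
    if (with_ep) {
      row <- cbind(row, data.frame(EP = NA_real_, EP1 = NA_real_,
                                   EP2 = NA_real_, EP3 = NA_real_,
                                   EPm = NA_real_, fraction_m = NA_real_))
    }
    if (!is.null(d)) {
      row$mode <- classify_mode(d)
      row$delta <- dominance_delta(d)
      row$mass_off <- sum(d$P0); row$mass_on <- sum(d$P1)
      row$ok <- TRUE
      if (with_ep) {
        b <- ep_decomposition(d, p)
        row[c("EP", "EP1", "EP2", "EP3", "EPm", "fraction_m")] <-
          list(b$EP, b$EP1, b$EP2, b$EP3, b$EPm, b$fraction_m)
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  grid <- do.call(rbind, rows)
  boundary <- vapply(a_grid, function(a) {
    tryCatch(find_boundary(base, a, min(k3_grid), max(k3_grid)),
             error = function(e) NA_real_)
  }, 0)
  structure(list(grid = grid, a_grid = a_grid, k3_grid = k3_grid,
                 boundary = data.frame(a = a_grid, k3_boundary = boundary)),
            class = "ddl_phase_map")
}

#' @export
print.ddl_phase_map <- function(x, ...) {
  cat(sprintf("ddl_phase_map: %d x %d nodes; boundary k3 in [%g, %g]\n",
              length(x$a_grid), length(x$k3_grid),
              suppressWarnings(min(x$boundary$k3_boundary, na.rm = TRUE)),
              suppressWarnings(max(x$boundary$k3_boundary, na.rm = TRUE))))
  invisible(x)
}

#' Locate the Mode I/II boundary in k3 at fixed signal strength
#'
#' Bisection on the off-minus-on mass difference as a function of k3.  The
#' bracket endpoints must classify to different modes; otherwise the
#' boundary is not bracketed and an error is raised.
#'
#' @param base a \code{\link{ddl_params}} supplying k1, k2, kon, koff.
#' @param a signal strength at which to trace the boundary.
#' @param k3_lo,k3_hi bracketing synthesis rates.
#' @param tol absolute k3 tolerance of the bisection (default 1e-4).
#' @return Boundary value of k3.
#' @export
find_boundary <- function(base, a, k3_lo, k3_hi, tol = 1e-4) {
  stopifnot(inherits(base, "ddl_params"))
  if (!(k3_lo > 0 && k3_hi > k3_lo)) stop("need 0 < k3_lo < k3_hi")
  gap <- function(k3) {
    d <- stationary_distribution(point_params(base, a, k3))
    sum(d$P0) - sum(d$P1)
  }
  g_lo <- gap(k3_lo); g_hi <- gap(k3_hi)
  if (sign(g_lo) == sign(g_hi)) {
    stop("boundary not bracketed: both endpoints on the same side")
  }
  while (k3_hi - k3_lo > tol) {
    mid <- (k3_lo + k3_hi) / 2
    g_mid <- gap(mid)
    if (g_mid == 0) return(mid)
    if (sign(g_mid) == sign(g_lo)) {
      k3_lo <- mid; g_lo <- g_mid
    } else {
      k3_hi <- mid
    }
  }
  (k3_lo + k3_hi) / 2
}
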