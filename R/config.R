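CONFIG_KEYS <- c("k1", "k2", "k3", "k4", "kon", "koff", "a",
                 "method", "tail_tol", "n_traj", "t_end", "burn_in",
                 "seed", "a_grid", "k3_grid", "k3_lo", "k3_hi", "strict")

CONFIG_DEFAULTS <- list(k4 = 1, method = "analytic", tail_tol = 1e-12,
                        n_traj = 20L, t_end = 500, burn_in = 50,
                        seed = 1L, strict = TRUE)

#' Load a run configuration
#'
#' Reads a flat JSON file with the rate constants \code{k1, k2, k3, k4,
#' kon, koff}, the signal strength \code{a}, and optional run settings
#' (\code{method}, \code{tail_tol}, SSA budget \code{n_traj}/\code{t_end}/
#' \code{burn_in}/\code{seed}, grids \code{a_grid}/\code{k3_grid},
#' boundary bracket \code{k3_lo}/\code{k3_hi}, \code{strict}).  Missing
#' \code{k4} defaults to 1 (already-normalised rates); other defaults:
#' method "analytic", tail_tol 1e-12, n_traj 20, t_end 500, burn_in 50,
#' seed 1.  Unknown keys are rejected.
#'
#' @param path path to the JSON configuration file.
#' @return An object of class \code{ddl_config}: list with \code{params}
#'   (a \code{\link{ddl_params}}) and the validated run options.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_ddl_config(raw)
}

#' Validate a configuration list
#'
#' @param raw named list as read from JSON (or built inline).
#' @return An object of class \code{ddl_config}.
#' @export
as_ddl_config <- function(raw) {
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  required <- c("k1", "k2", "k3", "kon", "koff", "a")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing config keys: ", paste(missing, collapse = ", "))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  if (!cfg$method %in% c("analytic", "cme", "ssa")) {
    stop("method must be one of analytic, cme, ssa")
  }
  if (cfg$tail_tol <= 0 || cfg$tail_tol >= 1) stop("tail_tol must be in (0,1)")
  params <- ddl_params(k1 = cfg$k1, k2 = cfg$k2, k3 = cfg$k3, k4 = cfg$k4,
                       kon = cfg$kon, koff = cfg$koff, a = cfg$a)
  structure(list(
    params = params,
    method = cfg$method, tail_tol = cfg$tail_tol,
    n_traj = as.integer(cfg$n_traj), t_end = cfg$t_end,
    burn_in = cfg$burn_in, seed = as.integer(cfg$seed),
    a_grid = cfg$a_grid, k3_grid = cfg$k3_grid,
    k3_lo = cfg$k3_lo, k3_hi = cfg$k3_hi,
    strict = isTRUE(cfg$strict)
  ), class = "ddl_config")
}

#' Write a configuration back to JSON
#'
#' Round-trips with \code{\link{load_config}}: rates are written in raw
#' units (normalised rates multiplied back by \code{k4_raw}).
#'
#' @param cfg a \code{ddl_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ddl_config"))
  p <- cfg$params
  k4 <- p$k4_raw
  out <- list(k1 = p$k1 * k4, k2 = p$k2 * k4, k3 = p$k3 * k4, k4 = k4,
              kon = p$kon * k4, koff = p$koff * k4, a = p$a,
              method = cfg$method, tail_tol = cfg$tail_tol,
              n_traj = cfg$n_traj, t_end = cfg$t_end, burn_in = cfg$burn_in,
              seed = cfg$seed, strict = cfg$strict)
  for (k in c("a_grid", "k3_grid", "k3_lo", "k3_hi")) {
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
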