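# common metadata block embedded with every result file
result_metadata <- function(params, method, extra = list()) {
  base <- list(
    package = "ddlswitch",
    version = as.character(utils::packageVersion("ddlswitch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = list(k1 = params$k1, k2 = params$k2, k3 = params$k3,
                  kon = params$kon, koff = params$koff, a = params$a,
                  k4_raw = params$k4_raw),
    method = method
  )
  utils::modifyList(base, extra)
}

write_metadata <- function(meta, path) {
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a distribution pair to TSV (+ JSON metadata sidecar)
#'
#' Columns \code{m, P0, P1, P_total}; full double precision.  A sidecar
#' \code{<path>.json} records parameters, provenance, truncation and any
#' extra metadata so the run can be reproduced.
#'
#' @param dist a \code{\link{ddl_dist}}.
#' @param path output TSV path.
#' @param params parameters to record; defaults to \code{dist$params}.
#' @param extra named list merged into the metadata block.
#' @return \code{path}, invisibly.
#' @export
write_distribution <- function(dist, path, params = dist$params,
                               extra = list()) {
  stopifnot(inherits(dist, "ddl_dist"))
  df <- as.data.frame(dist)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params)) {
    meta <- result_metadata(params, dist$provenance,
                            utils::modifyList(list(m_max = dist$m_max,
                                                   overflow = dist$overflow),
                                              extra))
    write_metadata(meta, path)
  }
  invisible(path)
}

#' Write a trajectory event log to TSV
#'
#' Columns \code{time, gene, m}; metadata sidecar records the seed and
#' horizon so a byte-identical rerun is possible.
#'
#' @param traj a \code{ddl_trajectory}.
#' @param path output TSV path.
#' @param params parameters to record (optional).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, params = NULL) {
  stopifnot(inherits(traj, "ddl_trajectory"))
  utils::write.table(format(as.data.frame(traj), digits = 17,
                            scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params)) {
    meta <- result_metadata(params, "ssa",
                            list(t_end = attr(traj, "t_end"),
                                 seed = attr(traj, "seed"),
                                 frozen = attr(traj, "frozen")))
    write_metadata(meta, path)
  }
  invisible(path)
}

#' Write a long-format table (EP profile or phase scan) to TSV
#'
#' @param df data frame payload.
#' @param path output TSV path.
#' @param params parameters to record (optional).
#' @param method method label for the metadata block.
#' @param extra named list merged into the metadata block.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path, params = NULL, method = "analytic",
                        extra = list()) {
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params)) write_metadata(result_metadata(params, method, extra), path)
  invisible(path)
}
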