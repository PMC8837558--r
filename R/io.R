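# Readers and writers for the package's plain-text interchange formats:
# trace CSV (t_ms,value), feature tables, density JSON, parameter-set JSON,
# population CSV. Every writer output is re-readable by the matching reader.

#' Read and write trace CSV files
#'
#' Trace CSVs have a mandatory header `t_ms,value`.
#'
#' @param tr a [trace()].
#' @param path file path.
#' @param kind trace kind for the reader (`"SL"`, `"Ca"` or `"force"`).
#' @return `read_trace_csv` returns a [trace()]; `write_trace_csv` returns
#'   `path` invisibly.
#' @export
write_trace_csv <- function(tr, path) {
  stopifnot(inherits(tr, "trace"))
  utils::write.csv(data.frame(t_ms = tr$t, value = tr$v), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, kind = "SL") {
  df <- utils::read.csv(path)
  if (!all(c("t_ms", "value") %in% names(df)))
    stop("trace CSV must have header columns t_ms,value: ", path)
  trace(df$t_ms, df$value, kind)
}

#' Read and write feature tables
#'
#' Feature tables are CSVs with columns
#' `cell_id,group,dSL_um,sSL_um,TTP_ms`.
#'
#' @param features n x 3 matrix with columns `dSL`, `sSL`, `TTP`.
#' @param group group label recorded for every row.
#' @param path file path.
#' @return `read_feature_table` returns a data frame with columns `cell_id`,
#'   `group`, `dSL`, `sSL`, `TTP`.
#' @export
write_feature_table <- function(features, group, path) {
  features <- as.matrix(features)
  df <- data.frame(cell_id = sprintf("%s_%03d", group, seq_len(nrow(features))),
                   group = group, dSL_um = features[, 1],
                   sSL_um = features[, 2], TTP_ms = features[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "group", "dSL_um", "sSL_um", "TTP_ms")
  if (!all(need %in% names(df)))
    stop("feature table must have columns ", paste(need, collapse = ","))
  data.frame(cell_id = df$cell_id, group = df$group, dSL = df$dSL_um,
             sSL = df$sSL_um, TTP = df$TTP_ms)
}

#' Read and write feature-density JSON
#'
#' Densities are stored as JSON with `mean`, covariance (row-major `cov`),
#' `n` and `group`.
#'
#' @param d a `"feature_density"`.
#' @param path file path.
#' @return `read_density_json` returns a `"feature_density"`.
#' @export
write_density_json <- function(d, path) {
  stopifnot(inherits(d, "feature_density"))
  obj <- list(group = d$group, n = d$n, feature_names = names(d$mean),
              mean = unname(d$mean), cov = as.numeric(t(d$cov)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_json
#' @export
read_density_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.numeric(obj$mean)
  names(mu) <- obj$feature_names
  S <- matrix(as.numeric(obj$cov), 3, 3, byrow = TRUE,
              dimnames = list(obj$feature_names, obj$feature_names))
  structure(list(mean = mu, cov = S, n = as.integer(obj$n),
                 group = obj$group),
            class = "feature_density")
}

#' Read and write parameter-set JSON
#'
#' Parameter sets are stored with keys exactly matching the
#' [sarcomere_params()] field names.
#'
#' @param p a [sarcomere_params()] object.
#' @param path file path.
#' @return `read_params_json` returns a [sarcomere_params()].
#' @export
write_params_json <- function(p, path) {
  stopifnot(inherits(p, "sarcomere_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  do.call(sarcomere_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read and write population CSV files
#'
#' Populations are written with schema-ordered parameter columns (see
#' [param_names()]), an optional `SL_slack` column, and a `group` column.
#'
#' @param pop data frame of one group's parameter rows.
#' @param group group label.
#' @param path file path.
#' @return `read_population_csv` returns the data frame (with `group`).
#' @export
write_population_csv <- function(pop, group, path) {
  cols <- intersect(c(param_names(), "SL_slack"), names(pop))
  df <- pop[cols]
  df$group <- group
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(param_names() %in% names(df)))
    stop("population CSV must contain columns ",
         paste(param_names(), collapse = ","))
  df
}
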