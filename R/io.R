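#' Read and write response / response-time matrices
#'
#' Responses and response times travel as delimited text with one header
#' row of item labels and one row per person; response times are in
#' seconds.  Numeric output keeps full precision (17 significant
#' digits).
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_matrix_file`: numeric matrix with item labels as
#'   column names.
#' @export
read_matrix_file <- function(path, sep = ",") {
  x <- utils::read.table(path, sep = sep, header = TRUE,
                         check.names = FALSE)
  as.matrix(x)
}

#' @rdname read_matrix_file
#' @param x matrix to write; column names default to `Item1..ItemJ`.
#' @export
write_matrix_file <- function(x, path, sep = ",") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("Item", seq_len(ncol(x)))
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

write_table_full <- function(df, path, sep = ",") {
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model configuration file
#'
#' YAML configuration with optional blocks `priors:` (fields of
#' [rtcdm_priors()]) and `chain:` (fields of [chain_config()]); absent
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return list with elements `priors` and `chain`.
#' @export
read_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  priors <- do.call(rtcdm_priors, cfg$priors %||% list())
  chain <- do.call(chain_config, cfg$chain %||% list())
  list(priors = priors, chain = chain, raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
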