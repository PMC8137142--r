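#' Read and write spot tables
#'
#' Spot tables are plain CSV with one row per spot and the standard
#' column set (`channel, cell_id, z_um, y_um, x_um, ...`). Files written
#' by the pipeline carry a `# config_hash:` comment line, which the
#' reader skips.
#'
#' @param spots spot table data.frame.
#' @param path file path.
#' @param config_hash optional hash string embedded as a comment.
#' @return `write_spot_table()` returns `path` invisibly;
#'   `read_spot_table()` returns the data.frame.
#' @export
write_spot_table <- function(spots, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  write.csv(spots, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write expression matrices as TSV
#'
#' TSV layout: first column the gene ID, header row the sample IDs.
#' Roles are supplied separately (config) or inferred from sample names
#' containing "control".
#'
#' @param em an [expression_matrix()] (write) / path (read).
#' @param path file path.
#' @param roles optional role vector for `read_expression_tsv`.
#' @param unit unit tag for `read_expression_tsv`.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene = em$genes, em$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, roles = NULL,
                                unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  if (is.null(roles))
    roles <- ifelse(grepl("control", colnames(values), ignore.case = TRUE),
                    "control", "pulldown")
  expression_matrix(values, genes = genes, samples = colnames(values),
                    roles = roles, unit = unit)
}

# stable md5 hash of an R object via its canonical JSON
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
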