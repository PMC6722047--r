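#' Read a log2 expression matrix TSV (gene_id x sample columns)
#'
#' @param path TSV with a `gene_id` column and one numeric column per sample.
#' @return numeric gene x sample matrix with gene row names.
#' @export
read_expression <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tb)) stop("expression TSV needs a gene_id column")
  m <- as.matrix(tb[, setdiff(names(tb), "gene_id"), drop = FALSE])
  rownames(m) <- tb$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a log2 expression matrix TSV
#' @param expr gene x sample matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(cbind(gene_id = rownames(expr), as.data.frame(expr)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired design TSV (sample_id, run, arm, ...)
#' @param path TSV path.
#' @return a [paired_design()].
#' @export
read_design <- function(path) {
  paired_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a paired design TSV
#' @param design a [paired_design()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mediator concentration TSV (analyte x sample columns)
#' @param path TSV with an `analyte` column and one numeric column per sample.
#' @return numeric analyte x sample matrix.
#' @export
read_mediators <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"analyte" %in% names(tb)) stop("mediator TSV needs an analyte column")
  m <- as.matrix(tb[, setdiff(names(tb), "analyte"), drop = FALSE])
  rownames(m) <- tb$analyte
  storage.mode(m) <- "double"
  m
}

#' Write a mediator concentration TSV
#' @param conc analyte x sample matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mediators <- function(conc, path) {
  utils::write.table(cbind(analyte = rownames(conc), as.data.frame(conc)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contrast manifest TSV
#'
#' Long-format index of contrast files: columns `contrast_id`, `item`,
#' `concentration`, `timepoint`, `path` (paths relative to the manifest's
#' directory are resolved).
#'
#' @param path manifest TSV.
#' @return data frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contrast_id", "path")
  if (!all(need %in% names(tb)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", tb$path)
  tb$path[rel] <- file.path(dirname(path), tb$path[rel])
  tb
}
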