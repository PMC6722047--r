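#' Signed two-layer causal network model
#'
#' A causal network model has a functional backbone layer — signed directed
#' cause-effect edges among biological entities (node labels are opaque
#' strings; BEL-like labels such as `"p(HGNC:HMGB1)"` are fine) — and a
#' signed downstream layer linking backbone nodes to measurable gene
#' expression. Gene-level evidence enters the model only through the
#' downstream layer.
#'
#' @param name network label.
#' @param family network family the model belongs to (e.g. "cell fate",
#'   "cell proliferation", "cell stress", "inflammatory process").
#' @param backbone_nodes character vector of node labels.
#' @param backbone_edges data frame with columns `src`, `tgt`, `sign`
#'   (+1/-1); may have zero rows.
#' @param downstream_edges data frame with columns `node`, `gene`, `sign`
#'   (+1/-1); at least one edge required.
#' @return an object of class `causal_network`.
#' @export
causal_network <- function(name, family, backbone_nodes, backbone_edges,
                           downstream_edges) {
  backbone_nodes <- as.character(backbone_nodes)
  if (anyDuplicated(backbone_nodes)) stop("duplicate backbone node labels")
  be <- as.data.frame(backbone_edges)
  de <- as.data.frame(downstream_edges)
  if (nrow(be) > 0) {
    if (!all(c("src", "tgt", "sign") %in% names(be)))
      stop("backbone_edges needs columns src, tgt, sign")
    if (!all(be$sign %in% c(-1, 1))) stop("sign must be +1/-1")
    if (any(be$src == be$tgt)) stop("self-loops not allowed in the backbone")
    if (!all(c(be$src, be$tgt) %in% backbone_nodes))
      stop("backbone edge references undeclared node")
    key <- paste(be$src, be$tgt)
    dup <- duplicated(key)
    if (any(dup)) {
      for (k in unique(key[dup]))
        if (length(unique(be$sign[key == k])) > 1L)
          stop("conflicting sign on duplicate backbone edge: ", k)
      be <- be[!dup, , drop = FALSE]
    }
  } else {
    be <- data.frame(src = character(), tgt = character(), sign = numeric())
  }
  if (nrow(de) == 0L) stop("at least one downstream edge is required")
  if (!all(c("node", "gene", "sign") %in% names(de)))
    stop("downstream_edges needs columns node, gene, sign")
  if (!all(de$sign %in% c(-1, 1))) stop("sign must be +1/-1")
  if (!all(de$node %in% backbone_nodes))
    stop("downstream edge to undeclared backbone node")
  key <- paste(de$node, de$gene)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup]))
      if (length(unique(de$sign[key == k])) > 1L)
        stop("conflicting sign on duplicate downstream edge: ", k)
    de <- de[!dup, , drop = FALSE]
  }
  rownames(be) <- rownames(de) <- NULL
  structure(list(name = name, family = family,
                 backbone_nodes = backbone_nodes,
                 backbone_edges = be, downstream_edges = de),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf(
    "causal_network '%s' (family: %s): %d backbone nodes, %d backbone edges, %d downstream gene edges\n",
    x$name, x$family, length(x$backbone_nodes), nrow(x$backbone_edges),
    nrow(x$downstream_edges)))
  invisible(x)
}

#' Load a causal network model from JSON
#'
#' Schema: `{"name": str, "family": str, "backbone_nodes": [str],
#' "backbone_edges": [{"src","tgt","sign"}], "downstream_edges":
#' [{"node","gene","sign"}]}` with signs +1/-1.
#'
#' @param path JSON file path.
#' @return a validated [causal_network()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "family", "backbone_nodes", "backbone_edges",
            "downstream_edges")
  miss <- setdiff(need, names(j))
  if (length(miss)) stop("network JSON missing fields: ",
                         paste(miss, collapse = ", "))
  be <- as.data.frame(j$backbone_edges)
  de <- as.data.frame(j$downstream_edges)
  for (df in list(be, de))
    if (nrow(df) > 0 && !all(df$sign %in% c(-1, 1)))
      stop("sign must be +1/-1")
  causal_network(j$name, j$family, j$backbone_nodes, be, de)
}

#' Write a causal network model to JSON
#'
#' @param network a [causal_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "causal_network"))
  jsonlite::write_json(
    list(name = network$name, family = network$family,
         backbone_nodes = network$backbone_nodes,
         backbone_edges = network$backbone_edges,
         downstream_edges = network$downstream_edges),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Gene-level contrast container
#'
#' One exposed-vs-air comparison: per-gene log2 fold-change and standard
#' error, plus contrast metadata (item, concentration, post-exposure time).
#'
#' @param gene character vector of gene ids (unique).
#' @param log2fc numeric log2 fold-changes.
#' @param se numeric standard errors (>= 0).
#' @param meta named list of contrast metadata (free-form).
#' @return an object of class `gene_contrast` (a data frame with columns
#'   `gene`, `log2fc`, `se` and attribute `meta`).
#' @export
gene_contrast <- function(gene, log2fc, se, meta = list()) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("one record per gene required")
  if (length(log2fc) != length(gene) || length(se) != length(gene))
    stop("gene, log2fc, se must have equal length")
  if (!all(is.finite(log2fc)) || !all(is.finite(se)))
    stop("log2fc and se must be finite")
  if (any(se < 0)) stop("se must be nonnegative")
  out <- data.frame(gene = gene, log2fc = log2fc, se = se,
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  class(out) <- c("gene_contrast", "data.frame")
  out
}

#' Read a contrast TSV (columns gene_id, log2fc, se)
#'
#' @param path TSV path.
#' @param meta optional metadata list to attach.
#' @return a [gene_contrast()].
#' @export
read_contrast <- function(path, meta = list()) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc", "se") %in% names(tb)))
    stop("contrast TSV needs columns gene_id, log2fc, se")
  gene_contrast(tb$gene_id, tb$log2fc, tb$se, meta = meta)
}

#' Write a contrast TSV
#'
#' @param contrast a [gene_contrast()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  utils::write.table(
    data.frame(gene_id = contrast$gene, log2fc = contrast$log2fc,
               se = contrast$se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
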