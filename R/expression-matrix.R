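#' Cells-by-genes expression matrix with gene-class annotation
#'
#' The central container of the pipeline: a numeric matrix of non-negative
#' expression values (TPM units) with cells in rows and genes in columns,
#' plus a per-gene class label distinguishing endogenous genes, ERCC
#' spike-ins and mitochondrial genes. Spike-ins are excluded from TPM
#' rescaling and from the mitochondrial-content QC fraction; mitochondrial
#' genes define the QC numerator.
#'
#' @param values numeric matrix, cells x genes, non-negative and finite;
#'   rownames are cell identifiers, colnames gene identifiers (both may be
#'   supplied via `cell_ids` / `gene_ids` instead)
#' @param gene_class character vector, one of `"endogenous"`, `"spike_in"`,
#'   `"mitochondrial"` per gene; defaults to all-endogenous
#' @param cell_ids,gene_ids optional identifier vectors overriding dimnames
#' @return an object of class `ExpressionMatrix`
#' @export
expression_matrix <- function(values, gene_class = NULL,
                              cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(gene_class)) gene_class <- rep("endogenous", ncol(values))
  gene_class <- as.character(gene_class)
  if (length(gene_class) != ncol(values))
    stop("gene_class must have one entry per gene")
  bad <- setdiff(unique(gene_class), c("endogenous", "spike_in", "mitochondrial"))
  if (length(bad))
    stop("unknown gene_class value(s): ", paste(bad, collapse = ", "))
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, gene_class = stats::setNames(gene_class, gene_ids)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(factor(x$gene_class,
                      levels = c("endogenous", "spike_in", "mitochondrial")))
  cat(sprintf(
    "ExpressionMatrix: %d cells x %d genes (%d endogenous, %d spike-in, %d mitochondrial)\n",
    nrow(x$values), ncol(x$values), tab[["endogenous"]], tab[["spike_in"]],
    tab[["mitochondrial"]]))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Cell and gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`
#' @return character vector of identifiers
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by cell or gene identifiers
#'
#' Order of the supplied identifiers is preserved in the result.
#'
#' @param x an `ExpressionMatrix`
#' @param cells,genes character vectors of identifiers to keep
#' @return an `ExpressionMatrix`
#' @export
subset_cells <- function(x, cells) {
  missing <- setdiff(cells, cell_ids(x))
  if (length(missing))
    stop("unknown cell identifiers: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[cells, , drop = FALSE], x$gene_class)
}

#' @rdname subset_cells
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing))
    stop("unknown gene identifiers: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[, genes, drop = FALSE], x$gene_class[genes])
}

#' Assign gene classes by identifier prefix
#'
#' Genes whose identifier starts with `spike_in_prefix` (ERCC spike-in
#' standards by default) are classed `spike_in`; genes starting with any of
#' `mito_prefixes` are classed `mitochondrial`; all others are `endogenous`.
#' The three classes partition the gene set. Identifiers are matched
#' case-sensitively; a gene matching both prefix families is an error.
#'
#' @param matrix an `ExpressionMatrix`
#' @param spike_in_prefix prefix marking spike-in genes (default `"ERCC-"`)
#' @param mito_prefixes character vector of mitochondrial-gene prefixes
#'   (default `"mt-"`, the mouse convention)
#' @return the matrix with `gene_class` reassigned
#' @export
annotate_gene_classes <- function(matrix, spike_in_prefix = "ERCC-",
                                  mito_prefixes = "mt-") {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            nzchar(spike_in_prefix), length(mito_prefixes) >= 1L,
            all(nzchar(mito_prefixes)))
  ids <- gene_ids(matrix)
  is_spike <- startsWith(ids, spike_in_prefix)
  is_mito <- Reduce(`|`, lapply(mito_prefixes, function(p) startsWith(ids, p)))
  clash <- is_spike & is_mito
  if (any(clash))
    stop("gene(s) match both spike-in and mitochondrial prefixes: ",
         paste(ids[clash], collapse = ", "))
  cls <- ifelse(is_spike, "spike_in",
                ifelse(is_mito, "mitochondrial", "endogenous"))
  expression_matrix(matrix$values, cls)
}

#' The ten-gene endothelial/haematopoietic marker panel
#'
#' A small panel of known genes whose joint expression separates endothelial
#' from haematopoietic-transitioning cells, together with an anchor gene
#' (Runx1 by default) whose high expression identifies the haematopoietic
#' mixture component.
#'
#' @param gene_symbols ordered character vector of panel gene symbols
#' @param annotation_gene the anchor gene used to label mixture components
#' @return an object of class `MarkerPanel`
#' @export
marker_panel <- function(gene_symbols = default_marker_panel(),
                         annotation_gene = "Runx1") {
  gene_symbols <- as.character(gene_symbols)
  if (!length(gene_symbols)) stop("marker panel must be non-empty")
  if (anyDuplicated(gene_symbols)) stop("duplicate panel genes")
  structure(list(gene_symbols = gene_symbols,
                 annotation_gene = as.character(annotation_gene)),
            class = "MarkerPanel")
}

#' @rdname marker_panel
#' @export
default_marker_panel <- function() {
  c("Cdh5", "Kdr", "Pecam1", "Pcdh12", "Sox7",
    "Gfi1", "Gfi1b", "Myb", "Runx1", "Spi1")
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat("MarkerPanel:", paste(x$gene_symbols, collapse = ", "),
      sprintf("(anchor: %s)\n", x$annotation_gene))
  invisible(x)
}
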