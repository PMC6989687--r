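#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. `"tsv"` is a tab-separated table with
#' a header row, genes in rows and cells in columns (the common Smart-seq2
#' convention); set `transpose = TRUE` if the file holds cells in rows.
#' `"mtx"` is MatrixMarket sparse format with two plain-text sidecar files
#' (one name per line): `<path>.rownames` for genes and `<path>.colnames`
#' for cells (override via `rownames_path` / `colnames_path`).
#'
#' @param path file path
#' @param format `"tsv"` or `"mtx"`
#' @param transpose for tsv: `TRUE` if the file is cells-in-rows
#' @param rownames_path,colnames_path for mtx: sidecar name files
#' @return an `ExpressionMatrix` (gene classes all `"endogenous"`; apply
#'   [annotate_gene_classes()] afterwards)
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx"),
                                   transpose = FALSE,
                                   rownames_path = paste0(path, ".rownames"),
                                   colnames_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric values in expression table")
    if (!transpose) m <- t(m)  # file is genes x cells; container is cells x genes
  } else {
    sp <- Matrix::readMM(path)
    genes <- readLines(rownames_path)
    cells <- readLines(colnames_path)
    if (nrow(sp) != length(genes) || ncol(sp) != length(cells))
      stop("mtx dimensions do not match sidecar name files")
    m <- t(as.matrix(sp))
    dimnames(m) <- list(cells, genes)
  }
  eht_log("debug", "read ", nrow(m), " cells x ", ncol(m), " genes from ", path)
  expression_matrix(m)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression_matrix()]; the tsv writer emits genes in rows
#' with full precision (15 significant digits) so a read/write round trip
#' preserves values. The mtx writer drops exact zeros (sparsity pattern) and
#' writes the two sidecar name files.
#'
#' @param matrix an `ExpressionMatrix`
#' @param path output file path
#' @inheritParams read_expression_matrix
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(matrix, path, format = c("tsv", "mtx"),
                                    rownames_path = paste0(path, ".rownames"),
                                    colnames_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (format == "tsv") {
    gxc <- t(matrix$values)  # genes in rows on disk
    tab <- data.frame(gene_id = rownames(gxc), gxc, check.names = FALSE)
    utils::write.table(format(tab, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(matrix$values), sparse = TRUE), path)
    writeLines(gene_ids(matrix), rownames_path)
    writeLines(cell_ids(matrix), colnames_path)
  }
  invisible(path)
}

#' Read a per-cell mapped-read-count table
#'
#' Tab-separated, two columns with header: `cell_id`, `mapped_reads`.
#'
#' @param path file path
#' @return data.frame with columns `cell_id` (character) and `mapped_reads`
#'   (non-negative numeric)
#' @export
read_read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = c("character", "numeric"))
  if (!all(c("cell_id", "mapped_reads") %in% names(tab)))
    stop("read-count table needs columns cell_id, mapped_reads")
  if (anyDuplicated(tab$cell_id)) stop("duplicate cell_id in read-count table")
  if (any(tab$mapped_reads < 0)) stop("mapped_reads must be non-negative")
  tab[c("cell_id", "mapped_reads")]
}

#' @rdname read_read_counts
#' @param reads data.frame as returned by `read_read_counts`
#' @export
write_read_counts <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker-panel file
#'
#' Plain text, one gene symbol per line; the first line may optionally be
#' overridden as the annotation gene.
#'
#' @param path file path
#' @param annotation_gene anchor gene (default `"Runx1"`)
#' @return a `MarkerPanel`
#' @export
read_marker_panel <- function(path, annotation_gene = "Runx1") {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  marker_panel(genes, annotation_gene)
}

# Write a numeric-columned data.frame as TSV with a fixed 10-significant-digit
# rendering, so identical runs give byte-identical files.
write_result_table <- function(df, path, digits = 10) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "NA", formatC(signif(v, digits), digits = digits,
                                   format = "g"))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
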