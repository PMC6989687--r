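#' Per-cell quality control
#'
#' Flags cells with fewer than `min_reads` mapped reads (strictly less) or a
#' mitochondrial content strictly greater than `max_mito`. The mitochondrial
#' fraction is, by default, computed from expression units: the sum of
#' mitochondrial-gene expression over the sum of endogenous plus
#' mitochondrial expression for the cell, with spike-ins excluded from both
#' numerator and denominator. A per-cell read-based fraction may be supplied
#' instead via `mito_fraction`.
#'
#' A cell with zero total (non-spike-in) expression has an undefined
#' fraction; it is failed with reason `high_mito` and a logged warning.
#'
#' @param matrix an `ExpressionMatrix` with gene classes assigned
#' @param reads data.frame with columns `cell_id`, `mapped_reads`, covering
#'   every cell of the matrix
#' @param min_reads minimum mapped reads (default 500,000; fail iff `<`)
#' @param max_mito maximum mitochondrial fraction (default 0.30; fail iff `>`)
#' @param mito_fraction optional named numeric of per-cell mitochondrial
#'   read fractions, overriding the expression-based computation
#' @return data.frame of class `CellQCRecord` with columns `cell_id`,
#'   `mapped_reads`, `mito_fraction`, `pass`, `fail_reasons` (comma-joined,
#'   empty string iff `pass`)
#' @export
compute_qc <- function(matrix, reads, min_reads = 500000, max_mito = 0.30,
                       mito_fraction = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  cells <- cell_ids(matrix)
  missing <- setdiff(cells, reads$cell_id)
  if (length(missing))
    stop("cells missing from read-count table: ", paste(missing, collapse = ", "))
  mapped <- reads$mapped_reads[match(cells, reads$cell_id)]

  if (is.null(mito_fraction)) {
    non_spike <- matrix$gene_class != "spike_in"
    mito <- matrix$gene_class == "mitochondrial"
    denom <- rowSums(matrix$values[, non_spike, drop = FALSE])
    numer <- rowSums(matrix$values[, mito, drop = FALSE])
    frac <- numer / denom
    if (any(denom == 0)) {
      eht_log("warn", "cell(s) with zero non-spike-in expression; ",
              "mitochondrial fraction undefined, failing QC: ",
              paste(cells[denom == 0], collapse = ", "))
      frac[denom == 0] <- NA_real_
    }
  } else {
    frac <- mito_fraction[cells]
    if (anyNA(frac)) stop("mito_fraction missing for some cells")
  }

  low_depth <- mapped < min_reads
  high_mito <- is.na(frac) | frac > max_mito
  reasons <- ifelse(low_depth & high_mito, "low_depth,high_mito",
                    ifelse(low_depth, "low_depth",
                           ifelse(high_mito, "high_mito", "")))
  out <- data.frame(cell_id = cells, mapped_reads = mapped,
                    mito_fraction = frac, pass = !(low_depth | high_mito),
                    fail_reasons = reasons, stringsAsFactors = FALSE)
  class(out) <- c("CellQCRecord", "data.frame")
  out
}

#' Drop QC-failing cells from a matrix
#'
#' @param matrix an `ExpressionMatrix`
#' @param qc the QC table from [compute_qc()], covering all cells
#' @return the sub-matrix of passing cells, cell order preserved
#' @export
filter_cells <- function(matrix, qc) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  missing <- setdiff(cell_ids(matrix), qc$cell_id)
  if (length(missing))
    stop("cells missing from QC table: ", paste(missing, collapse = ", "))
  keep <- qc$cell_id[qc$pass]
  eht_log("info", "QC retained ", length(intersect(cell_ids(matrix), keep)),
          " of ", nrow(matrix$values), " cells")
  subset_cells(matrix, intersect(cell_ids(matrix), keep))
}

#' Rescale TPM excluding spike-ins
#'
#' Drops spike-in genes and rescales each cell so the retained (endogenous
#' plus mitochondrial) genes sum to exactly 1e6, i.e. TPM over endogenous
#' gene expression only. Ratios between retained genes are preserved.
#'
#' @param matrix an `ExpressionMatrix`
#' @return an `ExpressionMatrix` without spike-in genes, rows summing to 1e6
#' @export
rescale_tpm_excluding_spikeins <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  keep <- matrix$gene_class != "spike_in"
  vals <- matrix$values[, keep, drop = FALSE]
  tot <- rowSums(vals)
  if (any(tot == 0))
    stop("cell(s) with all-zero non-spike-in expression: ",
         paste(rownames(vals)[tot == 0], collapse = ", "))
  expression_matrix(vals * (1e6 / tot), matrix$gene_class[keep])
}
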