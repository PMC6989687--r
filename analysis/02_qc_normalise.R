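#!/usr/bin/env Rscript
# Per-cell QC (mapped reads >= 500,000; mitochondrial content <= 30%) and
# spike-in-excluded TPM rescaling of the retained cells.

library(ehtmarkers)

mat <- annotate_gene_classes(
  read_expression_matrix("results/data/expression_tpm.tsv"))
reads <- read_read_counts("results/data/mapped_reads.tsv")

qc <- compute_qc(mat, reads)
write.table(qc, "results/qc.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

kept <- filter_cells(mat, qc)
rescaled <- rescale_tpm_excluding_spikeins(kept)
write_expression_matrix(rescaled, "results/data/expression_rescaled.tsv")

cat(sprintf("QC: %d of %d cells retained (%d low_depth, %d high_mito discarded).\n",
            sum(qc$pass), nrow(qc),
            sum(grepl("low_depth", qc$fail_reasons)),
            sum(grepl("high_mito", qc$fail_reasons))))
cat(sprintf("Rescaled matrix: every cell sums to 1e6 TPM over %d non-spike-in genes.\n",
            ncol(rescaled$values)))
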