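#!/usr/bin/env Rscript
# Generate the synthetic AGM single-cell dataset at study conditions:
# 78 analysable cells (10 haematopoietic), 2000 endogenous genes with a
# ten-gene marker panel and 25 planted markers (Cd44-role strongest),
# 92 ERCC spike-ins at 2% of TPM, 13 mitochondrial genes, and 10 injected
# QC failures (5 low-depth, 5 high-mito). Everything downstream reads the
# files written here.

library(ehtmarkers)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = 20260930L)
ds <- generate_dataset(cfg)

write_expression_matrix(ds$matrix, "results/data/expression_tpm.tsv")
write_read_counts(ds$reads, "results/data/mapped_reads.tsv")
write.table(data.frame(cell_id = names(ds$truth$cell_label),
                       true_label = unname(ds$truth$cell_label)),
            "results/data/ground_truth_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(ds$truth$planted_markers, "results/data/planted_markers.txt")
yaml::write_yaml(unclass(cfg), "results/data/simulation_config.yaml")

cat(sprintf("Simulated %d cells x %d genes; %d haematopoietic, %d QC failures planted.\n",
            nrow(ds$matrix$values), ncol(ds$matrix$values),
            sum(ds$truth$cell_label == "haematopoietic"),
            sum(startsWith(ds$truth$cell_label, "qc_fail"))))
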