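#!/usr/bin/env Rscript
# Downstream enrichment of the significant markers: one-sided Fisher exact
# test against a synthetic gene-category map (a stand-in for a metabolic
# annotation), and reporter-metabolite scoring of the scan p-values over a
# synthetic gene-metabolite bipartite network.

library(ehtmarkers)

tab <- read.delim("results/markers.tsv")
universe <- tab$gene_id
hits <- tab$gene_id[tab$p_bonferroni < 0.05]

# synthetic annotation: a quarter of the tested genes are "metabolic"
cm <- generate_category_map(universe, 0.25, seed = 515L)
enr <- fisher_enrichment(hits, cm$gene_id[cm$in_category], universe)
write.table(as.data.frame(unclass(enr)), "results/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Fisher: %d/%d selected vs %d/%d background; %.2f-fold, p = %.3g.\n",
            enr$x, enr$n, enr$K, enr$N, enr$fold, enr$p_one_sided))

net <- generate_metabolite_network(universe, 300, lambda = 4, seed = 516L)
gp <- setNames(tab$p_raw, tab$gene_id)
rep_tab <- reporter_scores(gp, net, n_background = 4000, seed = 517L)
write.table(rep_tab, "results/reporter.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Reporter metabolites scored: %d; %d with p_met < 0.05; top: %s (z_corrected %.2f).\n",
            nrow(rep_tab), sum(rep_tab$p_met < 0.05),
            rep_tab$metabolite_id[1], rep_tab$z_corrected[1]))
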