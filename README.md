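# ehtmarkers

Finding the rare cells that become blood — and the genes that mark them.

During mouse embryogenesis, a small subset of aortic endothelial cells in
the aorta-gonad-mesonephros (AGM) region undergoes the
endothelial-to-haematopoietic transition (EHT) and gives rise to definitive
blood stem and progenitor cells. In plate-based single-cell RNA-seq of
sorted AGM endothelium these transitioning cells are a ~10-cell minority
among ~80 analysable cells; finding them, and nominating surface markers
(such as **Cd44**) that isolate them prospectively, is a computational
problem. `ehtmarkers` implements that analysis as a tested R pipeline for
anyone working with TPM-quantified plate data:

1. **QC** — discard cells with < 500,000 mapped reads or > 30%
   mitochondrial content (both thresholds strict);
2. **normalisation** — drop ERCC spike-ins and rescale each cell's TPM to
   sum to 1e6 over endogenous genes;
3. **classification** — PCA on the log-transformed ten-gene panel (Cdh5,
   Kdr, Pecam1, Pcdh12, Sox7, Gfi1, Gfi1b, Myb, Runx1, Spi1), then a
   two-component Gaussian mixture on PC1/PC2, the Runx1-high component
   labelled haematopoietic;
4. **marker scan** — per-gene likelihood-ratio test
   `Λ = n·ln(RSS_null/RSS_alt)` (χ², 1 df) of a binary group term on
   log(TPM+1), Bonferroni-corrected over the tested genes;
5. **enrichment** — one-sided Fisher exact test with fold enrichment
   `(x/n)/(K/N)`, and reporter-metabolite scoring
   `z_agg = Σ Φ⁻¹(1−p_g)/√k` corrected against size-matched random gene
   sets over a gene–metabolite network;
6. **group statistics** — Welch's unequal-variance t-test with
   Welch–Satterthwaite df, computable directly from printed means/SDs/sizes.

A synthetic-data generator with planted ground truth (`generate_dataset()`)
emulates the study conditions — 78 passing cells, 10 haematopoietic, 25
planted markers, spike-ins, injected QC failures — so every stage is
verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic dataset; each prints what it found:

```sh
Rscript analysis/01_simulate.R      # Simulated 88 cells x 2105 genes; 10 haematopoietic, 10 QC failures planted.
Rscript analysis/02_qc_normalise.R  # QC: 78 of 88 cells retained (5 low_depth, 5 high_mito discarded).
Rscript analysis/03_classify.R      # Mixture found 10 haematopoietic cells; 10/10 match the planted truth.
Rscript analysis/04_marker_scan.R   # Planted markers recovered: 25/25; Cd44-role gene ranks 5 (effect 3.19, p_bonf 3.90e-21).
Rscript analysis/05_enrichment.R    # Fisher: 5/30 selected vs 493/2013 background; 0.68-fold, p = 0.893.
Rscript analysis/06_group_stats.R   # Welch's t-test: t(6.7) = 2.633, p = 0.0351 (two-sided).
```

Reading the output: QC removes exactly the ten injected failures; the
Gaussian mixture recovers the planted haematopoietic cells perfectly; all
25 planted markers clear Bonferroni-corrected p < 0.05 with the Cd44-role
gene among the very top (the four genes above it are haematopoietic panel
genes, which are genuinely differential by construction); the Fisher result
is null, as it should be — the synthetic category map is independent of the
planted markers; and the Welch recomputation from two-decimal summaries
(means 22.13 vs 30.88, SDs 4.85 vs 5.08, n = 4 vs 5) gives t(6.7) = 2.633,
matching the published 2.635 to input-rounding accuracy. Tables land in
`results/`.

Or in R, end to end:

```r
library(ehtmarkers)
man <- run_pipeline(list(synthetic = list(), seed = 1), "results/run1")
man$n_cells_retained   # 78
man$n_haematopoietic   # 10
```

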