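---
title: "Identifying haematopoietic-transitioning cells and their markers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying haematopoietic-transitioning cells and their markers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehtmarkers)
options(ehtmarkers.log_level = "warn")
```

## The problem

During mouse embryogenesis, definitive blood stem and progenitor cells arise
in the aorta-gonad-mesonephros (AGM) region when a subset of aortic
endothelial cells undergoes the endothelial-to-haematopoietic transition
(EHT). In a plate-based (Smart-seq2/Fluidigm C1) single-cell RNA-seq
experiment on sorted AGM endothelium, these transitioning cells form a small
minority that must be found computationally before surface markers suitable
for prospective isolation — Cd44 being the headline candidate — can be
nominated. `ehtmarkers` implements that computational chain as a reusable,
tested pipeline: per-cell quality control, spike-in-excluded TPM rescaling,
marker-panel PCA with two-component Gaussian-mixture classification, a
genome-wide likelihood-ratio marker scan under Bonferroni family-wise error
control, and two downstream enrichment analyses (Fisher's exact test and
reporter-metabolite scoring). A Welch t-test from summary statistics rounds
out the statistical toolkit for recomputing figure-legend comparisons.

## Quality control and normalisation

Each cell is kept only if it has at least 500,000 mapped reads and a
mitochondrial content of at most 30%. Both thresholds are strict as
stated: a cell fails if `mapped_reads < 500000` or `mito_fraction > 0.30`,
so a cell sitting exactly on either boundary passes. The mitochondrial
fraction is computed from expression units — mitochondrial-gene TPM over
endogenous-plus-mitochondrial TPM, spike-ins excluded from both sides —
because the pipeline consumes TPM matrices rather than raw reads; a
read-derived per-cell fraction can be supplied instead via the
`mito_fraction` argument of `compute_qc()` when alignment statistics are
available. A cell with zero non-spike-in expression has an undefined
fraction and is failed (reason `high_mito`) with a logged warning.

After filtering, TPM values are rescaled to exclude ERCC spike-in
expression: spike-in genes are dropped and every cell is rescaled so its
remaining genes sum to exactly 1e6. Mitochondrial genes are retained at
this step — only spike-ins, which are exogenous standards, are removed.
Ratios between retained genes are unchanged.

## Classification on the marker panel

Cells are classified on a ten-gene panel — Cdh5, Kdr, Pecam1, Pcdh12, Sox7
(endothelial identity) and Gfi1, Gfi1b, Myb, Runx1, Spi1 (haematopoietic
programme). The pipeline takes `ln(TPM + 1)` of the panel genes, centres
each gene (no unit-variance scaling), and keeps the first two principal
components. A two-component full-covariance Gaussian mixture is then fitted
to the 2-D scores by EM with ten restarts; each restart is seeded
k-means++-style (first centre uniform, second proportional to squared
distance). Component covariances get a ridge of 1e-6 times the mean score
variance on their diagonals so the likelihood stays bounded; a component
carrying fewer than 2/n cells flags the fit as degenerate rather than
failing silently. Cells are hard-assigned to their maximum-responsibility
component, and the component with the larger responsibility-weighted mean
log Runx1 expression is labelled haematopoietic. An exact tie in that
statistic is an error: the anchor gene then carries no information and the
caller must choose another.

Several choices here were genuinely open and are pinned for
reproducibility rather than inferred: the log base (natural; any fixed base
yields identical assignments up to covariance rescaling), unscaled PCA (the
minimal reading of "PCA on log-transformed values"), unconstrained
covariances, hard assignment, and dropping — not imputing — panel genes
absent from a matrix. `log(x + 1)` breaks exact scale invariance of the
end-to-end classification, so multiplying all TPM by a constant is only
neutral if applied before rescaling; the test suite documents this
behaviour rather than asserting an invariance that does not hold.

## The marker scan

For every gene with positive total variance, a Gaussian likelihood-ratio
test compares a null model with one common mean against an alternative with
separate haematopoietic/endothelial means, both with a shared
maximum-likelihood (1/n) variance. The statistic is

$$\Lambda = n \,\ln\!\frac{\mathrm{RSS}_\mathrm{null}}{\mathrm{RSS}_\mathrm{alt}},$$

referred to a chi-square distribution with one degree of freedom; it is
algebraically the pooled-variance two-sample t-test through
$\Lambda = n \ln(1 + t^2/(n-2))$, an identity the tests exploit as an
independent oracle. Shared variance is the minimal linear-model reading of
"a binary group term"; a Welch-style unequal-variance scan is deliberately
out of scope. P-values are Bonferroni-corrected with `m` equal to the
number of genes actually tested — constant genes are excluded from testing
and from `m`. Genes are ranked by raw p-value, ties broken by decreasing
absolute effect (difference of group means of log expression) and then
lexicographically, so output order is deterministic. Perfect separation
(zero within-group variance with positive total variance) is reported as
p = 0 with an explicit `separated` flag. `volcano_table()` floors p at
1e-300 before taking `-log10` so such genes stay plottable.

## Enrichment

`fisher_enrichment()` tests over-representation of a gene category among
the selected (significant) genes with the one-sided hypergeometric tail
`P(X >= x)` and reports fold enrichment `(x/n)/(K/N)`. The background
universe is always an explicit argument — by default the genes tested in
the scan, not a whole annotation, since enrichment against an inflated
universe is anti-conservative. A two-sided variant is exposed but
non-default.

`reporter_scores()` aggregates gene-level p-values over a bipartite
gene-metabolite network: per gene $z_g = \Phi^{-1}(1 - p_g)$ (p clipped to
$[10^{-15}, 1 - 10^{-15}]$ to keep the quantile finite), per metabolite
with $k$ scored neighbours $z_{agg} = \sum z_g / \sqrt{k}$, corrected
against the empirical mean and SD of `n_background` random size-$k$ gene
sets drawn from the scored genes, and converted to
$p = 1 - \Phi(z_{corrected})$. This is the standard inverse-normal
reporter-feature formulation with a size-matched sampled background,
stated here explicitly because published descriptions often cite it only
by name; directional variants (splitting up/down-regulation) are not
implemented. Metabolites with no scored neighbours are omitted, not
zero-filled.

## Welch's t-test from summaries

`welch_from_summary()` computes $t$, Welch–Satterthwaite degrees of
freedom and a two-sided p-value from printed means, sample SDs (n − 1
denominator assumed) and sizes, with the sign convention group 2 minus
group 1. Recomputing a published comparison from rounded summaries
reproduces printed statistics only to input-rounding accuracy — e.g.
summaries printed to two decimals give t = 2.633 where unrounded data gave
2.635 — so agreement within 0.01 is the meaningful check.

## What the synthetic data emulate — and what they do not

`generate_dataset()` is first-class, tested code whose defaults encode the
study conditions: 78 analysable cells containing a 10-cell haematopoietic
minority, 2000 endogenous genes, 92 ERCC spike-ins at 2% of per-cell TPM,
the 13 mouse mitochondrial protein-coding genes, 5 injected low-depth
failures (under 500,000 reads) and 5 high-mito failures (fraction 0.35 to
0.55 against a passing range of 0.02 to 0.20). Expression is log-normal:
gene $g$ in cell $c$ is $\exp(N(\mu_g + \delta_{gc}, \sigma))$ with
gene-level baselines $\mu_g \sim N(2, 1.5^2)$ and noise $\sigma = 0.7$ on
the natural-log scale. Haematopoietic cells switch on the five
haematopoietic panel genes (shift 3.5) while retaining endothelial-gene
expression, as transitioning cells do, and carry 25 planted markers at
shift 2.0 — except the Cd44-role gene, planted at 1.5 x that effect to
emulate its status as one of the strongest markers; without this the five
haematopoietic panel genes, which are genuinely differential by
construction, would stochastically displace it from the top of the
ranking. Mapped read depths are log-normal around 1.5 million. All
randomness flows from one seed through named sub-streams, so adding a
stream never perturbs another and a fixed seed gives bit-identical output.
Spike-in content is a direct TPM fraction rather than a dilution model: a
physical 1-in-4000 dilution does not fix a read fraction, so the fraction
itself is the honest parameter. Library-size and mitochondrial-fraction
distributions are stated defaults, not fitted to data.

The generator deliberately omits several features of real plate data:
there is no count layer (the pipeline consumes TPM and its tests operate
on log TPM, so a negative-binomial stage would add nothing testable), no
explicit dropout/zero inflation (low-$\mu$ tails produce near-zeros
implicitly), no gene-length or GC effects, and no doublets. Passing tests
therefore demonstrate correctness of the computations under a clean
log-normal world with planted truth — they do not certify behaviour under
real-data pathologies such as zero-inflated bimodality or ambient
contamination.

## Numerical choices and problem sizes

PCA is computed by SVD with the loading sign fixed so each component's
largest-magnitude entry is positive. EM stops when the log-likelihood
improves by less than 1e-7 or after 500 iterations, whichever is first;
the best of ten restarts is returned, and fitting is deterministic given
its seed. Result tables are written with 10 significant digits, making
repeat runs byte-identical. The test suite exercises the pipeline at the
default 88-cell x 2105-gene scale and verifies calibration with 200
permutation replicates for family-wise error, 1000 random instances for
the LRT oracles, an exhaustive hypergeometric enumeration sweep for the
Fisher test, and 1000 metabolites with 4000 background sets per degree for
reporter calibration — sizes chosen to give tight Monte-Carlo bounds while
keeping a full run in a few minutes.

## Limitations

The pipeline reproduces the published analysis logic, not the published
dataset: recomputing the real 78-cell result requires the deposited raw
data and re-quantification, which is outside this package's scope, and the
printed bulk-RNA-seq enrichment (395 of 1605 genes, 1.32-fold) cannot be
recomputed because its background universe is not stated. The number of
mixture components is fixed at two by design; model selection over
components, t-SNE/UMAP embeddings, count-based differential expression and
FDR procedures other than Bonferroni are all out of scope.
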