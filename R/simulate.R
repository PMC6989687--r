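#' Configuration for the synthetic AGM single-cell dataset
#'
#' The generator emulates the analysable portion of a Smart-seq2 plate from
#' the embryonic aorta-gonad-mesonephros (AGM): a majority endothelial
#' population, a ~10-cell minority undergoing the endothelial-to-
#' haematopoietic transition (EHT), a ten-gene marker panel with bimodal
#' structure, planted differentially expressed marker genes (a "Cd44"-role
#' gene up in the EHT minority), ERCC spike-ins at a small read fraction,
#' the 13 mitochondrial protein-coding genes, and deliberately injected QC
#' failures (low sequencing depth; high mitochondrial content).
#'
#' Expression noise is log-normal: gene `g` in cell `c` is drawn as
#' `exp(Normal(mu_g + shift, noise_sd))` where `shift` is the planted
#' log-scale effect for marker genes in haematopoietic cells. Values are
#' then rescaled per cell so endogenous + spike-in TPM sums to 1e6 with
#' spike-ins at exactly `spike_in_fraction` and the mitochondrial share of
#' the non-spike-in total at the cell's target fraction.
#'
#' @param n_cells_pass cells passing QC (default 78)
#' @param n_haem haematopoietic cells among the passing cells (default 10)
#' @param n_genes endogenous genes, including panel and planted markers
#'   (default 2000)
#' @param n_markers_planted planted marker genes, the first of which plays
#'   the Cd44 role (default 25)
#' @param marker_effect natural-log mean shift of planted markers in
#'   haematopoietic cells (default 2.0)
#' @param cd44_effect shift for the Cd44-role gene; larger than the rest by
#'   default (1.5 x `marker_effect`) because the emulated study singles
#'   Cd44 out as one of the strongest markers
#' @param base_log_mean_sd length-2 numeric: mean and SD of the gene-level
#'   baseline log-mean distribution
#' @param noise_sd per-gene log-scale noise SD
#' @param spike_in_fraction fraction of each cell's TPM assigned to
#'   spike-ins (default 0.02)
#' @param n_spike_ins number of ERCC spike-in genes (default 92)
#' @param n_mito number of mitochondrial genes (default 13, the mouse
#'   protein-coding complement)
#' @param n_fail_depth,n_fail_mito injected QC failures of each kind
#' @param depth_mean mean mapped reads for passing cells (default 1.5e6)
#' @param seed integer seed; all randomness flows from it via named
#'   sub-streams
#' @return a validated list of class `SimulationConfig`
#' @export
simulation_config <- function(n_cells_pass = 78L, n_haem = 10L,
                              n_genes = 2000L, n_markers_planted = 25L,
                              marker_effect = 2.0,
                              cd44_effect = 1.5 * marker_effect,
                              base_log_mean_sd = c(2.0, 1.5),
                              noise_sd = 0.7,
                              spike_in_fraction = 0.02,
                              n_spike_ins = 92L, n_mito = 13L,
                              n_fail_depth = 5L, n_fail_mito = 5L,
                              depth_mean = 1500000L, seed = 1L) {
  cfg <- list(n_cells_pass = as.integer(n_cells_pass),
              n_haem = as.integer(n_haem),
              n_genes = as.integer(n_genes),
              n_markers_planted = as.integer(n_markers_planted),
              marker_effect = marker_effect, cd44_effect = cd44_effect,
              base_log_mean_sd = base_log_mean_sd, noise_sd = noise_sd,
              spike_in_fraction = spike_in_fraction,
              n_spike_ins = as.integer(n_spike_ins),
              n_mito = as.integer(n_mito),
              n_fail_depth = as.integer(n_fail_depth),
              n_fail_mito = as.integer(n_fail_mito),
              depth_mean = depth_mean, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_haem < n_cells_pass, n_haem >= 0,
              spike_in_fraction > 0, spike_in_fraction < 1,
              n_genes >= n_markers_planted + 10L,
              n_markers_planted >= 1L,
              length(base_log_mean_sd) == 2L, base_log_mean_sd[2] > 0,
              noise_sd > 0, n_spike_ins >= 1L, n_mito >= 1L,
              n_fail_depth >= 0L, n_fail_mito >= 0L, depth_mean > 500000)
  })
  structure(cfg, class = "SimulationConfig")
}

# Mouse mitochondrial protein-coding gene symbols (exactly 13); recycled with
# numeric suffixes if a config asks for more.
mito_gene_names <- function(n) {
  base <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
            "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
            "mt-Cytb")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("mt-x%02d", seq_len(n - length(base))))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' See [simulation_config()] for the generative model. The returned ground
#' truth records each cell's label (`endothelial`, `haematopoietic`,
#' `qc_fail_depth`, `qc_fail_mito`), the planted marker genes, and the
#' mapping from panel roles to synthetic gene identifiers (the identity map:
#' synthetic panel genes carry the real symbols).
#'
#' Panel structure mirrors the emulated biology: the five endothelial panel
#' genes (Cdh5, Kdr, Pecam1, Pcdh12, Sox7) are expressed in all cells, the
#' five haematopoietic panel genes (Gfi1, Gfi1b, Myb, Runx1, Spi1) only in
#' the haematopoietic minority, which retains endothelial-gene expression
#' as transitioning cells do.
#'
#' @param config a `SimulationConfig`
#' @return list with elements `matrix` (`ExpressionMatrix`, QC-failing cells
#'   included), `reads` (data.frame `cell_id`, `mapped_reads`) and `truth`
#'   (class `GroundTruth`: `cell_label` named character, `planted_markers`,
#'   `marker_panel_map`, `mito_fraction_target` named numeric)
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  n_cells <- cfg$n_cells_pass + cfg$n_fail_depth + cfg$n_fail_mito

  panel <- default_marker_panel()
  endo_panel <- panel[1:5]
  haem_panel <- panel[6:10]
  marker_names <- c("Cd44", sprintf("marker_%02d", seq_len(cfg$n_markers_planted - 1L) + 1L))
  n_other <- cfg$n_genes - length(panel) - cfg$n_markers_planted
  other_names <- sprintf("gene_%04d", seq_len(n_other))
  endo_genes <- c(panel, marker_names, other_names)
  mito_genes <- mito_gene_names(cfg$n_mito)
  spike_genes <- sprintf("ERCC-%05d", seq_len(cfg$n_spike_ins))
  genes <- c(endo_genes, mito_genes, spike_genes)

  cells <- sprintf("cell_%03d", seq_len(n_cells))
  label <- rep(c("endothelial", "haematopoietic", "qc_fail_depth", "qc_fail_mito"),
               c(cfg$n_cells_pass - cfg$n_haem, cfg$n_haem,
                 cfg$n_fail_depth, cfg$n_fail_mito))
  label <- with_substream(cfg$seed, "cell_order", sample(label))
  names(label) <- cells
  is_haem <- label == "haematopoietic"

  # gene-level baselines
  mu <- with_substream(cfg$seed, "baselines", {
    m <- stats::rnorm(length(genes), cfg$base_log_mean_sd[1], cfg$base_log_mean_sd[2])
    names(m) <- genes
    m[endo_panel] <- 4.0          # endothelial identity genes: on everywhere
    m[haem_panel] <- 0.5          # haematopoietic panel: off in endothelium
    m[mito_genes] <- 3.0
    m
  })

  # per-cell x per-gene log means, with planted shifts in haematopoietic cells
  shift <- matrix(0, n_cells, length(genes), dimnames = list(cells, genes))
  shift[is_haem, haem_panel] <- 3.5  # panel bimodality: haem cells switch on
  shift[is_haem, marker_names] <- cfg$marker_effect
  shift[is_haem, "Cd44"] <- cfg$cd44_effect

  raw <- with_substream(cfg$seed, "expression", {
    noise <- matrix(stats::rnorm(n_cells * length(genes), 0, cfg$noise_sd),
                    n_cells, length(genes))
    exp(sweep(shift + noise, 2L, mu, `+`))
  })

  # per-cell target mitochondrial fraction of the non-spike-in total
  mito_target <- with_substream(cfg$seed, "mito_fraction", {
    f <- stats::runif(n_cells, 0.02, 0.20)
    f[label == "qc_fail_mito"] <- stats::runif(cfg$n_fail_mito, 0.35, 0.55)
    stats::setNames(f, cells)
  })

  # rescale blocks so each cell sums to exactly 1e6 TPM with the stated
  # spike-in fraction and mitochondrial share
  s <- cfg$spike_in_fraction
  endo_cols <- genes %in% endo_genes
  mito_cols <- genes %in% mito_genes
  spike_cols <- genes %in% spike_genes
  vals <- raw
  for (blk in list(list(endo_cols, (1 - mito_target) * (1 - s) * 1e6),
                   list(mito_cols, mito_target * (1 - s) * 1e6),
                   list(spike_cols, rep(s * 1e6, n_cells)))) {
    cols <- blk[[1]]; target <- blk[[2]]
    vals[, cols] <- raw[, cols] * (target / rowSums(raw[, cols, drop = FALSE]))
  }

  reads <- with_substream(cfg$seed, "depths", {
    depth <- round(stats::rlnorm(n_cells, log(cfg$depth_mean), 0.2))
    fail <- label == "qc_fail_depth"
    depth[fail] <- round(stats::runif(sum(fail), 1e5, 499999))
    depth[!fail] <- pmax(depth[!fail], 500000)
    data.frame(cell_id = cells, mapped_reads = depth,
               stringsAsFactors = FALSE)
  })

  cls <- ifelse(spike_cols, "spike_in",
                ifelse(mito_cols, "mitochondrial", "endogenous"))
  truth <- structure(
    list(cell_label = label,
         planted_markers = marker_names,
         marker_panel_map = stats::setNames(panel, panel),
         mito_fraction_target = mito_target),
    class = "GroundTruth")
  list(matrix = expression_matrix(vals, cls), reads = reads, truth = truth)
}

#' Generate a random gene-category membership map
#'
#' Each gene joins the category independently with probability
#' `category_fraction`; used as input to Fisher-exact enrichment testing.
#'
#' @param n_genes number of genes (or a character vector of gene ids)
#' @param category_fraction membership probability in `[0, 1]`
#' @param seed integer seed
#' @return data.frame with columns `gene_id`, `in_category` (logical)
#' @export
generate_category_map <- function(n_genes, category_fraction, seed = 1L) {
  stopifnot(category_fraction >= 0, category_fraction <= 1)
  ids <- if (is.character(n_genes)) n_genes else sprintf("gene_%04d", seq_len(n_genes))
  member <- with_substream(seed, "category_map",
                           stats::runif(length(ids)) < category_fraction)
  data.frame(gene_id = ids, in_category = member, stringsAsFactors = FALSE)
}

#' Generate a random bipartite gene-metabolite network
#'
#' Each metabolite is connected to `k >= 1` distinct genes, with `k` drawn
#' as 1 + Poisson(`lambda`); used as input to reporter-metabolite scoring.
#'
#' @param n_genes number of genes (or a character vector of gene ids)
#' @param n_metabolites number of metabolites
#' @param lambda Poisson rate of the degree law (mean degree `1 + lambda`)
#' @param seed integer seed
#' @return data.frame edge list with columns `metabolite_id`, `gene_id`
#' @export
generate_metabolite_network <- function(n_genes, n_metabolites, lambda = 4,
                                        seed = 1L) {
  stopifnot(n_metabolites >= 1, lambda >= 0)
  ids <- if (is.character(n_genes)) n_genes else sprintf("gene_%04d", seq_len(n_genes))
  stopifnot(length(ids) >= 1)
  with_substream(seed, "metabolite_network", {
    k <- pmin(1L + stats::rpois(n_metabolites, lambda), length(ids))
    edges <- lapply(seq_len(n_metabolites), function(i) {
      data.frame(metabolite_id = sprintf("met_%04d", i),
                 gene_id = ids[sample.int(length(ids), k[i])],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, edges)
  })
}
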