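#' End-to-end pipeline run
#'
#' Orchestrates the full analysis: obtain an expression matrix and
#' read-count table (either generated synthetically or read from files),
#' annotate gene classes, run per-cell QC, drop failing cells, rescale TPM
#' excluding spike-ins, classify cells on the marker panel, scan all genes
#' for markers, and — when a category map and/or gene-metabolite network is
#' supplied — run Fisher enrichment of the significant markers and
#' reporter-metabolite scoring of the scan p-values.
#'
#' The configuration is a plain list (readable from YAML via
#' [read_run_config()]) with exactly one of:
#' \describe{
#'   \item{`synthetic`}{a [simulation_config()] (or argument list for it)}
#'   \item{`input`}{list with `matrix` (path), `format`, `reads` (path)}
#' }
#' plus optional elements `min_reads` (default 500000), `max_mito` (0.30),
#' `panel` (a `MarkerPanel` or path to a panel file), `annotation_gene`,
#' `seed` (default 1; fanned out to per-stage sub-streams), `n_init` (10),
#' `alpha` (0.05, marker significance for enrichment), `category_map`
#' (data.frame or path), `network` (data.frame or path), `n_background`.
#'
#' All result tables are written with 10 significant digits so identical
#' configurations give byte-identical outputs.
#'
#' @param config run configuration list (see Details)
#' @param outdir output directory, created if needed
#' @return the manifest, invisibly: a list recording the configuration,
#'   seeds, package version, output files and their row counts, and the
#'   headline numbers (cells retained, haematopoietic count)
#' @export
run_pipeline <- function(config, outdir) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("config must have exactly one of 'synthetic' or 'input'")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  panel <- config$panel %||% marker_panel()
  if (is.character(panel))
    panel <- read_marker_panel(panel, config$annotation_gene %||% "Runx1")

  if (has_syn) {
    scfg <- config$synthetic
    if (!inherits(scfg, "SimulationConfig"))
      scfg <- do.call(simulation_config, as.list(scfg))
    scfg$seed <- substream_seed(seed, "simulate")
    ds <- generate_dataset(scfg)
    mat <- ds$matrix
    reads <- ds$reads
  } else {
    mat <- read_expression_matrix(config$input$matrix,
                                  config$input$format %||% "tsv")
    mat <- annotate_gene_classes(mat,
                                 config$spike_in_prefix %||% "ERCC-",
                                 config$mito_prefixes %||% "mt-")
    reads <- read_read_counts(config$input$reads)
  }

  qc <- compute_qc(mat, reads,
                   min_reads = config$min_reads %||% 500000,
                   max_mito = config$max_mito %||% 0.30)
  write_result_table(qc, file.path(outdir, "qc.tsv"))

  kept <- filter_cells(mat, qc)
  rescaled <- rescale_tpm_excluding_spikeins(kept)

  cls <- classify_cells(rescaled, panel,
                        n_init = config$n_init %||% 10L,
                        seed = substream_seed(seed, "gmm"))
  write_result_table(cls$labels$labels, file.path(outdir, "labels.tsv"))
  scores <- data.frame(cell_id = rownames(cls$pca$scores),
                       PC1 = cls$pca$scores[, 1], PC2 = cls$pca$scores[, 2],
                       stringsAsFactors = FALSE)
  write_result_table(scores, file.path(outdir, "pca_scores.tsv"))

  markers <- scan_all(log_transform(rescaled), cls$labels)
  write_result_table(markers, file.path(outdir, "markers.tsv"))

  alpha <- config$alpha %||% 0.05
  files <- c("qc.tsv", "labels.tsv", "pca_scores.tsv", "markers.tsv")

  if (!is.null(config$category_map)) {
    cm <- config$category_map
    if (is.character(cm)) cm <- utils::read.delim(cm, stringsAsFactors = FALSE)
    hits <- markers$gene_id[markers$p_bonferroni < alpha]
    # the background is the tested universe; category annotations outside it
    # are irrelevant to the test and dropped
    cat_genes <- intersect(cm$gene_id[as.logical(cm$in_category)],
                           markers$gene_id)
    if (!length(cat_genes))
      stop("no category genes overlap the tested gene universe")
    enr <- fisher_enrichment(hits, cat_genes, markers$gene_id)
    write_result_table(as.data.frame(unclass(enr)),
                       file.path(outdir, "enrichment.tsv"))
    files <- c(files, "enrichment.tsv")
  }

  if (!is.null(config$network)) {
    net <- config$network
    if (is.character(net)) net <- utils::read.delim(net, stringsAsFactors = FALSE)
    gp <- stats::setNames(markers$p_raw, markers$gene_id)
    rep_tab <- reporter_scores(gp, net,
                               n_background = config$n_background %||% 10000L,
                               seed = substream_seed(seed, "reporter"))
    write_result_table(rep_tab, file.path(outdir, "reporter.tsv"))
    files <- c(files, "reporter.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ehtmarkers")),
    seed = seed,
    thresholds = list(min_reads = config$min_reads %||% 500000,
                      max_mito = config$max_mito %||% 0.30),
    panel = panel$gene_symbols, annotation_gene = panel$annotation_gene,
    n_cells_input = nrow(qc), n_cells_retained = sum(qc$pass),
    n_haematopoietic = sum(cls$labels$labels$label == "haematopoietic"),
    n_genes_tested = markers$n_tested[1],
    outputs = lapply(stats::setNames(files, files), function(f)
      list(rows = length(readLines(file.path(outdir, f))) - 1L))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  eht_log("info", "pipeline complete: ", manifest$n_cells_retained,
          " cells retained, ", manifest$n_haematopoietic, " haematopoietic")
  invisible(manifest)
}

#' Read a pipeline run configuration from a YAML file
#'
#' @param path YAML file path
#' @return configuration list for [run_pipeline()]
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
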