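#' One-sided Fisher exact test for gene-category over-representation
#'
#' With `x` category genes among the `n` selected, `K` category genes among
#' the `N` background genes, the one-sided (enrichment) p-value is
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)` and the fold enrichment is
#' `(x/n) / (K/N)`. The background universe must be passed explicitly —
#' typically all genes tested in the marker scan, not a whole annotation.
#'
#' @param selected character vector of selected genes (subset of background)
#' @param category character vector of category genes (subset of background)
#' @param background character vector, the gene universe
#' @param alternative `"greater"` (default, enrichment-only) or
#'   `"two.sided"` (delegated to [stats::fisher.test()])
#' @return list of class `EnrichmentResult`: `x`, `n`, `K`, `N`, `fold`,
#'   `p_one_sided`
#' @export
fisher_enrichment <- function(selected, category, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  selected <- unique(as.character(selected))
  category <- unique(as.character(category))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  if (!length(category)) stop("empty category")
  if (length(setdiff(selected, background)))
    stop("selected genes not contained in background")
  if (length(setdiff(category, background)))
    stop("category genes not contained in background")
  N <- length(background)
  n <- length(selected)
  K <- length(category)
  x <- length(intersect(selected, category))
  if (n == 0) stop("empty selected set")
  p <- if (alternative == "greater") {
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(x, K - x, n - x, N - K - n + x), 2, 2),
                       alternative = "two.sided")$p.value
  }
  structure(list(x = x, n = n, K = K, N = N,
                 fold = (x / n) / (K / N), p_one_sided = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Fisher enrichment: %d/%d selected vs %d/%d background; %.2f-fold, p = %.3g\n",
              x$x, x$n, x$K, x$N, x$fold, x$p_one_sided))
  invisible(x)
}

#' Reporter-metabolite scoring over a gene-metabolite network
#'
#' Inverse-normal aggregation of gene-level p-values over the neighbourhood
#' of each metabolite in a bipartite gene-metabolite network, corrected
#' against size-matched random gene sets. Per gene, `z_g = qnorm(1 - p_g)`
#' after clipping p to `[1e-15, 1 - 1e-15]`. Per metabolite with `k` scored
#' neighbour genes, `z_agg = sum(z_g) / sqrt(k)`. For every distinct `k`,
#' `n_background` random size-`k` gene sets are drawn (without replacement
#' within a set) from the scored genes; their aggregate mean `mu_k` and SD
#' `sigma_k` give the corrected score `z_corrected = (z_agg - mu_k) /
#' sigma_k` and `p_met = 1 - pnorm(z_corrected)`.
#'
#' Network edges referencing genes without a p-value are dropped with a
#' logged warning; metabolites left without any scored neighbour are
#' omitted from the result, not zero-filled.
#'
#' @param gene_p named numeric vector of per-gene p-values
#' @param network data.frame edge list with columns `metabolite_id`,
#'   `gene_id`
#' @param n_background random background sets per distinct degree
#'   (default 10000)
#' @param seed integer seed for background sampling
#' @return data.frame of class `ReporterScoreTable`: `metabolite_id`, `k`,
#'   `z_agg`, `z_corrected`, `p_met`
#' @export
reporter_scores <- function(gene_p, network, n_background = 10000L,
                            seed = 1L) {
  stopifnot(is.numeric(gene_p), !is.null(names(gene_p)),
            all(c("metabolite_id", "gene_id") %in% names(network)),
            n_background >= 100)
  if (any(gene_p < 0 | gene_p > 1)) stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(gene_p, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(1 - p)

  unscored <- setdiff(unique(network$gene_id), names(z))
  if (length(unscored)) {
    eht_log("warn", length(unscored),
            " network gene(s) lack p-values; their edges are dropped")
    network <- network[network$gene_id %in% names(z), , drop = FALSE]
  }
  if (!nrow(network)) stop("no network edges reference scored genes")

  zsum <- tapply(z[network$gene_id], network$metabolite_id, sum)
  k <- tapply(network$gene_id, network$metabolite_id, length)
  mets <- names(zsum)
  k <- as.integer(k[mets])
  z_agg <- as.numeric(zsum) / sqrt(k)
  if (any(k > length(z)))
    stop("metabolite degree exceeds number of scored genes")

  # size-matched sampled background per distinct degree
  ks <- sort(unique(k))
  bg <- withr::with_seed(as.integer(seed), {
    res <- lapply(ks, function(kk) {
      agg <- vapply(seq_len(n_background), function(i)
        sum(z[sample.int(length(z), kk)]), numeric(1)) / sqrt(kk)
      c(mu = mean(agg), sigma = stats::sd(agg))
    })
    do.call(rbind, res)
  })
  rownames(bg) <- ks
  if (any(bg[, "sigma"] == 0)) stop("degenerate background (sigma = 0)")

  mu_k <- bg[as.character(k), "mu"]
  sd_k <- bg[as.character(k), "sigma"]
  z_corr <- (z_agg - mu_k) / sd_k
  out <- data.frame(metabolite_id = mets, k = k, z_agg = z_agg,
                    z_corrected = z_corr,
                    p_met = stats::pnorm(z_corr, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_met, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ReporterScoreTable", "data.frame")
  out
}
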