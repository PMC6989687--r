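#' Per-gene likelihood-ratio test for a binary group term
#'
#' Gaussian likelihood with maximum-likelihood (1/n) variance, shared across
#' groups. The null model fits one common mean; the alternative adds a
#' binary term for group membership (two group means). The statistic is
#' `n * ln(RSS_null / RSS_alt)` and is referred to the upper tail of a
#' chi-square with one degree of freedom. It is algebraically equivalent to
#' the pooled-variance two-sample t test via
#' `n * ln(1 + t^2 / (n - 2))`.
#'
#' Perfect separation (`RSS_alt = 0` with `RSS_null > 0`) yields an
#' infinite statistic; the p-value is reported as 0 with `separated = TRUE`.
#'
#' @param values per-cell log-expression vector
#' @param labels binary group vector (logical, or coercible to 0/1), same
#'   length; `TRUE`/1 is the haematopoietic group
#' @return list: `lrt_stat`, `p_raw`, `effect` (group-1 mean minus group-0
#'   mean), `separated`
#' @export
lrt_gene <- function(values, labels) {
  values <- as.numeric(values)
  g <- as.logical(labels)
  n <- length(values)
  stopifnot(length(g) == n, n >= 3, !anyNA(values), !anyNA(g))
  if (!any(g) || all(g)) stop("both groups must be non-empty")
  rss_null <- sum((values - mean(values))^2)
  m1 <- mean(values[g]); m0 <- mean(values[!g])
  rss_alt <- sum((values[g] - m1)^2) + sum((values[!g] - m0)^2)
  if (rss_alt == 0) {
    if (rss_null == 0)
      return(list(lrt_stat = 0, p_raw = 1, effect = m1 - m0, separated = FALSE))
    return(list(lrt_stat = Inf, p_raw = 0, effect = m1 - m0, separated = TRUE))
  }
  stat <- n * log(rss_null / rss_alt)
  list(lrt_stat = stat,
       p_raw = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       effect = m1 - m0, separated = FALSE)
}

#' Genome-wide marker scan with Bonferroni correction
#'
#' Applies [lrt_gene()] to every gene whose total variance exceeds
#' `min_variance` (zero-variance genes can never be markers and would make
#' the LRT 0/0), Bonferroni-adjusts the p-values with `m` equal to the
#' number of genes actually tested, and ranks genes by raw p-value with
#' ties broken by decreasing absolute effect and then gene identifier.
#'
#' The computation is vectorised across genes: residual sums of squares for
#' the common-mean and two-group-mean models are obtained from column sums,
#' so the scan over thousands of genes costs a few matrix passes.
#'
#' @param log_matrix log-transformed `ExpressionMatrix`
#' @param labels a `CellLabelSet`, or a named character/logical vector over
#'   cells where `"haematopoietic"`/`TRUE` marks group 1
#' @param min_variance genes with total variance `<=` this are excluded
#'   from testing and from the Bonferroni `m` (default 0)
#' @return data.frame of class `MarkerTable`, sorted, with columns
#'   `gene_id`, `lrt_stat`, `p_raw`, `p_bonferroni`, `effect`, `separated`,
#'   `n_tested`, `rank`
#' @export
scan_all <- function(log_matrix, labels, min_variance = 0) {
  stopifnot(inherits(log_matrix, "ExpressionMatrix"))
  x <- log_matrix$values
  g <- .group_indicator(labels, rownames(x))
  n <- nrow(x)
  n1 <- sum(g); n0 <- n - n1
  if (n1 < 2 || n0 < 2) stop("need at least 2 cells per group")

  mu <- colMeans(x)
  rss_null <- colSums(x^2) - n * mu^2
  tot_var <- rss_null / (n - 1)
  keep <- tot_var > min_variance
  if (!any(keep)) stop("all genes excluded by the variance guard")
  x <- x[, keep, drop = FALSE]
  rss_null <- rss_null[keep]

  m1 <- colSums(x[g, , drop = FALSE]) / n1
  m0 <- colSums(x[!g, , drop = FALSE]) / n0
  rss_alt <- colSums(x^2) - n1 * m1^2 - n0 * m0^2
  rss_alt <- pmax(rss_alt, 0)  # guard tiny negative rounding

  sep <- rss_alt <= .Machine$double.eps * rss_null
  stat <- ifelse(sep, Inf, n * log(rss_null / pmax(rss_alt, .Machine$double.xmin)))
  p <- ifelse(sep, 0, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  m <- sum(keep)
  out <- data.frame(gene_id = colnames(x), lrt_stat = stat, p_raw = p,
                    p_bonferroni = pmin(1, m * p), effect = m1 - m0,
                    separated = sep, n_tested = m, stringsAsFactors = FALSE)
  ord <- order(out$p_raw, -abs(out$effect), out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}

# Coerce the various accepted label representations to a logical vector
# aligned with `cells` (TRUE = haematopoietic).
.group_indicator <- function(labels, cells) {
  if (inherits(labels, "CellLabelSet")) {
    v <- stats::setNames(labels$labels$label == "haematopoietic",
                         labels$labels$cell_id)
  } else if (is.logical(labels)) {
    v <- labels
    if (is.null(names(v))) names(v) <- cells
  } else {
    v <- stats::setNames(as.character(labels) == "haematopoietic",
                         names(labels) %||% cells)
  }
  missing <- setdiff(cells, names(v))
  if (length(missing))
    stop("labels missing for cell(s): ", paste(missing, collapse = ", "))
  unname(v[cells])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Volcano-plot table
#'
#' Long-format plotting table of effect size against `-log10` of the
#' Bonferroni-adjusted p-value, with p floored at 1e-300 before taking the
#' log so separated genes stay finite.
#'
#' @param table a `MarkerTable`
#' @return data.frame with columns `gene_id`, `effect`, `neg_log10_p`
#' @export
volcano_table <- function(table) {
  stopifnot(inherits(table, "MarkerTable"), nrow(table) > 0)
  data.frame(gene_id = table$gene_id, effect = table$effect,
             neg_log10_p = -log10(pmax(table$p_bonferroni, 1e-300)),
             stringsAsFactors = FALSE)
}

#' Top-marker heatmap matrix
#'
#' Log-expression of the top `k` ranked marker genes across cells, with
#' cells ordered by group (haematopoietic first) — a plotting-ready
#' analogue of the marker heatmap.
#'
#' @param log_matrix log-transformed `ExpressionMatrix`
#' @param table a `MarkerTable`
#' @param labels a `CellLabelSet` (or label vector) for cell ordering
#' @param k number of top-ranked genes to include (default 20)
#' @return numeric matrix, genes x cells
#' @export
heatmap_matrix <- function(log_matrix, table, labels, k = 20L) {
  genes <- utils::head(table$gene_id, k)
  g <- .group_indicator(labels, cell_ids(log_matrix))
  cells <- c(cell_ids(log_matrix)[g], cell_ids(log_matrix)[!g])
  t(log_matrix$values[cells, genes, drop = FALSE])
}
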