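#' Natural-log transform of expression values
#'
#' Replaces every value `x` with `ln(x + 1)`. Any fixed log base gives the
#' same mixture assignments up to a rescaling of the covariances; natural
#' log is pinned for reproducibility.
#'
#' @param matrix an `ExpressionMatrix` (TPM units)
#' @return an `ExpressionMatrix` of log-transformed values
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  expression_matrix(log1p(matrix$values), matrix$gene_class)
}

#' PCA on the marker panel
#'
#' Principal component analysis of the log-transformed expression of the
#' marker-panel genes: columns (genes) are centred but not scaled, and the
#' first two components are retained for mixture modelling. Panel genes
#' absent from the matrix are dropped with a logged warning. The loading
#' sign is fixed so each component's largest-magnitude entry is positive,
#' making the result fully deterministic.
#'
#' @param log_matrix log-transformed `ExpressionMatrix`
#' @param panel a `MarkerPanel`
#' @return list of class `PCAResult`: `panel_genes_used`,
#'   `component_loadings` (2 x p), `explained_variance` (non-increasing
#'   pair), `scores` (cells x 2), `centering_means`
#' @export
marker_pca <- function(log_matrix, panel) {
  stopifnot(inherits(log_matrix, "ExpressionMatrix"),
            inherits(panel, "MarkerPanel"))
  if (nrow(log_matrix$values) < 3) stop("need at least 3 cells for PCA")
  used <- intersect(panel$gene_symbols, gene_ids(log_matrix))
  dropped <- setdiff(panel$gene_symbols, used)
  if (length(dropped))
    eht_log("warn", "panel gene(s) absent from matrix, dropped: ",
            paste(dropped, collapse = ", "))
  if (length(used) < 2) stop("fewer than 2 usable panel genes")
  x <- log_matrix$values[, used, drop = FALSE]
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (sum(xc^2) == 0) stop("panel sub-matrix has zero total variance")
  sv <- svd(xc, nu = 0, nv = 2)
  load <- t(sv$v)                      # 2 x p
  for (i in 1:2) {                     # sign convention
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  scores <- xc %*% t(load)
  colnames(scores) <- c("PC1", "PC2")
  ev <- sv$d[1:2]^2 / (nrow(x) - 1)
  structure(list(panel_genes_used = used, component_loadings = load,
                 explained_variance = ev, scores = scores,
                 centering_means = ctr),
            class = "PCAResult")
}

# log of the bivariate normal density, hand-rolled for the 2x2 case
.ldmvnorm2 <- function(x, mean, sigma) {
  d <- sweep(x, 2L, mean)
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det
  q <- rowSums((d %*% inv) * d)
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Full-covariance two-component Gaussian mixture on the 2-D principal
#' component scores, fitted by expectation-maximisation with `n_init`
#' restarts from k-means++-style seedings (first centre uniform, second
#' with probability proportional to squared distance). Covariances are
#' regularised by adding a ridge of `1e-6` times the mean score variance to
#' the diagonals. The restart with the highest final log-likelihood wins.
#'
#' A fit in which a component carries fewer than 2/n of the cells is
#' returned with `degenerate = TRUE` rather than silently.
#'
#' @param scores cells x 2 numeric matrix of PC scores
#' @param n_init number of EM restarts (default 10)
#' @param max_iter maximum EM iterations per restart (default 500)
#' @param tol absolute log-likelihood convergence tolerance (default 1e-7)
#' @param seed integer seed driving all restarts
#' @return list of class `MixtureFit`: `weights`, `means` (2 x 2, one row
#'   per component), `covariances` (list of two 2 x 2 matrices),
#'   `responsibilities` (cells x 2, rows summing to 1), `loglik`,
#'   `loglik_trace` (non-decreasing), `n_init`, `seed`, `degenerate`,
#'   `converged`
#' @export
fit_gmm2 <- function(scores, n_init = 10L, max_iter = 500L, tol = 1e-7,
                     seed = 1L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, all(is.finite(scores)), nrow(scores) >= 4L)
  n <- nrow(scores)
  ridge <- diag(2) * 1e-6 * mean(apply(scores, 2, stats::var))

  run_em <- function(mu) {
    # initial hard assignment to the two seeding centres
    d1 <- rowSums(sweep(scores, 2L, mu[1, ])^2)
    d2 <- rowSums(sweep(scores, 2L, mu[2, ])^2)
    z <- cbind(d1 <= d2, d1 > d2) * 1
    if (any(colSums(z) == 0)) z[which.max(abs(d1 - d2)), ] <- rev(z[which.max(abs(d1 - d2)), ])
    w <- colSums(z) / n
    pars <- list(w = w, mu = mu, sigma = list(diag(2), diag(2)))
    # M step from assignment z, then iterate E/M on soft responsibilities
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M step
      nk <- colSums(z)
      pars$w <- nk / n
      for (k in 1:2) {
        mk <- colSums(scores * z[, k]) / nk[k]
        d <- sweep(scores, 2L, mk)
        sk <- crossprod(d * z[, k], d) / nk[k] + ridge
        pars$mu[k, ] <- mk
        pars$sigma[[k]] <- sk
      }
      # E step
      lg <- cbind(log(pars$w[1]) + .ldmvnorm2(scores, pars$mu[1, ], pars$sigma[[1]]),
                  log(pars$w[2]) + .ldmvnorm2(scores, pars$mu[2, ], pars$sigma[[2]]))
      m <- pmax(lg[, 1], lg[, 2])
      ll <- sum(m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m)))
      z <- exp(lg - (m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(pars = pars, resp = z, trace = trace,
         loglik = trace[length(trace)], converged = converged)
  }

  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_init)) {
      i1 <- sample.int(n, 1L)
      d2 <- rowSums(sweep(scores, 2L, scores[i1, ])^2)
      i2 <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      fit <- run_em(scores[c(i1, i2), , drop = FALSE])
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  degenerate <- min(best$pars$w) < 2 / n
  if (degenerate)
    eht_log("warn", "degenerate mixture fit: smallest component weight ",
            format(min(best$pars$w), digits = 3))
  means <- best$pars$mu
  dimnames(means) <- list(c("comp1", "comp2"), colnames(scores))
  resp <- best$resp
  dimnames(resp) <- list(rownames(scores), c("comp1", "comp2"))
  structure(list(weights = best$pars$w, means = means,
                 covariances = best$pars$sigma, responsibilities = resp,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 degenerate = degenerate, converged = best$converged),
            class = "MixtureFit")
}

#' Log-likelihood of a 2-D two-component Gaussian mixture at fixed parameters
#'
#' Utility used to compare a fitted mixture against known (planted)
#' parameters.
#'
#' @param scores cells x 2 matrix
#' @param weights length-2 weights summing to 1
#' @param means 2 x 2 matrix of component means (rows)
#' @param covariances list of two 2 x 2 covariance matrices
#' @return scalar log-likelihood
#' @export
gmm2_loglik <- function(scores, weights, means, covariances) {
  scores <- as.matrix(scores)
  lg <- cbind(log(weights[1]) + .ldmvnorm2(scores, means[1, ], covariances[[1]]),
              log(weights[2]) + .ldmvnorm2(scores, means[2, ], covariances[[2]]))
  m <- pmax(lg[, 1], lg[, 2])
  sum(m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m)))
}

#' Label mixture components by the annotation gene
#'
#' Hard-assigns every cell to its maximum-responsibility component, then
#' labels haematopoietic the component with the strictly larger
#' responsibility-weighted mean log expression of the annotation gene
#' (Runx1 by default); the other component is endothelial. An exact tie in
#' the annotation statistic is an error — the caller must disambiguate.
#'
#' @param fit a `MixtureFit`
#' @param log_matrix the log-transformed `ExpressionMatrix` the scores came
#'   from
#' @param panel a `MarkerPanel` providing the annotation gene
#' @return list of class `CellLabelSet`: `labels` (data.frame `cell_id`,
#'   `label`, `responsibility` — the posterior probability of the assigned
#'   component), `component_map` (named int: haematopoietic/endothelial ->
#'   component index), `annotation_statistic` (per-component weighted mean)
#' @export
annotate_components <- function(fit, log_matrix, panel) {
  stopifnot(inherits(fit, "MixtureFit"),
            inherits(log_matrix, "ExpressionMatrix"),
            inherits(panel, "MarkerPanel"))
  gene <- panel$annotation_gene
  if (!gene %in% gene_ids(log_matrix))
    stop("annotation gene not in matrix: ", gene)
  x <- log_matrix$values[rownames(fit$responsibilities), gene]
  stat <- colSums(fit$responsibilities * x) / colSums(fit$responsibilities)
  if (stat[1] == stat[2])
    stop("annotation statistic tied between components; cannot assign labels")
  haem <- as.integer(which.max(stat))
  hard <- max.col(fit$responsibilities)
  labels <- data.frame(
    cell_id = rownames(fit$responsibilities),
    label = ifelse(hard == haem, "haematopoietic", "endothelial"),
    responsibility = fit$responsibilities[cbind(seq_along(hard), hard)],
    stringsAsFactors = FALSE)
  structure(list(labels = labels,
                 component_map = c(haematopoietic = haem,
                                   endothelial = 3L - haem),
                 annotation_statistic = unname(stat)),
            class = "CellLabelSet")
}

#' @export
print.CellLabelSet <- function(x, ...) {
  cat(sprintf("CellLabelSet: %d cells (%d haematopoietic, %d endothelial)\n",
              nrow(x$labels), sum(x$labels$label == "haematopoietic"),
              sum(x$labels$label == "endothelial")))
  invisible(x)
}

#' End-to-end classification of cells on the marker panel
#'
#' Convenience composition: log transform, marker-panel PCA, two-component
#' Gaussian mixture, annotation-gene labelling.
#'
#' @param matrix rescaled `ExpressionMatrix` (TPM)
#' @param panel a `MarkerPanel`
#' @param n_init,seed passed to [fit_gmm2()]
#' @return list with `labels` (`CellLabelSet`), `pca` (`PCAResult`), `fit`
#'   (`MixtureFit`)
#' @export
classify_cells <- function(matrix, panel = marker_panel(), n_init = 10L,
                           seed = 1L) {
  lm <- log_transform(matrix)
  pca <- marker_pca(lm, panel)
  fit <- fit_gmm2(pca$scores, n_init = n_init, seed = seed)
  labels <- annotate_components(fit, lm, panel)
  list(labels = labels, pca = pca, fit = fit)
}
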