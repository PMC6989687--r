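test_that("log transform is ln(x+1) and monotone", {
  em <- expression_matrix(matrix(c(0, exp(1) - 1, 5, 10), 2, 2),
                          cell_ids = c("a", "b"), gene_ids = c("g1", "g2"))
  lt <- log_transform(em)
  expect_equal(unname(lt$values[1, 1]), 0)
  expect_equal(unname(lt$values[2, 1]), 1)
  x <- sort(runif(50, 0, 100))
  lx <- log_transform(expression_matrix(matrix(x, 1)))$values[1, ]
  expect_true(all(diff(lx) > 0))
})

test_that("marker PCA matches a brute-force eigendecomposition oracle", {
  set.seed(31)
  vals <- matrix(rexp(12, 0.1), 4, 3,
                 dimnames = list(sprintf("c%d", 1:4), c("Runx1", "Myb", "Cdh5")))
  em <- expression_matrix(vals)
  panel <- marker_panel(c("Runx1", "Myb", "Cdh5"))
  res <- marker_pca(em, panel)

  # oracle: eigen-decomposition of the sample covariance of centred data
  xc <- scale(vals, center = TRUE, scale = FALSE)
  eg <- eigen(cov(xc), symmetric = TRUE)
  for (i in 1:2) {
    v <- eg$vectors[, i]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(res$component_loadings[i, ]), v, tolerance = 1e-8)
    expect_equal(unname(res$scores[, i]), unname(drop(xc %*% v)),
                 tolerance = 1e-8)
    expect_equal(res$explained_variance[i], eg$values[i], tolerance = 1e-8)
  }
  expect_gte(res$explained_variance[1], res$explained_variance[2])
  expect_lt(max(abs(colMeans(res$scores))), 1e-10)
})

test_that("PCA degenerate inputs and sign convention behave as documented", {
  # identical cells -> all scores exactly zero... but zero variance errors
  em <- expression_matrix(matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(marker_pca(em, marker_panel(c("a", "b", "c"))), "zero total variance")

  # missing panel genes dropped with a warning; < 2 usable is an error
  set.seed(1)
  em2 <- expression_matrix(matrix(runif(12), 4, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  expect_message(res <- marker_pca(em2, marker_panel(c("a", "b", "zzz"))),
                 "dropped")
  expect_equal(res$panel_genes_used, c("a", "b"))
  expect_error(suppressMessages(marker_pca(em2, marker_panel(c("a", "x", "y")))),
               "fewer than 2")

  # sign convention: largest-magnitude loading entry positive; distances
  # between cell scores are unaffected by any sign choice
  set.seed(2)
  em3 <- expression_matrix(matrix(rexp(40), 8, 5,
                                  dimnames = list(NULL, letters[1:5])))
  r3 <- marker_pca(em3, marker_panel(letters[1:5]))
  for (i in 1:2)
    expect_gt(r3$component_loadings[i, which.max(abs(r3$component_loadings[i, ]))], 0)
  d <- dist(r3$scores)
  d_flip <- dist(r3$scores %*% diag(c(-1, -1)))
  expect_equal(as.numeric(d), as.numeric(d_flip), tolerance = 1e-12)
})

test_that("GMM separates well-separated planted blobs essentially perfectly", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(80, 0, 0.5), ncol = 2),
                matrix(rnorm(40, 10, 0.5), ncol = 2))
  fit <- fit_gmm2(blob, seed = 3)
  truth <- rep(1:2, c(40, 20))
  hard <- max.col(fit$responsibilities)
  if (hard[1] != 1) hard <- 3 - hard
  expect_equal(hard, truth)
  expect_true(all(fit$responsibilities[cbind(seq_along(hard), hard)] >= 0.999))
  expect_false(fit$degenerate)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-12))
})

test_that("EM ascends and beats the planted parameters' likelihood", {
  set.seed(8)
  w <- c(0.6, 0.4)
  mu <- rbind(c(0, 0), c(4, 3))
  sg <- list(diag(c(1, 0.5)), diag(c(0.8, 1.2)))
  n <- 300
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  pts <- t(vapply(comp, function(k)
    mu[k, ] + sqrt(diag(sg[[k]])) * rnorm(2), numeric(2)))
  fit <- fit_gmm2(pts, seed = 17)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  ll_true <- gmm2_loglik(pts, w, mu, sg)
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("planted mixture means are recovered at n = 500", {
  set.seed(21)
  n <- 500
  comp <- rep(1:2, c(250, 250))
  mu <- rbind(c(-2, 0), c(2, 1))
  pts <- t(vapply(comp, function(k) mu[k, ] + rnorm(2, 0, 1), numeric(2)))
  fit <- fit_gmm2(pts, seed = 4)
  est <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(est - mu)), 0.5)  # within 0.5 within-component SD
})

test_that("GMM fitting is deterministic under its seed and flags degeneracy", {
  ds <- default_dataset()
  resc <- rescale_tpm_excluding_spikeins(
    filter_cells(ds$matrix, compute_qc(ds$matrix, ds$reads)))
  pca <- marker_pca(log_transform(resc), marker_panel())
  f1 <- fit_gmm2(pca$scores, seed = 99)
  f2 <- fit_gmm2(pca$scores, seed = 99)
  expect_identical(f1$responsibilities, f2$responsibilities)
  expect_identical(f1$loglik, f2$loglik)

  # an outlier-plus-tight-cluster degenerate case is flagged, not hidden
  pts <- rbind(matrix(rnorm(30, 0, 1e-4), ncol = 2), c(100, 100))
  expect_message(fd <- fit_gmm2(pts, seed = 1), "degenerate")
  expect_true(fd$degenerate)
})

test_that("component annotation follows the anchor gene and survives label switching", {
  ds <- default_dataset()
  resc <- rescale_tpm_excluding_spikeins(
    filter_cells(ds$matrix, compute_qc(ds$matrix, ds$reads)))
  lm <- log_transform(resc)
  pca <- marker_pca(lm, marker_panel())
  fit <- fit_gmm2(pca$scores, seed = 12)
  lab <- annotate_components(fit, lm, marker_panel())
  truth_h <- names(ds$truth$cell_label)[ds$truth$cell_label == "haematopoietic"]
  expect_setequal(lab$labels$cell_id[lab$labels$label == "haematopoietic"],
                  truth_h)
  # Runx1 weighted mean is strictly higher in the haematopoietic component
  hm <- lab$component_map[["haematopoietic"]]
  expect_gt(lab$annotation_statistic[hm], lab$annotation_statistic[3 - hm])

  # swapping component indices leaves the labels unchanged
  swapped <- fit
  swapped$responsibilities <- fit$responsibilities[, 2:1]
  swapped$means <- fit$means[2:1, ]
  swapped$covariances <- fit$covariances[2:1]
  swapped$weights <- fit$weights[2:1]
  lab2 <- annotate_components(swapped, lm, marker_panel())
  expect_equal(lab2$labels[order(lab2$labels$cell_id), c("cell_id", "label")],
               lab$labels[order(lab$labels$cell_id), c("cell_id", "label")])
})

test_that("an exactly tied annotation statistic raises", {
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2)
  fit <- fit_gmm2(pts, seed = 2)
  flat <- expression_matrix(matrix(1, 20, 1,
                                   dimnames = list(paste0("c", 1:20), "Runx1")))
  fit$responsibilities <- matrix(0.5, 20, 2,
                                 dimnames = list(paste0("c", 1:20), c("comp1", "comp2")))
  expect_error(annotate_components(fit, flat, marker_panel("Runx1")), "tied")
})

test_that("classification agrees with an independent mixture implementation", {
  # mclust as cross-check on clearly bimodal scores (never the implementation)
  library(mclust)
  ds <- default_dataset()
  resc <- rescale_tpm_excluding_spikeins(
    filter_cells(ds$matrix, compute_qc(ds$matrix, ds$reads)))
  pca <- marker_pca(log_transform(resc), marker_panel())
  ours <- max.col(fit_gmm2(pca$scores, seed = 5)$responsibilities)
  mc <- Mclust(pca$scores, G = 2, modelNames = "VVV", verbose = FALSE)
  agree <- max(mean(ours == mc$classification),
               mean(ours == 3 - mc$classification))
  expect_equal(agree, 1)
})
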