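test_that("RBF kernel matches its closed form", {
  a <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(rbf_kernel(a, a, gamma = 0.7)[1, 1], 1)
  # 1-D points 0 and 1 at gamma 1
  expect_equal(rbf_kernel(matrix(0), matrix(1), gamma = 1)[1, 1], exp(-1))
  # elementwise loop oracle on random input
  withr::with_seed(11, {
    A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(12), 4, 3)
  })
  K <- rbf_kernel(A, B, gamma = 0.3)
  K_loop <- matrix(0, 5, 4)
  for (i in 1:5) for (j in 1:4) {
    K_loop[i, j] <- exp(-0.3 * sum((A[i, ] - B[j, ])^2))
  }
  expect_lt(max(abs(K - K_loop)), 1e-12)
  expect_error(rbf_kernel(matrix(NA_real_, 1, 1), matrix(1), 1), "finite")
})

test_that("self-kernel is symmetric PSD with unit diagonal", {
  withr::with_seed(3, X <- matrix(rnorm(60), 12, 5))
  K <- rbf_kernel(X, X, gamma = 1 / 5)
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 12))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("linear-kernel KPCA reproduces classical PCA scores up to sign", {
  withr::with_seed(5, X <- matrix(rnorm(200), 20, 10))
  Xc <- scale(X, scale = FALSE)
  fit <- fit_kernel_pca(Xc, n_components = 5, kernel = "linear")
  pc <- prcomp(Xc, center = FALSE)
  expect_equal(abs(fit$scores), abs(unname(pc$x[, 1:5])), tolerance = 1e-8)
  expect_equal(abs(fit$pseudo_loadings), abs(unname(pc$rotation[, 1:5])),
               tolerance = 1e-8)
})

test_that("degenerate and truncated KPCA inputs are handled", {
  X <- matrix(1, 6, 4)  # identical rows: no variance after centering
  expect_error(fit_kernel_pca(X, 2), "no variance")
  withr::with_seed(6, {
    low <- matrix(rnorm(8), 8, 1) %*% matrix(rnorm(5), 1, 5)  # rank 1
  })
  expect_warning(fit <- fit_kernel_pca(low, 4, kernel = "linear"), "truncated")
  expect_equal(ncol(fit$scores), 1L)
})

test_that("first kernel component separates two clusters", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(40, mean = 0), 10, 4),
               matrix(rnorm(40, mean = 6), 10, 4))
  })
  fit <- fit_kernel_pca(X, 2)
  side <- sign(fit$scores[, 1])
  expect_true(all(side[1:10] == side[1]) && all(side[11:20] == -side[1]))
})

test_that("alignment similarities equal the SVD of the loading cross-product", {
  fake_model <- function(P) {
    structure(list(pseudo_loadings = P,
                   training_matrix = matrix(0, 3, nrow(P)),
                   center = rep(0, nrow(P))),
              class = "kernel_pca")
  }
  # identical orthonormal loadings -> all similarities 1
  P <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  emb <- align_components(fake_model(P), fake_model(P), threshold = 0.3)
  expect_equal(emb$component_similarities, rep(1, 4), tolerance = 1e-10)
  expect_true(all(emb$retained))
  # mutually orthogonal loadings -> nothing passes 0.3
  Q8 <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  expect_error(
    align_components(fake_model(Q8[, 1:3]), fake_model(Q8[, 4:6]), 0.3),
    "threshold")
  # dense-SVD oracle on random (non-orthonormal) loadings
  for (trial in 1:5) {
    withr::with_seed(100 + trial, {
      P <- matrix(rnorm(100), 20, 5); Q <- matrix(rnorm(100), 20, 5)
    })
    P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
    Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
    emb <- align_components(fake_model(P), fake_model(Q), threshold = 0)
    expect_equal(emb$component_similarities, svd(crossprod(P, Q))$d,
                 tolerance = 1e-10)
  }
})

test_that("alignment similarities ignore component order and sign", {
  withr::with_seed(21, {
    P <- matrix(rnorm(60), 15, 4); Q <- matrix(rnorm(60), 15, 4)
  })
  P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
  fake <- function(P) structure(list(pseudo_loadings = P,
                                     training_matrix = matrix(0, 3, nrow(P)),
                                     center = rep(0, nrow(P))),
                                class = "kernel_pca")
  base <- align_components(fake(P), fake(Q), 0)$component_similarities
  perm <- align_components(fake(P[, c(3, 1, 4, 2)]), fake(Q), 0)$component_similarities
  flip <- align_components(fake(P %*% diag(c(1, -1, 1, -1))), fake(Q),
                           0)$component_similarities
  expect_equal(perm, base, tolerance = 1e-10)
  expect_equal(flip, base, tolerance = 1e-10)
})

test_that("integrating a dataset with its own copy aligns it onto itself", {
  ds <- toy_dataset(n = 12, g = 8, seed = 31)
  emb <- integrate(ds, ds, n_components = 5, threshold = 0.3)
  expect_equal(emb$spatial_scores, emb$ref_scores, tolerance = 1e-8)
})

test_that("linear-kernel integration equals the classical PCA + SVD oracle", {
  sim <- simulate_paired(simulation_config(
    n_ref_cells = 60, n_spots = 40, n_genes = 30, n_shared_genes = 30,
    seed = 14))
  emb <- integrate(sim$ref, sim$spatial, n_components = 5, threshold = 0.3,
                   kernel = "linear")
  # independent oracle: classical PCA loadings per dataset, SVD alignment,
  # projection of both centered matrices onto the reference-side basis
  norm_mat <- function(ds) {
    X <- as.matrix(ds$matrix)
    f <- median(rowSums(X)) / rowSums(X)
    log1p(X * f)
  }
  gi <- intersect_genes(sim$ref, sim$spatial)
  Xr <- norm_mat(subset_dataset(sim$ref, genes = gi$ref_index))
  Xs <- norm_mat(subset_dataset(sim$spatial, genes = gi$spatial_index))
  P <- prcomp(Xr)$rotation[, 1:5]
  Q <- prcomp(Xs)$rotation[, 1:5]
  sv <- svd(crossprod(P, Q))
  keep <- sv$d > 0.3
  basis <- P %*% sv$u[, keep, drop = FALSE]
  ref_scores <- scale(Xr, scale = FALSE) %*% basis
  sp_scores <- scale(Xs, scale = FALSE) %*% basis
  expect_equal(sv$d, emb$component_similarities, tolerance = 1e-8)
  expect_equal(abs(unname(ref_scores)), abs(emb$ref_scores), tolerance = 1e-8)
  expect_equal(abs(unname(sp_scores)), abs(emb$spatial_scores), tolerance = 1e-8)
})

test_that("raising the threshold never increases retained components", {
  sim <- simulate_paired(simulation_config(
    n_ref_cells = 40, n_spots = 30, n_genes = 25, n_shared_genes = 20,
    seed = 9))
  lo <- integrate(sim$ref, sim$spatial, n_components = 8, threshold = 0.3)
  n_hi <- tryCatch(
    sum(integrate(sim$ref, sim$spatial, n_components = 8,
                  threshold = 0.99)$retained),
    error = function(e) 0L)  # nothing passes: retained count is zero
  expect_lte(n_hi, sum(lo$retained))
})

test_that("stage failures are reported with the failing stage name", {
  a <- omics_dataset(matrix(1:12, 3, 4), gene_ids = paste0("a", 1:4))
  b <- omics_dataset(matrix(1:12, 3, 4), gene_ids = paste0("b", 1:4))
  expect_error(integrate(a, b), "intersect_genes")
})
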