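#' Radial basis function kernel
#'
#' `K[i, j] = exp(-gamma * ||A_i - B_j||^2)`. Values lie in (0, 1];
#' `rbf_kernel(A, A, gamma)` is symmetric with unit diagonal.
#'
#' @param A,B numeric matrices with the same number of columns (features)
#' @param gamma positive kernel width; the conventional default elsewhere in
#'   the package is 1 / n_features
#' @return an `nrow(A)` x `nrow(B)` kernel matrix
#' @export
rbf_kernel <- function(A, B, gamma) {
  A <- as_dense(A); B <- as_dense(B)
  sv_assert(ncol(A) == ncol(B), "A and B must share feature count")
  sv_assert(is.numeric(gamma) && length(gamma) == 1 && gamma > 0,
            "`gamma` must be a positive scalar")
  sv_assert(all(is.finite(A)) && all(is.finite(B)),
            "kernel inputs must be finite")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical negatives from cancellation
  exp(-gamma * d2)
}

#' Fit kernel PCA to an expression matrix
#'
#' The kernel matrix (RBF by default; a linear kernel reduces the whole
#' procedure to classical PCA) is double-centered before symmetric
#' eigendecomposition. Scores are eigenvectors scaled by `sqrt(eigenvalue)`.
#' Because kernel components live in sample space and two datasets share
#' only gene space, each component also carries a gene-space surrogate
#' direction — the *pseudo-loading* — computed as the column-normalized
#' `t(X_centered) %*% v`. With a linear kernel the pseudo-loadings are
#' exactly the classical PCA loadings, which makes that mode the analytic
#' oracle for the downstream alignment.
#'
#' Eigenvalues below `max(eigenvalue) * 1e-9` are treated as numerically
#' zero and dropped; tiny negative eigenvalues (>= -1e-10) are clipped to 0.
#' For determinism across linear-algebra backends each pseudo-loading
#' column is flipped so its largest-magnitude entry is positive.
#'
#' @param X obs x genes numeric matrix (already normalized)
#' @param n_components number of components requested (at most n_obs - 1;
#'   truncated with a warning if the kernel rank is lower)
#' @param gamma RBF width; default `1 / ncol(X)`
#' @param kernel `"rbf"` or `"linear"`
#' @return object of class `kernel_pca` with fields `scores`, `eigenvalues`,
#'   `dual_coefficients`, `pseudo_loadings`, `center` (gene means),
#'   `training_matrix`, `gamma`, `kernel`
#' @export
fit_kernel_pca <- function(X, n_components, gamma = NULL,
                           kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  X <- as_dense(X)
  n <- nrow(X)
  sv_assert(n_components >= 1 && n_components <= n - 1,
            "`n_components` must be in [1, n_obs - 1]")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- if (kernel == "rbf") rbf_kernel(X, X, gamma) else tcrossprod(X)
  # double centering: remove row, column and grand means
  rm_ <- rowMeans(K); gm <- mean(K)
  Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  eg <- eigen(Kc, symmetric = TRUE)
  ev <- eg$values
  sv_assert(all(ev >= -1e-10 * max(abs(ev), 1)),
            "kernel matrix is not PSD within tolerance")
  ev[ev < 0] <- 0
  keep <- which(ev > max(ev) * 1e-9)
  if (!length(keep) || max(ev) == 0) {
    sv_stop("input has no variance (all observations identical after centering)")
  }
  if (length(keep) < n_components) {
    warning(sprintf("requested %d components but kernel rank is %d; truncated",
                    n_components, length(keep)))
  }
  keep <- keep[seq_len(min(n_components, length(keep)))]
  ev <- ev[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  scores <- sweep(V, 2, sqrt(ev), "*")
  alpha <- sweep(V, 2, sqrt(ev), "/")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  P <- crossprod(Xc, V)                       # genes x c
  nrm <- sqrt(colSums(P^2))
  nrm[nrm == 0] <- 1
  P <- sweep(P, 2, nrm, "/")
  # deterministic sign: largest-|entry| positive per column
  flip <- vapply(seq_len(ncol(P)), function(j) {
    i <- which.max(abs(P[, j])); sign(P[i, j]) < 0
  }, logical(1))
  P[, flip] <- -P[, flip]
  scores[, flip] <- -scores[, flip]
  alpha[, flip] <- -alpha[, flip]
  structure(
    list(scores = scores, eigenvalues = ev, dual_coefficients = alpha,
         pseudo_loadings = P, center = center, training_matrix = X,
         gamma = gamma, kernel = kernel),
    class = "kernel_pca"
  )
}

#' @export
print.kernel_pca <- function(x, ...) {
  cat(sprintf("kernel_pca (%s): %d obs, %d components\n",
              x$kernel, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Align two kernel PCA models by SVD of their loading cross-product
#'
#' Given reference pseudo-loadings `P` (genes x p) and spatial
#' pseudo-loadings `Q` (genes x q), computes `svd(t(P) %*% Q) = U S V'`.
#' The singular values are the component similarities (for orthonormal
#' loadings, cosines of the principal angles between the two subspaces);
#' aligned directions are `basis_ref = P %*% U` and
#' `basis_spatial = Q %*% V`. Components with similarity strictly above
#' `threshold` are retained, and both expression matrices are projected
#' (after their own gene-centering) onto `basis_ref`, the reference-side
#' aligned basis, which serves as the common latent space.
#'
#' @param ref_model,spatial_model `kernel_pca` models fitted on the same
#'   gene set in the same order
#' @param threshold cosine-similarity retention cutoff (default 0.3)
#' @return object of class `aligned_embedding` with `ref_scores`,
#'   `spatial_scores`, `component_similarities` (all, non-increasing),
#'   `retained` (logical), `threshold`, `basis_ref`, `basis_spatial`
#' @export
align_components <- function(ref_model, spatial_model, threshold = 0.3) {
  P <- ref_model$pseudo_loadings
  Q <- spatial_model$pseudo_loadings
  sv_assert(nrow(P) == nrow(Q),
            "models must be fitted on the same gene set and order")
  sv <- svd(crossprod(P, Q))
  sims <- sv$d
  retained <- sims > threshold
  if (!any(retained)) {
    sv_stop(sprintf(
      "no aligned component exceeds similarity threshold %.3g (best: %.4g); the datasets may share too little structure",
      threshold, max(sims)))
  }
  keep <- which(retained)
  basis_ref <- P %*% sv$u[, keep, drop = FALSE]
  basis_spatial <- Q %*% sv$v[, keep, drop = FALSE]
  # deterministic sign, applied to both sides to preserve pairing
  for (j in seq_along(keep)) {
    i <- which.max(abs(basis_ref[, j]))
    if (basis_ref[i, j] < 0) {
      basis_ref[, j] <- -basis_ref[, j]
      basis_spatial[, j] <- -basis_spatial[, j]
    }
  }
  ref_scores <- sweep(ref_model$training_matrix, 2, ref_model$center) %*% basis_ref
  spatial_scores <- sweep(spatial_model$training_matrix, 2,
                          spatial_model$center) %*% basis_ref
  structure(
    list(ref_scores = ref_scores, spatial_scores = spatial_scores,
         component_similarities = sims, retained = retained,
         threshold = threshold, basis_ref = basis_ref,
         basis_spatial = basis_spatial),
    class = "aligned_embedding"
  )
}

#' @export
print.aligned_embedding <- function(x, ...) {
  cat(sprintf(
    "aligned_embedding: %d retained components (threshold %.2f)\n  similarities: %s\n",
    sum(x$retained), x$threshold,
    paste(sprintf("%.3f", head(x$component_similarities, 8)), collapse = ", ")))
  invisible(x)
}

#' Integrate reference and spatial datasets into a shared latent space
#'
#' Composes the integration stage: shared-gene intersection, per-dataset
#' library-size normalization (median target, log1p), per-dataset kernel
#' PCA, and SVD alignment of the gene-space component loadings with a
#' cosine-similarity retention threshold. Failures are re-raised with the
#' failing stage named.
#'
#' @param ref reference [omics_dataset()] (scRNA-seq)
#' @param spatial spatial [omics_dataset()]
#' @param n_components per-dataset components before alignment; default
#'   `min(50, n_obs - 1)`
#' @param threshold cosine-similarity retention cutoff (default 0.3)
#' @param gamma RBF width; default 1 / n_shared_genes
#' @param kernel `"rbf"` (default) or `"linear"` (classical-PCA mode)
#' @param normalize apply [normalize_expression()] to each dataset first
#' @param verbose log the retained-component count and similarity spectrum
#' @return an `aligned_embedding`; the `gene_intersection` used is attached
#'   as attribute `"genes"`
#' @export
integrate <- function(ref, spatial, n_components = 50, threshold = 0.3,
                      gamma = NULL, kernel = c("rbf", "linear"),
                      normalize = TRUE, verbose = FALSE) {
  kernel <- match.arg(kernel)
  sv_assert(n_obs(ref) >= 3 && n_obs(spatial) >= 3,
            "each dataset needs at least 3 observations")
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) sv_stop(
      paste0("[", stage, "] ", conditionMessage(e))))
  }
  gi <- with_stage("intersect_genes", intersect_genes(ref, spatial))
  sv_assert(length(gi$genes) >= 2, "need at least 2 shared genes")
  r <- subset_dataset(ref, genes = gi$ref_index)
  s <- subset_dataset(spatial, genes = gi$spatial_index)
  if (normalize) {
    r <- with_stage("normalize", normalize_expression(r))
    s <- with_stage("normalize", normalize_expression(s))
  }
  nc_r <- min(n_components, n_obs(r) - 1)
  nc_s <- min(n_components, n_obs(s) - 1)
  rm_model <- with_stage("fit_kernel_pca(ref)",
                         fit_kernel_pca(as_dense(r$matrix), nc_r, gamma, kernel))
  sm_model <- with_stage("fit_kernel_pca(spatial)",
                         fit_kernel_pca(as_dense(s$matrix), nc_s, gamma, kernel))
  emb <- with_stage("align_components",
                    align_components(rm_model, sm_model, threshold))
  if (verbose) {
    message(sprintf("integrate: retained %d/%d components; similarities %s",
                    sum(emb$retained), length(emb$component_similarities),
                    paste(sprintf("%.3f", emb$component_similarities),
                          collapse = ", ")))
  }
  attr(emb, "genes") <- gi
  emb
}
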