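# small programmatic fixtures shared across test files

toy_dataset <- function(n = 3, g = 4, seed = 42, layers = FALSE,
                        coords = FALSE, labels = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * g, lambda = 5), n, g)
    omics_dataset(
      m, gene_ids = paste0("g", seq_len(g)),
      obs_ids = paste0("c", seq_len(n)),
      spliced = if (layers) matrix(rpois(n * g, 3), n, g) else NULL,
      unspliced = if (layers) matrix(rpois(n * g, 2), n, g) else NULL,
      coords = if (coords) cbind(runif(n), runif(n)) else NULL,
      labels = labels
    )
  })
}

as_mat <- function(m) if (is.null(m)) NULL else unname(as.matrix(m))

# weighted assignment built directly from a distance matrix
assignment_from_distances <- function(D) {
  a <- structure(
    list(neighbor_indices = matrix(rep(seq_len(ncol(D)), each = nrow(D)),
                                   nrow(D), ncol(D)),
         cosine_distances = D, weights = NULL, k = ncol(D)),
    class = "neighbor_assignment")
  a
}

expect_rows_sum_to <- function(m, value, tol = 1e-12) {
  expect_true(all(abs(rowSums(m) - value) < tol))
}

# columnwise sign-alignment of two matrices (components defined up to sign)
align_signs <- function(A, B) {
  for (j in seq_len(ncol(A))) {
    if (sum(A[, j] * B[, j]) < 0) B[, j] <- -B[, j]
  }
  B
}
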