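#' Find nearest reference cells for each spatial spot
#'
#' Neighbors are ranked by cosine distance `d = 1 - cos(angle)` between
#' latent-score vectors in the aligned space. Ties are broken by reference
#' index ascending. A zero-norm score vector has no direction; its distance
#' to anything is defined as 1 (orthogonal convention) with a warning.
#'
#' @param spatial_scores spots x c latent scores (or an `aligned_embedding`,
#'   from which both score matrices are taken)
#' @param ref_scores refs x c latent scores
#' @param k number of neighbors; clamped to the number of reference cells
#'   with a warning
#' @return object of class `neighbor_assignment`: `neighbor_indices`
#'   (spots x k), `cosine_distances` (spots x k), `weights` (NULL until
#'   [compute_weights()] is applied), `k`
#' @export
find_neighbors <- function(spatial_scores, ref_scores = NULL, k = 50) {
  if (inherits(spatial_scores, "aligned_embedding")) {
    ref_scores <- spatial_scores$ref_scores
    spatial_scores <- spatial_scores$spatial_scores
  }
  S <- as_dense(spatial_scores); R <- as_dense(ref_scores)
  sv_assert(ncol(S) == ncol(R) && ncol(S) >= 1,
            "score matrices must share at least one latent dimension")
  if (k > nrow(R)) {
    warning(sprintf("k = %d exceeds %d reference cells; clamped", k, nrow(R)))
    k <- nrow(R)
  }
  sv_assert(k >= 1, "`k` must be positive")
  ns <- sqrt(rowSums(S^2)); nr <- sqrt(rowSums(R^2))
  if (any(ns == 0) || any(nr == 0)) {
    warning("zero-norm score vector(s): cosine distance defined as 1")
  }
  ns[ns == 0] <- Inf; nr[nr == 0] <- Inf  # => similarity 0, distance 1
  D <- 1 - tcrossprod(S / ns, R / nr)
  D[D < 0] <- 0  # guard rounding below 0
  idx <- matrix(0L, nrow(S), k)
  dst <- matrix(0, nrow(S), k)
  for (i in seq_len(nrow(S))) {
    o <- order(D[i, ], seq_len(nrow(R)))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- D[i, o]
  }
  structure(list(neighbor_indices = idx, cosine_distances = dst,
                 weights = NULL, k = k),
            class = "neighbor_assignment")
}

#' Compute normalized kNN regression weights
#'
#' Implements the inverse-cosine-distance weighting
#' `a_ij = 1 - d_ij / sum_j d_ij` followed by `a*_ij = a_ij / (k - 1)`,
#' which makes each spot's weights sum to 1 exactly (each `a_ij` lies in
#' \[0, 1\] because no single non-negative distance can exceed the row sum).
#' Spots whose k distances are all zero take uniform weights `1/k` (the
#' continuity limit); with `k = 1` the single weight is 1.
#'
#' @param assignment a `neighbor_assignment` from [find_neighbors()]
#' @return the assignment with `weights` filled (rows sum to 1 within 1e-12)
#' @export
compute_weights <- function(assignment) {
  sv_assert(inherits(assignment, "neighbor_assignment"),
            "`assignment` must come from find_neighbors()")
  D <- assignment$cosine_distances
  sv_assert(all(D >= 0), "distances must be non-negative")
  k <- assignment$k
  if (k == 1) {
    assignment$weights <- matrix(1, nrow(D), 1)
    return(assignment)
  }
  rs <- rowSums(D)
  W <- matrix(1 / k, nrow(D), ncol(D))
  pos <- rs > 0
  if (any(!pos)) {
    message(sprintf("%d spot(s) with all-zero neighbor distances: uniform weights",
                    sum(!pos)))
  }
  if (any(pos)) {
    A <- 1 - D[pos, , drop = FALSE] / rs[pos]
    W[pos, ] <- A / (k - 1)
  }
  assignment$weights <- W
  assignment
}

#' @export
print.neighbor_assignment <- function(x, ...) {
  cat(sprintf("neighbor_assignment: %d spots, k = %d%s\n",
              nrow(x$neighbor_indices), x$k,
              if (is.null(x$weights)) " (weights not yet computed)" else ""))
  invisible(x)
}

# sparse spots x refs weight matrix for fast weighted averages
weight_matrix <- function(assignment, n_ref) {
  sv_assert(!is.null(assignment$weights),
            "weights missing: run compute_weights() first")
  n <- nrow(assignment$neighbor_indices)
  sparseMatrix(
    i = rep(seq_len(n), assignment$k),
    j = as.vector(assignment$neighbor_indices),
    x = as.vector(assignment$weights),
    dims = c(n, n_ref)
  )
}

#' Transfer spliced and unspliced layers to spatial spots
#'
#' Each spot's spliced/unspliced expression is the weighted average of its
#' reference neighbors' layers, `S'_ig = sum_j a*_ij S_R[j, g]` (and the
#' same for U). All reference genes are imputed by default — the shared
#' panel is only used to build the latent space — which is what enables
#' predicting genes the spatial platform never measured.
#'
#' @param assignment weighted `neighbor_assignment` (see [compute_weights()])
#' @param ref reference [omics_dataset()] carrying `spliced` and `unspliced`
#' @param genes optional gene subset (indices or names) to impute
#' @return list with matrices `spliced` and `unspliced` (spots x genes) and
#'   `gene_ids`
#' @export
impute_layers <- function(assignment, ref, genes = NULL) {
  for (nm in c("spliced", "unspliced")) {
    if (is.null(ref[[nm]])) {
      sv_stop(paste0("reference dataset has no '", nm, "' layer"))
    }
  }
  if (!is.null(genes)) ref <- subset_dataset(ref, genes = genes)
  W <- weight_matrix(assignment, n_obs(ref))
  list(
    spliced = as.matrix(W %*% ref$spliced),
    unspliced = as.matrix(W %*% ref$unspliced),
    gene_ids = ref$gene_ids
  )
}

#' Transfer cell-type labels to spatial spots
#'
#' For each spot and each cell type C the score is the summed weight of its
#' neighbors labeled C; scores sum to 1 per spot, and the spot is assigned
#' the argmax type, ties broken by lexicographic type order.
#'
#' @param assignment weighted `neighbor_assignment`
#' @param ref_labels character/factor label per reference cell
#' @return object of class `label_transfer`: `scores` (spots x types
#'   matrix), `assigned` (character), `types` (sorted vocabulary)
#' @export
transfer_labels <- function(assignment, ref_labels) {
  sv_assert(!is.null(assignment$weights),
            "weights missing: run compute_weights() first")
  ref_labels <- as.character(ref_labels)
  idx <- assignment$neighbor_indices
  sv_assert(!anyNA(ref_labels[unique(as.vector(idx))]),
            "every neighbor must carry a label")
  types <- sv_sort(unique(ref_labels[as.vector(idx)]))
  scores <- matrix(0, nrow(idx), length(types),
                   dimnames = list(NULL, types))
  lab_code <- match(ref_labels, types)
  for (j in seq_len(ncol(idx))) {
    code <- lab_code[idx[, j]]
    scores[cbind(seq_len(nrow(idx)), code)] <-
      scores[cbind(seq_len(nrow(idx)), code)] + assignment$weights[, j]
  }
  assigned <- types[max.col(scores, ties.method = "first")]
  structure(list(scores = scores, assigned = assigned, types = types),
            class = "label_transfer")
}

#' @export
print.label_transfer <- function(x, ...) {
  cat(sprintf("label_transfer: %d spots, %d types\n",
              nrow(x$scores), length(x$types)))
  print(table(x$assigned))
  invisible(x)
}
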