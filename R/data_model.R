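#' Expression dataset container
#'
#' Holds an observations x genes total-expression matrix together with the
#' optional layers and per-observation annotations used throughout the
#' package: spliced/unspliced counts (reference scRNA-seq), 2-D spatial
#' coordinates (spatial data), cell-type labels and pseudotime.
#'
#' Matrices denser than 50% zeros are stored dense; sparser ones as
#' `dgCMatrix`. All operations accept both representations and never permute
#' observation order: integer indices are the join keys across results.
#'
#' @param matrix non-negative numeric matrix, observations in rows, genes in
#'   columns. Dimnames, when present, are overridden by `gene_ids`/`obs_ids`.
#' @param gene_ids character vector of unique gene identifiers (whitespace is
#'   stripped; case is preserved).
#' @param obs_ids character vector of unique observation (cell/spot)
#'   identifiers. Defaults to `obs_1 ... obs_n`.
#' @param spliced,unspliced optional matrices of spliced/unspliced counts,
#'   same shape as `matrix`.
#' @param coords optional numeric matrix or data frame with two columns
#'   (x, y) of spatial coordinates per observation.
#' @param labels optional character/factor vector of cell-type labels.
#' @param pseudotime optional numeric vector; values are min-max normalized
#'   to \[0, 1\].
#' @param counts optional matrix of raw counts retained alongside a
#'   normalized `matrix` (filled in by [normalize_expression()]).
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(matrix, gene_ids, obs_ids = NULL, spliced = NULL,
                          unspliced = NULL, coords = NULL, labels = NULL,
                          pseudotime = NULL, counts = NULL) {
  sv_assert(length(dim(matrix)) == 2L, "`matrix` must be two-dimensional")
  gene_ids <- trimws(as.character(gene_ids))
  sv_assert(length(gene_ids) == ncol(matrix),
            "length(gene_ids) must equal ncol(matrix)")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    sv_stop(paste0("duplicated gene IDs: ", paste(dup, collapse = ", ")))
  }
  if (is.null(obs_ids)) obs_ids <- paste0("obs_", seq_len(nrow(matrix)))
  obs_ids <- as.character(obs_ids)
  sv_assert(length(obs_ids) == nrow(matrix) && !anyDuplicated(obs_ids),
            "obs_ids must be unique and match nrow(matrix)")
  matrix <- store_matrix(matrix)
  sv_assert(min_val(matrix) >= 0, "`matrix` must be non-negative")
  chk_layer <- function(l, nm) {
    if (is.null(l)) return(NULL)
    sv_assert(all(dim(l) == dim(matrix)),
              paste0("layer '", nm, "' must match matrix shape"))
    store_matrix(l)
  }
  spliced <- chk_layer(spliced, "spliced")
  unspliced <- chk_layer(unspliced, "unspliced")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    sv_assert(nrow(coords) == nrow(matrix) && ncol(coords) == 2L,
              "`coords` must be an n_obs x 2 matrix")
    sv_assert(all(is.finite(coords)), "`coords` must be finite")
    colnames(coords) <- c("x", "y")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    sv_assert(length(labels) == nrow(matrix),
              "`labels` must have one entry per observation")
  }
  if (!is.null(pseudotime)) {
    pseudotime <- as.numeric(pseudotime)
    sv_assert(length(pseudotime) == nrow(matrix) && all(is.finite(pseudotime)),
              "`pseudotime` must be finite, one value per observation")
    rng <- range(pseudotime)
    if (rng[1] < 0 || rng[2] > 1) {
      pseudotime <- if (rng[2] > rng[1]) {
        (pseudotime - rng[1]) / (rng[2] - rng[1])
      } else {
        rep(0, length(pseudotime))
      }
    }
  }
  structure(
    list(matrix = matrix, gene_ids = gene_ids, obs_ids = obs_ids,
         spliced = spliced, unspliced = unspliced, coords = coords,
         labels = labels, pseudotime = pseudotime, counts = counts),
    class = "omics_dataset"
  )
}

# sparse when more than half the entries are zero
store_matrix <- function(m) {
  if (is(m, "Matrix")) {
    dens <- Matrix::nnzero(m) / prod(dim(m))
    if (dens > 0.5) as.matrix(m) else as(as(m, "CsparseMatrix"), "generalMatrix")
  } else {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (mean(m == 0) > 0.5) as(as(Matrix(m, sparse = TRUE), "CsparseMatrix"),
                               "generalMatrix") else m
  }
}

min_val <- function(m) if (is(m, "sparseMatrix")) min(0, min(m@x, 0)) else min(m)

#' @export
dim.omics_dataset <- function(x) dim(x$matrix)

#' Number of observations / genes in a dataset
#' @param ds an [omics_dataset()]
#' @return integer scalar
#' @export
n_obs <- function(ds) nrow(ds$matrix)

#' @rdname n_obs
#' @export
n_genes <- function(ds) ncol(ds$matrix)

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d obs x %d genes\n", n_obs(x), n_genes(x)))
  extras <- c(
    if (!is.null(x$spliced)) "spliced", if (!is.null(x$unspliced)) "unspliced",
    if (!is.null(x$coords)) "coords", if (!is.null(x$labels)) "labels",
    if (!is.null(x$pseudotime)) "pseudotime", if (!is.null(x$counts)) "counts"
  )
  if (length(extras)) cat("  with:", paste(extras, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset by genes and/or observations
#'
#' Preserves all layers and annotations; never reorders observations unless
#' an explicit index vector does.
#'
#' @param ds an [omics_dataset()]
#' @param genes integer or character vector of genes to keep (default all)
#' @param obs integer vector of observations to keep (default all)
#' @return an [omics_dataset()]
#' @export
subset_dataset <- function(ds, genes = NULL, obs = NULL) {
  gi <- if (is.null(genes)) seq_len(n_genes(ds)) else {
    if (is.character(genes)) match(trimws(genes), ds$gene_ids) else genes
  }
  sv_assert(!anyNA(gi) && all(gi >= 1 & gi <= n_genes(ds)), "invalid gene subset")
  oi <- if (is.null(obs)) seq_len(n_obs(ds)) else obs
  sub <- function(m) if (is.null(m)) NULL else m[oi, gi, drop = FALSE]
  omics_dataset(
    matrix = sub(ds$matrix), gene_ids = ds$gene_ids[gi],
    obs_ids = ds$obs_ids[oi],
    spliced = sub(ds$spliced), unspliced = sub(ds$unspliced),
    coords = if (is.null(ds$coords)) NULL else ds$coords[oi, , drop = FALSE],
    labels = if (is.null(ds$labels)) NULL else ds$labels[oi],
    pseudotime = if (is.null(ds$pseudotime)) NULL else ds$pseudotime[oi],
    counts = sub(ds$counts)
  )
}

#' Common genes of two datasets
#'
#' The shared gene panel drives latent-space construction: both modalities
#' are compared only on genes measured in each. Matching is exact string
#' equality after whitespace stripping (no alias resolution); the result is
#' ordered lexicographically (C collation) for determinism.
#'
#' @param ref reference [omics_dataset()]
#' @param spatial spatial [omics_dataset()]
#' @return object of class `gene_intersection`: `genes` (sorted), and
#'   `ref_index` / `spatial_index` integer positions into each dataset's
#'   `gene_ids`.
#' @export
intersect_genes <- function(ref, spatial) {
  sv_assert(n_genes(ref) > 0 && n_genes(spatial) > 0,
            "both datasets must be non-empty")
  genes <- sv_sort(intersect(ref$gene_ids, spatial$gene_ids))
  if (!length(genes)) {
    sv_stop(paste0(
      "no shared genes between the two datasets; harmonize gene identifiers ",
      "(e.g. map both to the same symbol or accession namespace)"))
  }
  structure(
    list(genes = genes,
         ref_index = match(genes, ref$gene_ids),
         spatial_index = match(genes, spatial$gene_ids)),
    class = "gene_intersection"
  )
}

#' @export
print.gene_intersection <- function(x, ...) {
  cat(sprintf("gene_intersection: %d shared genes\n", length(x$genes)))
  invisible(x)
}

#' Library-size normalization
#'
#' Scales each observation's total expression to `target_sum` (default:
#' median total count over non-empty observations), then optionally applies
#' `log(1+x)`. Spliced and unspliced layers are scaled with the same
#' per-observation factor as the total matrix — never log-transformed — so
#' per-observation spliced:unspliced ratios are preserved exactly. The
#' original matrix is retained in `$counts` for kinetics fitting.
#'
#' All-zero observations are left unscaled with a warning.
#'
#' @param ds an [omics_dataset()]
#' @param target_sum positive scalar; default median library size
#' @param log1p apply log(1+x) to the total matrix after scaling
#' @return normalized [omics_dataset()]
#' @export
normalize_expression <- function(ds, target_sum = NULL, log1p = TRUE) {
  X <- ds$matrix
  totals <- as.numeric(Matrix::rowSums(X))
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero observation(s) left unscaled", sum(zero)))
  }
  if (is.null(target_sum)) {
    sv_assert(!all(zero), "cannot normalize: all observations are empty")
    target_sum <- median(totals[!zero])
  }
  sv_assert(is.numeric(target_sum) && target_sum > 0,
            "`target_sum` must be positive")
  fac <- ifelse(zero, 1, target_sum / totals)
  scale_rows <- function(m) {
    if (is.null(m)) return(NULL)
    if (is(m, "sparseMatrix")) Matrix::Diagonal(x = fac) %*% m else m * fac
  }
  Xn <- scale_rows(X)
  if (log1p) Xn <- if (is(Xn, "sparseMatrix")) {
    Xn@x <- log1p(Xn@x); Xn
  } else log1p(Xn)
  out <- ds
  out$counts <- X
  out$matrix <- store_matrix(Xn)
  out$spliced <- if (is.null(ds$spliced)) NULL else store_matrix(scale_rows(ds$spliced))
  out$unspliced <- if (is.null(ds$unspliced)) NULL else store_matrix(scale_rows(ds$unspliced))
  out
}
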