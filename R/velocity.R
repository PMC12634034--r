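#' Steady-state RNA velocity fit
#'
#' Under splicing kinetics with the splicing rate scaled to 1, cells at
#' extreme spliced abundance are assumed to sit on the steady-state line
#' `u = gamma * s`. Per gene, `gamma` is the slope of the zero-intercept
#' regression of U on S restricted to cells in the top and bottom
#' `quantile` of spliced abundance, and velocity is the residual
#' `v = U - gamma * S`: positive where unspliced transcript runs ahead of
#' equilibrium (induction), negative where it lags (repression).
#'
#' Genes with fewer than `min_cells` cells expressing them (S or U > 0),
#' zero spliced variance, or a non-positive fitted slope are masked
#' invalid: their velocity is 0 and `gamma`/`r2` are NA.
#'
#' @param S,U spots/cells x genes non-negative matrices of spliced and
#'   unspliced abundance (e.g. from [impute_layers()])
#' @param quantile extreme-quantile fraction in (0, 0.5]; default 0.05
#'   (top and bottom 5% of spliced abundance)
#' @param min_cells minimum expressing cells for a fit (default 10)
#' @param gene_ids optional gene names for reporting
#' @return object of class `velocity_model`: `gamma`, `r2`, `velocity`
#'   (obs x genes), `valid_genes` (logical), `gene_ids`
#' @export
fit_steady_state <- function(S, U, quantile = 0.05, min_cells = 10,
                             gene_ids = NULL) {
  S <- as_dense(S); U <- as_dense(U)
  sv_assert(all(dim(S) == dim(U)), "S and U must have identical shape")
  sv_assert(quantile > 0 && quantile <= 0.5, "`quantile` must be in (0, 0.5]")
  sv_assert(min(S) >= 0 && min(U) >= 0, "S and U must be non-negative")
  g <- ncol(S)
  gamma <- r2 <- rep(NA_real_, g)
  valid <- rep(FALSE, g)
  V <- matrix(0, nrow(S), g)
  for (j in seq_len(g)) {
    s <- S[, j]; u <- U[, j]
    if (sum(s > 0 | u > 0) < min_cells || var(s) == 0) next
    qs <- stats::quantile(s, c(quantile, 1 - quantile), names = FALSE)
    ext <- s <= qs[1] | s >= qs[2]
    ss <- s[ext]; uu <- u[ext]
    denom <- sum(ss^2)
    if (denom == 0) next
    gj <- sum(ss * uu) / denom
    if (!is.finite(gj) || gj <= 0) next
    gamma[j] <- gj
    res <- uu - gj * ss
    tot <- sum(uu^2)
    r2[j] <- if (tot > 0) 1 - sum(res^2) / tot else NA_real_
    V[, j] <- u - gj * s
    valid[j] <- TRUE
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  structure(list(gamma = gamma, r2 = r2, velocity = V, valid_genes = valid,
                 gene_ids = gene_ids),
            class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  cat(sprintf("velocity_model: %d obs x %d genes (%d valid fits)\n",
              nrow(x$velocity), length(x$gamma), sum(x$valid_genes)))
  invisible(x)
}

cos_rows <- function(a, b) {
  # cosine between corresponding rows; 0 where either row is zero
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  num <- rowSums(a * b)
  out <- rep(0, length(num))
  ok <- na > 0 & nb > 0
  out[ok] <- num[ok] / (na[ok] * nb[ok])
  out <- pmin(1, pmax(-1, out))
  # exactness guard: identical (or sign-flipped) rows get cosine +/-1 with
  # no floating-point residue
  same <- ok & rowSums(abs(a - b)) == 0
  opp <- ok & rowSums(abs(a + b)) == 0
  out[same] <- 1
  out[opp] <- -1
  out
}

#' Velocity transition graph
#'
#' For each observation a k-nearest-neighbor set is found in expression
#' space (Euclidean on the spliced layer, PCA-reduced to `pca_dims`
#' dimensions when more than 500 genes). The transition probability toward
#' neighbor j is `exp(cos(v_i, S_j - S_i) / sigma)`, restricted to
#' neighbors with positive cosine, and row-normalized: cells preferentially
#' transition toward neighbors whose displacement matches their velocity
#' direction. Observations with zero velocity, or no positively aligned
#' neighbor, take a uniform outgoing row over their neighbors and are
#' flagged.
#'
#' @param velocity obs x genes velocity matrix (or a `velocity_model`)
#' @param S obs x genes spliced matrix used for the kNN and displacements
#' @param neighbors k for the expression-space kNN (default 30)
#' @param sigma softmax scale in cosine units (default 0.05)
#' @param pca_dims PCA dimensionality for the kNN when genes > 500
#' @return object of class `velocity_graph`: `transition` (sparse
#'   row-stochastic dgCMatrix), `neighbors` (obs x k indices), `uniform`
#'   (logical flag per obs)
#' @export
velocity_graph <- function(velocity, S, neighbors = 30, sigma = 0.05,
                           pca_dims = 30) {
  if (inherits(velocity, "velocity_model")) velocity <- velocity$velocity
  velocity <- as_dense(velocity); S <- as_dense(S)
  sv_assert(all(dim(velocity) == dim(S)), "velocity and S must match in shape")
  sv_assert(neighbors >= 2, "`neighbors` must be >= 2")
  n <- nrow(S)
  neighbors <- min(neighbors, n - 1)
  knn_space <- if (ncol(S) > 500) {
    pr <- prcomp(S, rank. = min(pca_dims, ncol(S), n - 1))
    pr$x
  } else S
  D2 <- outer(rowSums(knn_space^2), rowSums(knn_space^2), "+") -
    2 * tcrossprod(knn_space)
  diag(D2) <- Inf
  nb <- t(apply(D2, 1, function(d) order(d, seq_len(n))[seq_len(neighbors)]))
  ii <- jj <- xx <- vector("list", n)
  uniform <- logical(n)
  for (i in seq_len(n)) {
    js <- nb[i, ]
    disp <- S[js, , drop = FALSE] - matrix(S[i, ], length(js), ncol(S), byrow = TRUE)
    cs <- cos_rows(matrix(velocity[i, ], length(js), ncol(S), byrow = TRUE), disp)
    pos <- cs > 0
    if (all(velocity[i, ] == 0) || !any(pos)) {
      uniform[i] <- TRUE
      p <- rep(1 / length(js), length(js))
      keep <- js
    } else {
      w <- exp(cs[pos] / sigma)
      p <- w / sum(w)
      keep <- js[pos]
    }
    ii[[i]] <- rep(i, length(keep)); jj[[i]] <- keep; xx[[i]] <- p
  }
  transition <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n, n))
  if (any(uniform)) {
    message(sprintf("%d observation(s) with zero/unaligned velocity: uniform transition rows",
                    sum(uniform)))
  }
  structure(list(transition = transition, neighbors = nb, uniform = uniform,
                 sigma = sigma),
            class = "velocity_graph")
}

#' @export
print.velocity_graph <- function(x, ...) {
  cat(sprintf("velocity_graph: %d obs, k = %d, %d uniform rows\n",
              nrow(x$transition), ncol(x$neighbors), sum(x$uniform)))
  invisible(x)
}

#' Project velocity onto a 2-D embedding
#'
#' The arrow of observation i is the transition-expected displacement minus
#' the uniform expectation over its neighbor set,
#' `arrow_i = sum_j pi_ij h(e_j - e_i) - (1/k) sum_j h(e_j - e_i)`,
#' where `h` unit-normalizes each displacement by default. Subtracting the
#' uniform expectation removes the density gradient of the embedding, so a
#' cell with an uninformative (uniform) transition row gets a zero arrow.
#' Tissue coordinates are the embedding of interest here — this is what
#' anchors velocity to physical space — but any 2-D embedding works.
#'
#' @param graph a `velocity_graph`
#' @param embedding obs x 2 coordinate matrix
#' @param normalize_displacement unit-normalize displacement vectors before
#'   averaging (default TRUE)
#' @return object of class `velocity_field`: `arrows` (obs x 2), the
#'   `embedding` and the `transition` used
#' @export
project_velocity <- function(graph, embedding, normalize_displacement = TRUE) {
  sv_assert(inherits(graph, "velocity_graph"), "`graph` must be a velocity_graph")
  E <- as.matrix(embedding)
  sv_assert(nrow(E) == nrow(graph$transition) && ncol(E) == 2,
            "`embedding` must be obs x 2")
  sv_assert(all(is.finite(E)), "`embedding` must be finite")
  n <- nrow(E)
  arrows <- matrix(0, n, 2)
  P <- graph$transition
  for (i in seq_len(n)) {
    js <- graph$neighbors[i, ]
    disp <- E[js, , drop = FALSE] - matrix(E[i, ], length(js), 2, byrow = TRUE)
    if (normalize_displacement) {
      nn <- sqrt(rowSums(disp^2)); nn[nn == 0] <- 1
      disp <- disp / nn
    }
    pij <- P[i, js]
    arrows[i, ] <- colSums(disp * pij) - colMeans(disp)
  }
  arrows[graph$uniform, ] <- 0
  structure(list(arrows = arrows, embedding = E, transition = P),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d arrows, mean length %.4g\n",
              nrow(x$arrows), mean(sqrt(rowSums(x$arrows^2)))))
  invisible(x)
}

#' Diffusion-rank pseudotime from a velocity graph
#'
#' A lightweight ordering along the velocity flow: mass diffuses from a
#' root (by default the observation with least incoming transition mass)
#' through the transition matrix; each observation is stamped with the step
#' at which mass first reaches it (ties within a step broken by arriving
#' mass, larger first), and the resulting order is rank-transformed and
#' min-max normalized to \[0, 1\]. Disconnected graphs are handled per
#' connected component with a warning. This is a pragmatic stand-in for
#' likelihood-based latent time, adequate for ordering but not for absolute
#' timing.
#'
#' @param graph a `velocity_graph` (or a row-stochastic transition matrix
#'   plus `neighbors = NULL`)
#' @param root optional root index; default argmin of incoming mass
#' @return numeric pseudotime in \[0, 1\] per observation
#' @export
velocity_pseudotime <- function(graph, root = NULL) {
  P <- if (inherits(graph, "velocity_graph")) graph$transition else graph
  n <- nrow(P)
  Pt <- as(as(Matrix::drop0(P), "generalMatrix"), "TsparseMatrix")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(Pt@i)) {
    g <- igraph::add_edges(g, rbind(Pt@i + 1L, Pt@j + 1L))
  }
  comp <- igraph::components(g)$membership
  if (max(comp) > 1) {
    warning(sprintf("transition graph has %d components; pseudotime computed per component",
                    max(comp)))
  }
  pt <- rep(0, n)
  degenerate <- 0L
  incoming <- as.numeric(Matrix::colSums(P))
  for (cc in seq_len(max(comp))) {
    ix <- which(comp == cc)
    Pc <- P[ix, ix, drop = FALSE]
    r <- if (!is.null(root) && (root %in% ix)) match(root, ix) else
      which.min(incoming[ix])
    # mean visitation time of the walk started at the root: cells the flow
    # reaches late accumulate their visits late
    nsteps <- min(4000L, max(200L, 8L * length(ix)))
    p <- rep(0, length(ix)); p[r] <- 1
    num <- rep(0, length(ix)); den <- p
    for (step in seq_len(nsteps)) {
      p <- as.numeric(p %*% Pc)
      num <- num + step * p
      den <- den + p
      if (sum(p) < 1e-12) break
    }
    reached <- den > 1e-12
    if (sum(reached) <= 1) {  # nothing beyond the root: no ordering exists
      pt[ix] <- 0
      degenerate <- degenerate + 1L
      next
    }
    arrival <- rep(NA_real_, length(ix))
    arrival[reached] <- num[reached] / den[reached]
    arrival[!reached] <- max(arrival, na.rm = TRUE) + 1
    rk <- rank(arrival, ties.method = "average")
    if (max(rk) > min(rk)) {
      pt[ix] <- (rk - min(rk)) / (max(rk) - min(rk))
    } else {
      pt[ix] <- 0
      degenerate <- degenerate + 1L
    }
  }
  if (degenerate > 0) {
    warning(sprintf("%d component(s) with no diffusion spread from root: pseudotime set to 0",
                    degenerate))
  }
  pt
}
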