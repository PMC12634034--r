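#' Magnitude-weighted cosine similarity between two velocity fields
#'
#' Per observation the cosine similarity `CS_i` between estimated and
#' reference vectors is weighted by the normalized reference-vector
#' magnitude `beta_i = M_i / sum_j M_j`, and the score is
#' `sum_i beta_i * CS_i`: strongly moving cells dominate, near-stationary
#' cells contribute little. The score lies in \[-1, 1\]; identical fields
#' score exactly 1 and sign-flipped fields exactly -1. A zero vector has
#' no direction, so its cosine is defined as 0.
#'
#' Works in any common space: gene-space (high-dimensional) velocity or
#' 2-D projected arrows.
#'
#' @param estimated,reference obs x d matrices of matching shape, d >= 2
#' @param weight_source which field's magnitudes define the weights;
#'   `"reference"` (default, ground-truth weighting) or `"estimated"` for
#'   sensitivity checks
#' @return object of class `similarity_breakdown`: `per_obs_cosine`,
#'   `magnitudes`, `weights` (sum to 1), `score`
#' @export
similarity_score <- function(estimated, reference,
                             weight_source = c("reference", "estimated")) {
  weight_source <- match.arg(weight_source)
  E <- as_dense(estimated); R <- as_dense(reference)
  sv_assert(all(dim(E) == dim(R)), "fields must have identical shape")
  sv_assert(ncol(E) >= 2, "vectors must have dimension >= 2")
  M <- sqrt(rowSums((if (weight_source == "reference") R else E)^2))
  if (sum(M) == 0) {
    sv_stop("all weighting vectors are zero: weights undefined")
  }
  beta <- M / sum(M)
  cs <- cos_rows(E, R)
  # ratio form: exact +/-1 when every cosine is +/-1
  structure(list(per_obs_cosine = cs, magnitudes = M, weights = beta,
                 score = sum(M * cs) / sum(M)),
            class = "similarity_breakdown")
}

#' @export
print.similarity_breakdown <- function(x, ...) {
  cat(sprintf("similarity_breakdown: score %.4f over %d observations\n",
              x$score, length(x$per_obs_cosine)))
  invisible(x)
}

#' Per-observation agreement between predicted and observed expression
#'
#' For each observation, the cosine similarity and Spearman correlation
#' (average ranks on ties) between its predicted and observed gene-vectors;
#' means are taken over observations whose observed vector has nonzero
#' variance (excluded observations are counted and reported).
#'
#' @param predicted,observed obs x genes matrices of matching shape
#' @return object of class `prediction_metrics`: `per_obs_cosine`,
#'   `per_obs_spearman` (NA where excluded), `mean_cosine`,
#'   `mean_spearman`, `n_excluded`
#' @export
prediction_metrics <- function(predicted, observed) {
  P <- as_dense(predicted); O <- as_dense(observed)
  sv_assert(all(dim(P) == dim(O)), "matrices must have identical shape")
  cs <- cos_rows(P, O)
  n <- nrow(P)
  sp <- rep(NA_real_, n)
  excl <- logical(n)
  for (i in seq_len(n)) {
    if (sd(O[i, ]) == 0 || sd(P[i, ]) == 0) {
      excl[i] <- TRUE
      next
    }
    sp[i] <- cor(P[i, ], O[i, ], method = "spearman")
  }
  if (any(excl)) {
    message(sprintf("%d observation(s) with zero-variance vectors excluded from means",
                    sum(excl)))
  }
  structure(list(per_obs_cosine = cs, per_obs_spearman = sp,
                 mean_cosine = mean(cs[!excl]),
                 mean_spearman = mean(sp[!excl]),
                 n_excluded = sum(excl)),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("prediction_metrics: mean cosine %.4f, mean Spearman %.4f (%d excluded)\n",
              x$mean_cosine, x$mean_spearman, x$n_excluded))
  invisible(x)
}
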