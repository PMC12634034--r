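#' Tidy a steady-state velocity model
#'
#' @param x a `velocity_model`
#' @param ... ignored
#' @return tibble with one row per gene: `gene`, `gamma`, `r2`, `valid`
#' @export
tidy.velocity_model <- function(x, ...) {
  tibble(gene = x$gene_ids, gamma = x$gamma, r2 = x$r2, valid = x$valid_genes)
}

#' @rdname tidy.velocity_model
#' @return for `glance()`: one-row tibble with `n_genes`, `n_valid`,
#'   `median_gamma`, `median_r2`
#' @export
glance.velocity_model <- function(x, ...) {
  tibble(n_genes = length(x$gamma), n_valid = sum(x$valid_genes),
         median_gamma = median(x$gamma, na.rm = TRUE),
         median_r2 = median(x$r2, na.rm = TRUE))
}

#' Tidy an aligned embedding
#'
#' @param x an `aligned_embedding`
#' @param ... ignored
#' @return tibble with one row per component: `component`, `similarity`,
#'   `retained`
#' @export
tidy.aligned_embedding <- function(x, ...) {
  tibble(component = seq_along(x$component_similarities),
         similarity = x$component_similarities,
         retained = x$retained)
}

#' @rdname tidy.aligned_embedding
#' @return for `glance()`: one-row tibble with `n_components`, `n_retained`,
#'   `threshold`, `best_similarity`
#' @export
glance.aligned_embedding <- function(x, ...) {
  tibble(n_components = length(x$component_similarities),
         n_retained = sum(x$retained), threshold = x$threshold,
         best_similarity = max(x$component_similarities))
}

#' Tidy a similarity breakdown
#'
#' @param x a `similarity_breakdown`
#' @param ... ignored
#' @return tibble with one row per observation: `obs`, `cosine`,
#'   `magnitude`, `weight`
#' @export
tidy.similarity_breakdown <- function(x, ...) {
  tibble(obs = seq_along(x$per_obs_cosine), cosine = x$per_obs_cosine,
         magnitude = x$magnitudes, weight = x$weights)
}

#' @rdname tidy.similarity_breakdown
#' @return for `glance()`: one-row tibble with `score` and `n_obs`
#' @export
glance.similarity_breakdown <- function(x, ...) {
  tibble(score = x$score, n_obs = length(x$per_obs_cosine))
}

#' Tidy a label transfer result
#'
#' @param x a `label_transfer`
#' @param ... ignored
#' @return tibble with one row per spot: `spot`, `assigned`, and the
#'   winning score `score`
#' @export
tidy.label_transfer <- function(x, ...) {
  tibble(spot = seq_len(nrow(x$scores)), assigned = x$assigned,
         score = x$scores[cbind(seq_len(nrow(x$scores)),
                                match(x$assigned, x$types))])
}

#' Tidy a spatiotemporal profile
#'
#' @param x a `spatiotemporal_profile`
#' @param ... ignored
#' @return tibble with one row per bin: `bin`, `t`, `variance`, `n`, and
#'   percentile columns when present
#' @export
tidy.spatiotemporal_profile <- function(x, ...) {
  out <- tibble(bin = seq_along(x$variances), t = x$bin_median_times,
                variance = x$variances, n = x$n_per_bin)
  if (!is.null(x$p_lo)) {
    out$p_lo <- x$p_lo
    out$p_hi <- x$p_hi
  }
  out
}
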