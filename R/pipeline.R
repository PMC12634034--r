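#' Pipeline configuration
#'
#' Collects every stage parameter with its default: 50 latent components,
#' component-similarity threshold 0.3, k = 50 transfer neighbors, 5%
#' steady-state quantile, 30 velocity-graph neighbors, ten pseudotime bins,
#' origin (0, 0). Validation is strict so misconfigurations fail before any
#' computation. The resolved configuration is embedded in every pipeline
#' report, and `pipeline_config(!!!jsonlite::fromJSON(...))`-style
#' round-trips reproduce it exactly.
#'
#' @param n_components latent components per dataset before alignment
#' @param threshold cosine-similarity retention cutoff, in (0, 1)
#' @param gamma optional RBF width (default 1 / n_shared_genes)
#' @param kernel `"rbf"` or `"linear"`
#' @param k transfer neighbors
#' @param quantile steady-state extreme-quantile fraction, in (0, 0.5]
#' @param graph_neighbors velocity-graph kNN size
#' @param n_bins pseudotime bins for the spatiotemporal profile
#' @param origin length-2 origin for spatial distances
#' @param seed integer seed for any stochastic stage
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(n_components = 50, threshold = 0.3, gamma = NULL,
                            kernel = "rbf", k = 50, quantile = 0.05,
                            graph_neighbors = 30, n_bins = 10,
                            origin = c(0, 0), seed = 1L) {
  sv_assert(is.numeric(threshold) && threshold > 0 && threshold < 1,
            "`threshold` must lie in (0, 1)")
  sv_assert(n_components >= 1, "`n_components` must be >= 1")
  sv_assert(k >= 1, "`k` must be >= 1")
  sv_assert(quantile > 0 && quantile <= 0.5, "`quantile` must be in (0, 0.5]")
  sv_assert(graph_neighbors >= 2, "`graph_neighbors` must be >= 2")
  sv_assert(n_bins >= 2, "`n_bins` must be >= 2")
  sv_assert(kernel %in% c("rbf", "linear"), "`kernel` must be rbf or linear")
  sv_assert(length(origin) == 2 && all(is.finite(origin)),
            "`origin` must be a finite pair")
  structure(
    list(n_components = as.integer(n_components), threshold = threshold,
         gamma = gamma, kernel = kernel, k = as.integer(k),
         quantile = quantile, graph_neighbors = as.integer(graph_neighbors),
         n_bins = as.integer(n_bins), origin = as.numeric(origin),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full spatial-velocity pipeline
#'
#' Composes all stages on in-memory datasets: integration (kernel PCA +
#' SVD alignment), kNN transfer of spliced/unspliced layers and labels,
#' steady-state velocity with spatial arrow projection and graph
#' pseudotime, and the spatiotemporal profile and omega analysis. Any
#' stage failure is re-raised with the stage named. Given identical inputs
#' and configuration the run is deterministic, so its metrics report is
#' byte-identical across repeats.
#'
#' @param ref reference [omics_dataset()] with spliced/unspliced layers
#' @param spatial spatial [omics_dataset()] with coordinates
#' @param config a [pipeline_config()]
#' @param reference_velocity optional spots x genes matrix of ground-truth
#'   velocity (same gene order as `ref`); when supplied a similarity score
#'   over the shared gene panel is reported
#' @param verbose print stage banners
#' @return object of class `pipeline_result`: `embedding`, `assignment`,
#'   `imputed`, `labels`, `velocity_model`, `graph`, `field`, `pseudotime`,
#'   `profile`, `omega`, `metrics` (flat list), `config`
#' @export
run_pipeline <- function(ref, spatial, config = pipeline_config(),
                         reference_velocity = NULL, verbose = FALSE) {
  sv_assert(inherits(config, "pipeline_config"),
            "`config` must come from pipeline_config()")
  sv_assert(!is.null(spatial$coords), "spatial dataset must carry coordinates")
  stage <- function(name, expr) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) sv_stop(sprintf(
      "pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  emb <- stage("integrate",
               integrate(ref, spatial, n_components = config$n_components,
                         threshold = config$threshold, gamma = config$gamma,
                         kernel = config$kernel))
  asg <- stage("impute", {
    a <- find_neighbors(emb, k = config$k)
    compute_weights(a)
  })
  imp <- stage("impute", impute_layers(asg, ref))
  lab <- if (!is.null(ref$labels)) {
    stage("transfer_labels", transfer_labels(asg, ref$labels))
  }
  vm <- stage("velocity",
              fit_steady_state(imp$spliced, imp$unspliced,
                               quantile = config$quantile,
                               gene_ids = imp$gene_ids))
  graph <- stage("velocity",
                 velocity_graph(vm, imp$spliced,
                                neighbors = config$graph_neighbors))
  field <- stage("velocity", project_velocity(graph, spatial$coords))
  pt <- if (!is.null(spatial$pseudotime)) spatial$pseudotime else
    stage("velocity", suppressWarnings(velocity_pseudotime(graph)))

  d <- distance_from_origin(spatial$coords, config$origin)
  profile <- stage("spatiotemporal",
                   percentile_trends(d, pt, n_bins = config$n_bins))
  omega <- if (!is.null(lab)) {
    y <- mean_nonzero_expression(spatial$matrix)
    stage("spatiotemporal", estimate_omega(pt, d, y, lab$assigned))
  }

  metrics <- list(
    n_shared_genes = length(attr(emb, "genes")$genes),
    n_components_retained = sum(emb$retained),
    component_similarities = round(emb$component_similarities, 10),
    n_valid_velocity_genes = sum(vm$valid_genes),
    median_gamma = round(median(vm$gamma, na.rm = TRUE), 10),
    mean_arrow_length = round(mean(sqrt(rowSums(field$arrows^2))), 10)
  )
  if (!is.null(reference_velocity)) {
    shared <- attr(emb, "genes")
    est <- vm$velocity[, match(shared$genes, imp$gene_ids), drop = FALSE]
    truth <- as_dense(reference_velocity)[, shared$ref_index, drop = FALSE]
    sim <- stage("evaluate", similarity_score(est, truth))
    metrics$velocity_similarity_score <- round(sim$score, 10)
  }
  if (!is.null(omega)) {
    metrics$omega <- setNames(round(omega$omega, 10), omega$type)
  }
  metrics$config <- unclass(config)

  structure(
    list(embedding = emb, assignment = asg, imputed = imp, labels = lab,
         velocity_model = vm, graph = graph, field = field, pseudotime = pt,
         profile = profile, omega = omega, metrics = metrics,
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  retained components: %d\n", x$metrics$n_components_retained))
  cat(sprintf("  valid velocity genes: %d\n", x$metrics$n_valid_velocity_genes))
  if (!is.null(x$metrics$velocity_similarity_score)) {
    cat(sprintf("  velocity similarity score: %.4f\n",
                x$metrics$velocity_similarity_score))
  }
  invisible(x)
}

#' Write a pipeline metrics report as JSON
#'
#' Deterministic serialization (fixed digit count, unboxed scalars): two
#' runs with the same inputs and configuration produce byte-identical
#' files.
#'
#' @param result a `pipeline_result`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_metrics <- function(result, path) {
  jsonlite::write_json(result$metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
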