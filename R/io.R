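#' Read a paired-omics dataset from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx_dir`}{a directory in 10x-style layout: `matrix.mtx`
#'     (genes x obs, MatrixMarket), `genes.tsv`, `barcodes.tsv`, optional
#'     layer files `spliced.mtx` / `unspliced.mtx`, optional `coords.csv`
#'     (`obs_id,x,y`) and `obs_meta.csv` (`obs_id` plus `label` and/or
#'     `pseudotime` columns).}
#'   \item{`csv`}{a single obs x genes matrix with header (gene IDs) and
#'     row names (obs IDs); no layers.}
#'   \item{`h5ad`}{an AnnData container. Layers named `spliced`/`unspliced`,
#'     spatial coordinates under `obsm["spatial"]`, labels in
#'     `obs["cell_type"]` and pseudotime in `obs["pseudotime"]` are picked
#'     up. Conversion runs through the `python` + `anndata` interpreter on
#'     PATH.}
#' }
#'
#' @param path file (csv, h5ad) or directory (mtx_dir)
#' @param format one of `"auto"`, `"h5ad"`, `"mtx_dir"`, `"csv"`; `"auto"`
#'   infers from the extension / directory-ness of `path`
#' @return an [omics_dataset()]
#' @export
read_dataset <- function(path, format = c("auto", "h5ad", "mtx_dir", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  sv_assert(file.exists(path), paste0("path does not exist: ", path),
            class = "spotvelo_format_error")
  switch(format,
    csv = read_csv_matrix(path),
    mtx_dir = read_mtx_dir(path),
    h5ad = read_h5ad(path)
  )
}

guess_format <- function(path) {
  if (dir.exists(path)) return("mtx_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext == "h5ad") return("h5ad")
  if (ext %in% c("csv", "txt")) return("csv")
  sv_stop(paste0("cannot infer format of '", path,
                 "'; pass `format` explicitly"), "spotvelo_format_error")
}

read_csv_matrix <- function(path) {
  df <- tryCatch(read.csv(path, row.names = 1, check.names = FALSE),
                 error = function(e) sv_stop(
                   paste0("failed to parse CSV '", path, "': ", conditionMessage(e)),
                   "spotvelo_format_error"))
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  omics_dataset(m, gene_ids = colnames(df), obs_ids = rownames(df))
}

read_mtx_dir <- function(path) {
  need <- c(matrix = "matrix.mtx", genes = "genes.tsv", barcodes = "barcodes.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      sv_stop(paste0("mtx_dir is missing required file '", f, "' in ", path),
              "spotvelo_format_error")
    }
  }
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))       # genes x obs
  genes <- readLines(file.path(path, "genes.tsv"))
  obs <- readLines(file.path(path, "barcodes.tsv"))
  X <- Matrix::t(m)                                        # obs x genes
  read_layer <- function(nm) {
    f <- file.path(path, paste0(nm, ".mtx"))
    if (file.exists(f)) Matrix::t(Matrix::readMM(f)) else NULL
  }
  coords <- labels <- pt <- NULL
  cf <- file.path(path, "coords.csv")
  if (file.exists(cf)) {
    cd <- read.csv(cf)
    ord <- match(obs, cd$obs_id)
    sv_assert(!anyNA(ord), "coords.csv does not cover all barcodes",
              class = "spotvelo_format_error")
    coords <- unname(as.matrix(cd[ord, c("x", "y")]))
  }
  mf <- file.path(path, "obs_meta.csv")
  if (file.exists(mf)) {
    md <- read.csv(mf)
    ord <- match(obs, md$obs_id)
    sv_assert(!anyNA(ord), "obs_meta.csv does not cover all barcodes",
              class = "spotvelo_format_error")
    if ("label" %in% names(md)) labels <- as.character(md$label[ord])
    if ("pseudotime" %in% names(md)) pt <- md$pseudotime[ord]
  }
  omics_dataset(X, gene_ids = genes, obs_ids = obs,
                spliced = read_layer("spliced"),
                unspliced = read_layer("unspliced"),
                coords = coords, labels = labels, pseudotime = pt)
}

#' Write a dataset to disk
#'
#' Round-trips through [read_dataset()] bit-exactly for integer counts and
#' to full double precision for reals (MatrixMarket values are written with
#' 17 significant digits).
#'
#' @param ds an [omics_dataset()]
#' @param path output file (csv, h5ad) or directory (mtx_dir; created)
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5ad"`
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path, format = c("mtx_dir", "csv", "h5ad")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) sv_stop(
                       paste0("unsupported format: ", format[1]),
                       "spotvelo_format_error"))
  switch(format,
    csv = {
      m <- as_dense(ds$matrix)
      dimnames(m) <- list(ds$obs_ids, ds$gene_ids)
      ok <- tryCatch({ write.csv(m, path); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) sv_stop(paste0("cannot write to ", path), "spotvelo_io_error")
    },
    mtx_dir = write_mtx_dir(ds, path),
    h5ad = write_h5ad(ds, path)
  )
  invisible(path)
}

write_mtx_dir <- function(ds, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0) {
    sv_stop(paste0("cannot write to directory ", path), "spotvelo_io_error")
  }
  wm <- function(m, f) {
    Matrix::writeMM(as(as(Matrix(as_dense(m), sparse = TRUE), "CsparseMatrix"),
                       "generalMatrix"),
                    file.path(path, f))
  }
  wm(Matrix::t(store_sparse(ds$matrix)), "matrix.mtx")
  writeLines(ds$gene_ids, file.path(path, "genes.tsv"))
  writeLines(ds$obs_ids, file.path(path, "barcodes.tsv"))
  if (!is.null(ds$spliced)) wm(Matrix::t(store_sparse(ds$spliced)), "spliced.mtx")
  if (!is.null(ds$unspliced)) wm(Matrix::t(store_sparse(ds$unspliced)), "unspliced.mtx")
  if (!is.null(ds$coords)) {
    write.csv(data.frame(obs_id = ds$obs_ids, x = ds$coords[, 1],
                         y = ds$coords[, 2]),
              file.path(path, "coords.csv"), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(ds$labels) || !is.null(ds$pseudotime)) {
    md <- data.frame(obs_id = ds$obs_ids)
    if (!is.null(ds$labels)) md$label <- ds$labels
    if (!is.null(ds$pseudotime)) md$pseudotime <- ds$pseudotime
    write.csv(md, file.path(path, "obs_meta.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

store_sparse <- function(m) {
  if (is(m, "sparseMatrix")) m else Matrix(as_dense(m), sparse = TRUE)
}

# ---- h5ad bridge -----------------------------------------------------------
# AnnData containers are HDF5; conversion runs through the python/anndata
# interpreter on PATH via the shipped helper script, using the mtx_dir
# layout as the on-disk exchange format.

h5ad_bridge <- function(args) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    sv_stop("h5ad support requires a `python` interpreter with `anndata` on PATH",
            "spotvelo_format_error")
  }
  script <- system.file("python", "h5ad_bridge.py", package = "spotvelo")
  sv_assert(nzchar(script), "h5ad bridge script not found in installed package")
  out <- suppressWarnings(system2(py, c(shQuote(script), shQuote(args)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    sv_stop(paste0("h5ad conversion failed:\n", paste(out, collapse = "\n")),
            "spotvelo_format_error")
  }
  invisible(out)
}

read_h5ad <- function(path) {
  tmp <- tempfile("h5ad_exchange_")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  h5ad_bridge(c("to-exchange", path, tmp))
  read_mtx_dir(tmp)
}

write_h5ad <- function(ds, path) {
  tmp <- tempfile("h5ad_exchange_")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_mtx_dir(ds, tmp)
  h5ad_bridge(c("from-exchange", tmp, path))
  invisible(path)
}
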