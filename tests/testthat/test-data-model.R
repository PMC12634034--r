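test_that("constructor enforces invariants", {
  expect_error(
    omics_dataset(matrix(1, 2, 3), gene_ids = c("a", "b", "a")),
    "duplicated gene IDs: a")
  expect_error(
    omics_dataset(matrix(1, 2, 2), gene_ids = c("a", "b"),
                  spliced = matrix(1, 3, 2)),
    "spliced")
  expect_error(
    omics_dataset(matrix(-1, 2, 2), gene_ids = c("a", "b")),
    "non-negative")
  ds <- toy_dataset(coords = TRUE)
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(colnames(ds$coords), c("x", "y"))
})

test_that("pseudotime is normalized into [0, 1]", {
  ds <- omics_dataset(matrix(1, 3, 2), gene_ids = c("a", "b"),
                      pseudotime = c(2, 6, 10))
  expect_equal(ds$pseudotime, c(0, 0.5, 1))
})

test_that("sparse/dense storage switches at 50% density", {
  dense <- omics_dataset(matrix(1, 4, 4), gene_ids = paste0("g", 1:4))
  expect_true(is.matrix(dense$matrix))
  m <- matrix(0, 4, 4); m[1, 1] <- 3
  sparse <- omics_dataset(m, gene_ids = paste0("g", 1:4))
  expect_s4_class(sparse$matrix, "sparseMatrix")
})

test_that("gene intersection is sorted, indexed, and symmetric in membership", {
  ref <- omics_dataset(matrix(1, 2, 3), gene_ids = c("A", "B", "C"))
  sp <- omics_dataset(matrix(1, 2, 3), gene_ids = c("D", "C", "B"))
  gi <- intersect_genes(ref, sp)
  expect_equal(gi$genes, c("B", "C"))
  expect_equal(ref$gene_ids[gi$ref_index], gi$genes)
  expect_equal(sp$gene_ids[gi$spatial_index], gi$genes)
  # symmetric as sets
  expect_setequal(gi$genes, intersect_genes(sp, ref)$genes)
  # identical gene lists -> identity indices
  gi2 <- intersect_genes(ref, ref)
  expect_equal(gi2$ref_index, gi2$spatial_index)
  # disjoint -> actionable error
  sp2 <- omics_dataset(matrix(1, 2, 2), gene_ids = c("X", "Y"))
  expect_error(intersect_genes(ref, sp2), "harmonize")
})

test_that("normalization scales rows to target and preserves layer ratios", {
  mk <- function(m, s = NULL, u = NULL) {
    omics_dataset(m, gene_ids = paste0("g", seq_len(ncol(m))),
                  spliced = s, unspliced = u)
  }
  # already at target
  expect_equal(as.numeric(normalize_expression(mk(rbind(c(2, 2))),
                                               target_sum = 4,
                                               log1p = FALSE)$matrix),
               c(2, 2))
  expect_equal(as.numeric(normalize_expression(mk(rbind(c(1, 3))),
                                               target_sum = 4,
                                               log1p = FALSE)$matrix),
               c(1, 3))
  # hand scaling: (10, 30) at target 4 -> (1, 3)
  expect_equal(as.numeric(normalize_expression(mk(rbind(c(10, 30))),
                                               target_sum = 4,
                                               log1p = FALSE)$matrix),
               c(1, 3))
  # spliced:unspliced ratios survive normalization exactly
  ds <- toy_dataset(n = 5, g = 6, layers = TRUE)
  nds <- normalize_expression(ds, log1p = TRUE)
  s0 <- as_mat(ds$spliced); u0 <- as_mat(ds$unspliced)
  s1 <- as_mat(nds$spliced); u1 <- as_mat(nds$unspliced)
  ok <- u0 > 0 & u1 > 0
  expect_equal((s1 / u1)[ok], (s0 / u0)[ok], tolerance = 1e-12)
  # raw counts retained
  expect_equal(as_mat(nds$counts), as_mat(ds$matrix))
  # all-zero row warns and is left unscaled
  m <- rbind(c(0, 0), c(2, 2))
  expect_warning(nz <- normalize_expression(mk(m), target_sum = 4, log1p = FALSE),
                 "unscaled")
  expect_equal(as.numeric(as_mat(nz$matrix)[1, ]), c(0, 0))
})

test_that("csv read-back is the identity on a minimal fixture", {
  ds <- toy_dataset(n = 3, g = 4)
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f, "csv")
  back <- read_dataset(f)
  expect_equal(dim(back), c(3L, 4L))
  expect_equal(as_mat(back$matrix), as_mat(ds$matrix))
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$obs_ids, ds$obs_ids)
  expect_null(back$spliced)
})

test_that("mtx_dir round trip preserves counts, layers and metadata", {
  ds <- toy_dataset(n = 6, g = 5, layers = TRUE, coords = TRUE,
                    labels = c("A", "A", "B", "B", "C", "C"))
  ds$pseudotime <- seq(0, 1, length.out = 6)
  d <- tempfile()
  write_dataset(ds, d, "mtx_dir")
  back <- read_dataset(d)
  expect_equal(as_mat(back$matrix), as_mat(ds$matrix))       # integer counts exact
  expect_equal(as_mat(back$spliced), as_mat(ds$spliced))
  expect_equal(as_mat(back$unspliced), as_mat(ds$unspliced))
  expect_equal(back$coords, ds$coords, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$pseudotime, ds$pseudotime, tolerance = 1e-12)
})

test_that("real-valued matrices round trip within 1e-12 relative error", {
  m <- matrix(runif(20) * 1e3, 4, 5)
  ds <- omics_dataset(m, gene_ids = paste0("g", 1:5))
  d <- tempfile()
  write_dataset(ds, d, "mtx_dir")
  back <- read_dataset(d)
  expect_equal(as_mat(back$matrix), m, tolerance = 1e-12)
})

test_that("I/O error contracts name the problem", {
  d <- tempfile(); dir.create(d)
  ds <- toy_dataset()
  write_dataset(ds, d, "mtx_dir")
  file.remove(file.path(d, "genes.tsv"))
  expect_error(read_dataset(d), "genes.tsv")
  expect_error(write_dataset(ds, tempfile(), "parquet"), "unsupported format")
  expect_error(read_dataset(tempfile(fileext = ".csv")), "does not exist")
  # unwritable target: a path whose parent is a regular file
  blocker <- tempfile(); file.create(blocker)
  expect_error(write_dataset(ds, file.path(blocker, "sub"), "mtx_dir"),
               "cannot write")
})

test_that("h5ad round trip through the python bridge preserves the dataset", {
  ds <- toy_dataset(n = 4, g = 3, layers = TRUE, coords = TRUE,
                    labels = c("A", "B", "A", "B"))
  f <- tempfile(fileext = ".h5ad")
  write_dataset(ds, f, "h5ad")
  back <- read_dataset(f)
  expect_equal(as_mat(back$matrix), as_mat(ds$matrix))
  expect_equal(as_mat(back$spliced), as_mat(ds$spliced))
  expect_equal(back$coords, ds$coords, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
})

test_that("subsetting preserves layers and never reorders silently", {
  ds <- toy_dataset(n = 5, g = 6, layers = TRUE)
  sub <- subset_dataset(ds, genes = c("g2", "g4"), obs = c(1, 3))
  expect_equal(sub$gene_ids, c("g2", "g4"))
  expect_equal(as_mat(sub$spliced), as_mat(ds$spliced)[c(1, 3), c(2, 4)])
})
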