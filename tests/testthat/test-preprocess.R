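# Quality control, normalisation and standardisation.

test_that("cells above the mitochondrial fraction threshold are removed", {
  x <- toy_counts(c(75, 25,
                    90, 10,
                    85, 15), genes = c("G1", "MT-1"))
  out <- qc_filter(x, qc_config(mito_fraction_max = 0.20))
  expect_identical(rownames(out$matrix), c("c2", "c3"))   # 25% mito fails
  expect_identical(out$log$removed[out$log$criterion == "mito_fraction_max"], 1L)
})

test_that("all-permissive thresholds are the identity and min_genes is >=", {
  x <- toy_counts(c(5, 0, 1,
                    2, 3, 4,
                    1, 1, 1), genes = c("G1", "G2", "G3"))
  ident <- qc_filter(x, qc_config(mito_fraction_max = 1.0))
  expect_identical(unclass(ident$matrix), unclass(x))

  # cell c1 expresses 2 genes; min_genes 3 removes exactly it
  out <- qc_filter(x, qc_config(min_genes_per_cell = 3, mito_fraction_max = 1))
  expect_identical(rownames(out$matrix), c("c2", "c3"))
  # a cell expressing exactly min_genes genes is kept (>= semantics)
  out2 <- qc_filter(x, qc_config(min_genes_per_cell = 2, mito_fraction_max = 1))
  expect_identical(nrow(out2$matrix), 3L)
})

test_that("qc log totals are consistent with the applied filters", {
  x <- toy_counts(c(100, 0, 0,
                    40, 30, 30,
                    1, 1, 0), genes = c("G1", "G2", "G3"))
  out <- qc_filter(x, qc_config(min_counts_per_cell = 10,
                                min_cells_per_gene = 2,
                                mito_fraction_max = 1))
  lg <- out$log
  expect_identical(lg$removed[lg$criterion == "cells_removed_total"],
                   3L - nrow(out$matrix))
  expect_identical(ncol(x) - ncol(out$matrix),
                   lg$removed[lg$criterion == "min_cells_per_gene"])
  expect_error(qc_filter(x, qc_config(min_counts_per_cell = 1000)),
               "empty after QC")
})

test_that("library-size normalisation conserves proportions and row sums", {
  x <- toy_counts(c(1, 1, 2,
                    10, 0, 0), genes = c("G1", "G2", "G3"))
  n6 <- normalize_total(x, 1e6)
  expect_equal(unname(n6["c1", ]), c(250000, 250000, 500000))
  n4 <- normalize_total(x, 1e4)
  expect_equal(unname(n4["c2", ]), c(10000, 0, 0))
  expect_equal(unname(rowSums(n4)), rep(1e4, 2), tolerance = 1e-6)
  # within-cell proportions unchanged
  expect_equal(n6["c1", ] / sum(n6["c1", ]), x["c1", ] / sum(x["c1", ]))
  x0 <- toy_counts(c(0, 0, 1, 1), genes = c("G1", "G2"))
  expect_error(normalize_total(x0), "zero total")
})

test_that("log1p transform maps 0 to 0, e-1 to 1, and is monotone", {
  x <- expr_matrix(matrix(c(0, exp(1) - 1, 2, 7), 2, 2,
                          dimnames = list(c("a", "b"), c("g1", "g2"))),
                   "normalized")
  out <- log1p_transform(x)
  expect_equal(out["a", "g1"], 0)
  expect_equal(out["b", "g1"], 1)
  expect_true(all(diff(sort(as.numeric(out))) >= 0))
  expect_identical(expr_layer(out), "log_normalized")
  neg <- expr_matrix(matrix(-1, 1, 1, dimnames = list("a", "g")), "normalized")
  expect_error(log1p_transform(neg), "non-negative")
})

test_that("z-scoring gives population moments, zero for constants, idempotency", {
  m <- expr_matrix(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                          dimnames = list(paste0("s", 1:3), c("v", "k"))),
                   "log_normalized")
  z <- zscore_genes(m)
  expect_equal(mean(z[, "v"]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z[, "v"]^2)), 1, tolerance = 1e-12)  # population sd
  expect_identical(unname(z[, "k"]), c(0, 0, 0))
  # idempotent on non-degenerate columns
  z2 <- zscore_genes(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-12)
  expect_error(zscore_genes(m[1, , drop = FALSE]), "at least 2")
})

test_that("per-gene moments after z-scoring are tight across a random matrix", {
  set.seed(3)
  m <- expr_matrix(matrix(rlnorm(600), 30, 20,
                          dimnames = list(paste0("s", 1:30),
                                          paste0("g", 1:20))),
                   "log_normalized")
  z <- zscore_genes(m)
  expect_true(all(abs(colMeans(z)) < 1e-8))
  expect_true(all(abs(sqrt(colMeans(z^2)) - 1) < 1e-6))
})
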