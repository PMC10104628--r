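# The paired bulk/single-cell generator.

test_that("source domain carries the configured class effect on signal genes only", {
  cfg <- sim_config(n_genes = 200, n_signal_genes = 30, n_source = 2000,
                    n_target = 50, effect_size = 1.5, seed = 8)
  sig <- drugadda:::signal_structure(cfg)
  src <- simulate_source(cfg, sig)
  y <- drugadda:::align_labels(src$matrix, src$labels)
  diff <- colMeans(src$matrix[y == 1, , drop = FALSE]) -
    colMeans(src$matrix[y == 0, , drop = FALSE])
  oriented <- diff[sig$signal_genes] * sig$direction
  expect_equal(mean(oriented), cfg$effect_size, tolerance = 0.1)
  null_genes <- setdiff(colnames(src$matrix), sig$signal_genes)
  expect_lt(max(abs(diff[null_genes])), 0.5)
  expect_equal(mean(y), cfg$source_sensitive_frac, tolerance = 0.01)
})

test_that("generators are deterministic under the configuration seed", {
  cfg <- sim_config(n_genes = 60, n_source = 40, n_target = 30,
                    n_signal_genes = 10, seed = 91)
  s1 <- simulate_domain_pair(cfg)
  s2 <- simulate_domain_pair(cfg)
  expect_identical(unclass(s1$source$matrix), unclass(s2$source$matrix))
  expect_identical(unclass(s1$target$matrix), unclass(s2$target$matrix))
  expect_identical(s1$target$labels$label, s2$target$labels$label)
  s3 <- simulate_domain_pair(sim_config(n_genes = 60, n_source = 40,
                                        n_target = 30, n_signal_genes = 10,
                                        seed = 92))
  expect_false(identical(unclass(s1$source$matrix),
                         unclass(s3$source$matrix)))
})

test_that("target counts show the configured dropout and library structure", {
  cfg <- sim_config(n_genes = 300, n_signal_genes = 30, n_source = 30,
                    n_target = 400, dropout_rate = 0.4, shift_magnitude = 0,
                    library_size_mean = 3000, library_size_dispersion = 0.3,
                    seed = 15)
  tgt <- simulate_target(cfg)
  m <- unclass(tgt$matrix)
  expect_true(all(m >= 0) && all(m == round(m)))
  # zero fraction at least the forced dropout rate (Poisson zeros add more)
  expect_gt(mean(m == 0), cfg$dropout_rate)
  # per-cell totals reflect the log-normal library spec shrunk by dropout
  totals <- rowSums(m)
  expect_equal(mean(totals), cfg$library_size_mean * (1 - cfg$dropout_rate),
               tolerance = 0.1 * cfg$library_size_mean)
  # mitochondrial genes present with roughly the configured share
  mito <- startsWith(colnames(m), "MT-")
  expect_identical(sum(mito), cfg$n_mito_genes)
  share <- sum(m[, mito]) / sum(m)
  expect_equal(share, cfg$mito_count_share, tolerance = 0.03)
  expect_true(isTRUE(attr(tgt$labels, "evaluation_only")))
})

test_that("zero shift and zero dropout recover a clean count family", {
  cfg <- sim_config(n_genes = 80, n_signal_genes = 10, n_source = 30,
                    n_target = 120, dropout_rate = 0, shift_magnitude = 0,
                    seed = 4)
  tgt <- simulate_target(cfg)
  expect_null(tgt$shift_loadings)
  m <- unclass(tgt$matrix)
  expect_lt(mean(m == 0), 0.6)   # only Poisson zeros remain
})

test_that("cohort simulation gives prognostic signal genes and null genes", {
  co <- simulate_cohort(n_genes = 60, n_signal_genes = 15, effect_size = 2,
                        seed = 44)
  expect_equal(sum(co$outcome), 14)
  expect_equal(length(co$outcome) - sum(co$outcome), 26)
  tab <- single_gene_auc(co$matrix, co$outcome)
  sig <- tab$auc[tab$gene %in% co$signal_genes]
  nul <- tab$auc[!tab$gene %in% co$signal_genes]
  expect_gt(mean(sig), 0.7)
  expect_lt(mean(nul), mean(sig))
  again <- simulate_cohort(n_genes = 60, n_signal_genes = 15, effect_size = 2,
                           seed = 44)
  expect_identical(unclass(co$matrix), unclass(again$matrix))
})

test_that("the full transfer experiment wrapper runs end to end at small scale", {
  res <- transfer_experiment(sim_config(n_genes = 80, n_signal_genes = 12,
                                        n_source = 80, n_target = 60,
                                        seed = 19),
                             lambda = 0.3, seed = 2,
                             h_dim = 16, z_dim = 8, epochs = 4)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_true(res$aupr >= 0 && res$aupr <= 1)
  expect_s3_class(res$model, "adda")
  expect_identical(colnames(res$source), colnames(res$target))
})
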