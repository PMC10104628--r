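# Attribution, biomarker calling and the exact lineage tests.

test_that("integrated gradients match the closed form for a logistic-linear model", {
  w <- c(0.8, -0.5, 0.3, 0.6)
  model <- logistic_linear_model(w)
  x <- c(1.2, -0.7, 0.4, -1.1)
  names(x) <- model$genes
  c_ <- sum(w * x)
  # exact path integral of sigma'(t*c): (sigma(c) - sigma(0)) / c
  exact <- w * x * (plogis(c_) - 0.5) / c_
  ig <- integrated_gradients(model, x, steps = 200)
  expect_equal(as.numeric(ig), unname(exact), tolerance = 5e-3)
  expect_lt(abs(sum(ig) - (plogis(c_) - 0.5)), 1e-3)
})

test_that("attribution is zero at the baseline and refines with steps", {
  st <- small_study()
  base <- numeric(ncol(st$target))
  ig0 <- integrated_gradients(st$fit, base, steps = 20)
  expect_true(all(ig0 == 0))

  x <- st$target[1, ]
  errs <- vapply(c(10, 40, 160), function(s) {
    attr(integrated_gradients(st$fit, x, steps = s,
                              completeness_tol = Inf), "completeness_error")
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("completeness holds on the fitted model at moderate step counts", {
  st <- small_study()
  ig <- integrated_gradients(st$fit, st$target[1:5, ], steps = 50,
                             completeness_tol = Inf)
  expect_true(all(attr(ig, "completeness_error") < 1e-2))
})

test_that("mean attribution averages cells within folds, then folds", {
  f1 <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  f2 <- matrix(7:12, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- mean_attribution(list(f1, f2))
  expect_equal(m, (colMeans(f1) + colMeans(f2)) / 2)
  # permutation over folds does not matter
  expect_equal(mean_attribution(list(f2, f1)), m)
  # equal fold sizes equal the flat mean
  expect_equal(m, colMeans(rbind(f1, f2)))
  # single fold, single cell: identity
  one <- matrix(c(5, 6), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(mean_attribution(list(one)), c(a = 5, b = 6))
})

test_that("tail gene selection sizes and monotonicity in q", {
  attr_vec <- setNames(seq_len(100) + rnorm(100, 0, 1e-6), paste0("g", 1:100))
  t5 <- tail_genes(attr_vec, 0.05)
  expect_length(t5, 10)
  t50 <- tail_genes(attr_vec, 0.5)
  expect_length(t50, 100)
  expect_true(all(t5 %in% tail_genes(attr_vec, 0.25)))
})

test_that("rank-sum DE finds direction and flags constant genes", {
  set.seed(6)
  n <- 10
  expr <- expr_matrix(
    matrix(c(rnorm(n, 5), rnorm(n, 0),     # gene up in group a
             rnorm(2 * n),                 # null gene
             rep(1, 2 * n)),               # constant gene
           2 * n, 3,
           dimnames = list(paste0("c", 1:(2 * n)), c("up_a", "null", "flat"))),
    "zscored")
  de <- rank_genes_de(expr, paste0("c", 1:n), paste0("c", (n + 1):(2 * n)))
  up <- de[de$gene == "up_a", ]
  expect_identical(up$direction, 1)
  expect_lt(up$p_value, 0.001)
  flat <- de[de$gene == "flat", ]
  expect_true(flat$constant)
  expect_identical(flat$p_value, 1)
  expect_true(all(de$p_adjusted >= de$p_value))
  expect_error(rank_genes_de(expr, paste0("c", 1:2), paste0("c", 2:4)),
               "disjoint")
})

test_that("BH adjustment matches the hand-computed step-down formula", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  # p_(i) * n / i with monotonicity from the largest p downwards
  raw <- p * length(p) / seq_along(p)
  manual <- rev(cummin(rev(raw)))
  expect_equal(manual, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(p.adjust(p, "BH"), manual)
})

test_that("biomarker sets partition significant genes by direction", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   direction = c(1, -1, 1, -1),
                   p_value = c(0.001, 0.002, 0.2, 0.9),
                   p_adjusted = c(0.004, 0.004, 0.3, 0.9))
  bm <- biomarker_sets(de, alpha = 0.05)
  expect_identical(bm$sc_sens, "a")
  expect_identical(bm$sc_res, "b")
  expect_length(intersect(bm$sc_sens, bm$sc_res), 0)
  all_in <- biomarker_sets(de, alpha = 1)
  expect_setequal(c(all_in$sc_sens, all_in$sc_res), de$gene)
  empty <- biomarker_sets(de[0, ], alpha = 0.05)
  expect_length(empty$sc_sens, 0)
})

test_that("single-gene prognostic AUC is oriented and behaves at the extremes", {
  set.seed(12)
  outcome <- rep(c(1, 0), each = 20)
  expr <- expr_matrix(
    matrix(c(ifelse(outcome == 1, 2, -2) + rnorm(40, 0, 0.1),
             ifelse(outcome == 1, -2, 2) + rnorm(40, 0, 0.1),
             rnorm(40)),
           40, 3, dimnames = list(paste0("p", 1:40),
                                  c("perfect", "anti", "noise"))),
    "normalized")
  tab <- single_gene_auc(expr, outcome)
  expect_equal(tab$auc[tab$gene == "perfect"], 1.0)
  expect_identical(tab$direction[tab$gene == "anti"], "negative")
  expect_gte(tab$auc[tab$gene == "anti"], 0.95)
  expect_lt(abs(tab$auc[tab$gene == "noise"] - 0.5), 0.25)
  expect_warning(single_gene_auc(expr, outcome, c("perfect", "nope")), "absent")
})

test_that("gene-set AUC comparison is symmetric with a rank-sum p", {
  set.seed(3)
  a <- runif(30, 0.6, 0.8)
  b <- runif(30, 0.5, 0.7)
  cmp <- gene_set_auc_compare(a, b)
  expect_equal(cmp$median_a, median(a))
  swapped <- gene_set_auc_compare(b, a)
  expect_equal(swapped$p_value, cmp$p_value)
  expect_equal(swapped$median_a, cmp$median_b)
  same <- gene_set_auc_compare(a, a)
  expect_gt(same$p_value, 0.9)
})

test_that("fisher exact reproduces the lineage tables and stats::fisher.test", {
  vor <- fisher_exact(c(19, 661, 41, 113))
  expect_lt(vor$p_value, 1e-5)
  sor <- fisher_exact(c(10, 241, 21, 121))
  expect_equal(sor$p_value, 3e-4, tolerance = 0.1)
  bal <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$p_value, 1)
  expect_equal(bal$odds_ratio, 1)
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "non-negative")

  set.seed(10)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("fisher exact agrees with margin-wise enumeration on small tables", {
  gap <- 0
  for (n in c(5, 12, 25)) {
    for (r1 in 0:n) {
      for (k in 0:n) {
        a_min <- max(0, k - (n - r1)); a_max <- min(k, r1)
        for (a in a_min:a_max) {
          b <- r1 - a; c_ <- k - a; d <- n - r1 - c_
          gap <- max(gap, abs(fisher_exact(c(a, b, c_, d))$p_value -
                                fisher_oracle(a, b, c_, d)))
        }
      }
    }
  }
  expect_lt(gap, 1e-12)
})

test_that("sensitive fractions reproduce the printed lineage percentages", {
  expect_equal(round(sensitive_fraction(c(19, 661, 41, 113), 1), 2), 2.79)
  expect_equal(round(sensitive_fraction(c(19, 661, 41, 113), 2), 2), 26.62)
  expect_equal(round(sensitive_fraction(c(10, 241, 21, 121), 1), 2), 3.98)
  expect_equal(round(sensitive_fraction(c(10, 241, 21, 121), 2), 2), 14.79)
  expect_identical(sensitive_fraction(c(0, 10, 1, 1), 1), 0)
})
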