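# Model interpretation: integrated-gradients gene attribution, attribution
# tail genes, differential-expression biomarker sets, single-gene prognostic
# AUC, and the lineage-stratified Fisher exact test.

#' Integrated-gradients attribution of the sensitivity probability
#'
#' Path-integral attribution of F(x) = P(M(x)), the predicted sensitivity
#' probability, from a baseline x' to each cell x:
#' `IG_i = (x_i - x'_i) * (1/steps) * sum_m dF/dx_i` evaluated at
#' `x' + (m/steps) * (x - x')`, m = 1..steps. Satisfies the completeness
#' axiom `sum_i IG_i ~ F(x) - F(x')` up to Riemann-sum error O(1/steps);
#' the realised error per cell is checked at runtime and stored.
#'
#' The default baseline is the all-zero vector, which in z-scored expression
#' space is approximately the per-gene cohort mean.
#'
#' @param model An [adda()] fit (evaluation mode is used throughout).
#' @param x One cell (numeric vector) or a cells x genes matrix.
#' @param baseline Baseline vector x' (default all zeros).
#' @param steps Riemann-sum resolution (default 50).
#' @param completeness_tol Warn if any cell's completeness gap exceeds this
#'   (default 1e-2).
#' @return Cells x genes attribution matrix with attributes
#'   `"completeness_error"` (per cell) and `"prediction"` (F(x)).
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50L,
                                 completeness_tol = 1e-2) {
  stopifnot(inherits(model, "adda"), steps >= 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  g <- length(model$genes)
  if (ncol(x) != g) stopf("x has %d genes, model expects %d", ncol(x), g)
  if (is.null(baseline)) baseline <- numeric(g)
  stopifnot(length(baseline) == g)

  alphas <- seq_len(steps) / steps
  out <- matrix(0, nrow(x), g, dimnames = list(rownames(x), model$genes))
  f_x <- numeric(nrow(x))
  f_0 <- predict_prob_vec(model, matrix(baseline, 1))
  for (ci in seq_len(nrow(x))) {
    diff <- x[ci, ] - baseline
    pts <- outer(alphas, diff) + rep(baseline, each = steps)
    grads <- input_gradient(model, pts)
    if (any(!is.finite(grads))) stopf("non-finite gradient in attribution")
    out[ci, ] <- diff * colMeans(grads)
    f_x[ci] <- predict_prob_vec(model, x[ci, , drop = FALSE])
  }
  err <- abs(rowSums(out) - (f_x - f_0))
  if (any(err > completeness_tol)) {
    warning(sprintf("completeness gap up to %.3g exceeds %.3g; increase steps",
                    max(err), completeness_tol))
  }
  attr(out, "completeness_error") <- err
  attr(out, "prediction") <- f_x
  out
}

predict_prob_vec <- function(model, X) {
  as.numeric(mlp_forward(model$predictor,
                         mlp_forward(model$extractor, X)$out)$out)
}

# d F / d x for a batch of inputs, F = sigmoid predictor prob, eval mode.
input_gradient <- function(model, X) {
  fm <- mlp_forward(model$extractor, X)
  fp <- mlp_forward(model$predictor, fm$out)
  p <- as.numeric(fp$out)
  gp <- mlp_backward(model$predictor, fp$caches, matrix(p * (1 - p)))
  mlp_backward(model$extractor, fm$caches, gp$dX)$dX
}

#' Average attributions over cells and cross-validation folds
#'
#' @param per_fold List of cells x genes attribution matrices (one per fold,
#'   identical gene columns).
#' @return Named per-gene mean attribution vector (cells averaged within each
#'   fold first, then folds averaged, so folds weigh equally).
#' @export
mean_attribution <- function(per_fold) {
  stopifnot(length(per_fold) >= 1)
  fold_means <- lapply(per_fold, colMeans)
  Reduce(`+`, fold_means) / length(fold_means)
}

#' Attribution tail genes
#'
#' Genes whose mean attribution lies below the `q` quantile or above the
#' `1 - q` quantile — the candidates most influential for the prediction in
#' either direction.
#'
#' @param mean_attr Named per-gene attribution vector.
#' @param q Tail fraction per side (default 0.05).
#' @return Character vector of gene ids.
#' @export
tail_genes <- function(mean_attr, q = 0.05) {
  stopifnot(q > 0, q <= 0.5, !is.null(names(mean_attr)))
  cuts <- stats::quantile(mean_attr, c(q, 1 - q), names = FALSE)
  names(mean_attr)[mean_attr < cuts[1] | mean_attr > cuts[2]]
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene with Benjamini-Hochberg
#' adjustment; direction is the sign of the group-mean difference (a - b).
#' Genes constant across both groups get p = 1 and are flagged.
#'
#' @param expr Cells x genes expression matrix.
#' @param group_a,group_b Disjoint cell-id (or index) sets, each of size
#'   >= 2. Group a is conventionally the predicted-sensitive group.
#' @param gene_subset Optional gene ids restricting the test (e.g.
#'   [tail_genes()] output).
#' @return data.frame with `gene`, `direction` (+1 up in a, -1 up in b, 0
#'   tie), `statistic`, `p_value`, `p_adjusted`, `constant`.
#' @export
rank_genes_de <- function(expr, group_a, group_b, gene_subset = NULL) {
  if (is.character(group_a)) group_a <- match(group_a, rownames(expr))
  if (is.character(group_b)) group_b <- match(group_b, rownames(expr))
  if (anyNA(group_a) || anyNA(group_b)) stopf("unknown cell id in group")
  if (length(intersect(group_a, group_b))) stopf("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stopf("each group needs at least 2 cells")
  }
  genes <- if (is.null(gene_subset)) colnames(expr) else
    intersect(colnames(expr), gene_subset)
  if (!length(genes)) stopf("no genes to test")
  res <- lapply(genes, function(gn) {
    va <- expr[group_a, gn]
    vb <- expr[group_b, gn]
    if (length(unique(c(va, vb))) == 1L) {
      return(data.frame(gene = gn, direction = 0, statistic = NA_real_,
                        p_value = 1, constant = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE,
                                              correct = TRUE))
    data.frame(gene = gn, direction = sign(mean(va) - mean(vb)),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               constant = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), c("gene", "direction", "statistic", "p_value",
                            "p_adjusted", "constant")]
}

#' Split a DE table into sensitivity / resistance biomarker sets
#'
#' `sc_sens` holds significant genes over-expressed in the predicted-sensitive
#' group (direction +1), `sc_res` those over-expressed in the
#' predicted-resistant group (direction -1); the sets are disjoint by
#' construction.
#'
#' @param de_table Output of [rank_genes_de()].
#' @param alpha Significance threshold on the BH-adjusted p (default 0.05;
#'   `alpha = 1` partitions all tested genes by direction).
#' @return List with character vectors `sc_sens` and `sc_res`.
#' @export
biomarker_sets <- function(de_table, alpha = 0.05) {
  sig <- de_table$p_adjusted <= alpha
  list(sc_sens = de_table$gene[sig & de_table$direction > 0],
       sc_res = de_table$gene[sig & de_table$direction < 0])
}

#' Per-gene prognostic AUC for a binary outcome
#'
#' For each gene, the AUC of its expression as a ranking score for the
#' outcome, reported oriented so values >= 0.5 (higher expression in
#' outcome-positive samples gives direction `"positive"`, the reverse
#' `"negative"`).
#'
#' @param expr Samples x genes cohort expression matrix.
#' @param outcome Binary 0/1 outcome per sample.
#' @param genes Gene ids to evaluate (default all; ids missing from the
#'   cohort are dropped with a warning).
#' @return data.frame with `gene`, `auc` (oriented, >= 0.5), `raw_auc`,
#'   `direction`.
#' @export
single_gene_auc <- function(expr, outcome, genes = colnames(expr)) {
  missing <- setdiff(genes, colnames(expr))
  if (length(missing)) {
    warning(sprintf("%d gene(s) absent from the cohort, dropped", length(missing)))
  }
  genes <- intersect(genes, colnames(expr))
  raw <- vapply(genes, function(gn) auc(outcome, expr[, gn]), numeric(1))
  data.frame(gene = genes,
             auc = pmax(raw, 1 - raw),
             raw_auc = raw,
             direction = ifelse(raw >= 0.5, "positive", "negative"),
             row.names = NULL)
}

#' Compare two gene sets' prognostic AUC distributions
#'
#' @param aucs_a,aucs_b Numeric AUC vectors (e.g. the `auc` column of
#'   [single_gene_auc()] for each biomarker set).
#' @return List with `median_a`, `median_b` and the two-sided Wilcoxon
#'   rank-sum `p_value`.
#' @export
gene_set_auc_compare <- function(aucs_a, aucs_b) {
  wt <- suppressWarnings(stats::wilcox.test(aucs_a, aucs_b,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(median_a = stats::median(aucs_a), median_b = stats::median(aucs_b),
       p_value = wt$p.value)
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Exact two-sided p by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's. The odds ratio is
#' the sample estimate `a*d / (b*c)` (`Inf` when `b*c = 0` with `a*d > 0`;
#' `NA` when both products are 0).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row: conventionally rows = lineage
#'   (solid, hematopoietic), columns = (sensitive, resistant).
#' @return List with `odds_ratio`, `p_value` and the table.
#' @export
#' @examples
#' # sensitive/resistant counts of solid vs hematopoietic cell lines
#' fisher_exact(c(19, 661, 41, 113))$p_value
fisher_exact <- function(tab) {
  if (is.null(dim(tab))) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2)) stopf("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stopf("counts must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n2 <- c_ + d        # row 2 total
  k <- a + c_         # column 1 total
  if (m + n2 == 0) stopf("empty table")
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NA_real_
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Sensitive fraction of one lineage row of a contingency table
#'
#' @param tab As in [fisher_exact()]; columns (sensitive, resistant).
#' @param row `1` (solid) or `2` (hematopoietic).
#' @return Percentage of sensitive samples in that row.
#' @export
#' @examples
#' sensitive_fraction(c(19, 661, 41, 113), row = 1)  # 2.79
sensitive_fraction <- function(tab, row = 1L) {
  if (is.null(dim(tab))) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(row %in% c(1L, 2L))
  total <- tab[row, 1] + tab[row, 2]
  if (total == 0) return(0)
  100 * tab[row, 1] / total
}

#' Attribution-based biomarker discovery across cross-validation folds
#'
#' Convenience wrapper for the full interpretation chain: per-fold
#' integrated-gradients attribution on held-out target cells, fold-averaged
#' mean attribution, tail-gene selection, differential expression between
#' predicted groups, and biomarker set calling.
#'
#' @param models List of fitted [adda()] models (one per fold).
#' @param fold_cells List of cells x genes matrices (the held-out target
#'   cells of each fold, same gene columns as the models).
#' @param expr Cells x genes matrix used for differential expression
#'   (typically all target cells).
#' @param group_mode `"median"` (binarise pooled predictions at their median)
#'   or `"quantile"` (compare the top and bottom strata of
#'   [stratify_quantiles()]).
#' @param steps,tail_q,alpha Tuning parameters of the stages.
#' @return List with `mean_attribution`, `tail_genes`, `de_table`,
#'   `biomarkers` and the per-cell `groups`.
#' @export
discover_biomarkers <- function(models, fold_cells, expr,
                                group_mode = c("median", "quantile"),
                                steps = 50L, tail_q = 0.05, alpha = 0.05) {
  group_mode <- match.arg(group_mode)
  stopifnot(length(models) == length(fold_cells))
  attr_folds <- mapply(function(m, x) integrated_gradients(m, x, steps = steps),
                       models, fold_cells, SIMPLIFY = FALSE)
  m_attr <- mean_attribution(attr_folds)
  tails <- tail_genes(m_attr, q = tail_q)
  scores <- predict(models[[1L]], expr)
  if (group_mode == "median") {
    calls <- binarize_median(scores)
    ga <- rownames(expr)[calls == "sensitive"]
    gb <- rownames(expr)[calls == "resistant"]
  } else {
    strata <- stratify_quantiles(scores)
    ga <- rownames(expr)[strata == "rank_Sens"]
    gb <- rownames(expr)[strata == "rank_Res"]
  }
  de <- rank_genes_de(expr, ga, gb, gene_subset = tails)
  list(mean_attribution = m_attr, tail_genes = tails, de_table = de,
       biomarkers = biomarker_sets(de, alpha = alpha),
       groups = list(sensitive = ga, resistant = gb))
}
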