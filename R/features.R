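# Feature selection (highly variable genes, gene panels) and class
# rebalancing (inverse-frequency weights, SMOTE).

#' Select highly variable genes by bin-normalised dispersion
#'
#' The classic single-cell HVG recipe: on the de-logged expression values,
#' compute each gene's mean and dispersion (variance / mean), cut genes into
#' `n_bins` equal-width bins of mean expression, z-normalise dispersion within
#' each bin, and keep the `n_top` genes with the highest normalised dispersion.
#' Ties are broken lexicographically by gene id, so the result is deterministic
#' and invariant to column permutation.
#'
#' @param target_log A `"log_normalized"`-layer expression matrix (dispersion
#'   is computed on the pre-z-score layer).
#' @param n_top Number of genes to keep (default 4000, the "tp4k" panel).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of selected gene ids (a gene panel).
#' @export
select_hvg <- function(target_log, n_top = 4000L, n_bins = 20L) {
  stopifnot(n_top >= 1, n_bins >= 1)
  if (expr_layer(target_log) != "log_normalized") {
    stopf("select_hvg expects log-normalized values, got layer '%s'",
          expr_layer(target_log))
  }
  x <- expm1(unclass(target_log))
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = n_bins, include.lowest = TRUE)
  norm_disp <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (!length(idx)) next
    m <- mean(disp[idx])
    s <- stats::sd(disp[idx])
    norm_disp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  if (n_top > ncol(target_log)) {
    warning(sprintf("n_top (%d) exceeds gene count (%d); returning all genes",
                    n_top, ncol(target_log)))
    n_top <- ncol(target_log)
  }
  ord <- order(-norm_disp, colnames(target_log))
  sort(colnames(target_log)[ord[seq_len(n_top)]])
}

#' Restrict an expression matrix to a gene panel
#'
#' @param m Expression matrix.
#' @param panel Character vector of gene ids (e.g. from [read_gene_panel()] or
#'   [select_hvg()]).
#' @return The matrix restricted to `panel` genes present in `m`, columns in
#'   lexicographic order; the count of panel genes missing from `m` is attached
#'   as attribute `"n_missing"`.
#' @export
apply_panel <- function(m, panel) {
  shared <- sort(intersect(colnames(m), panel))
  if (!length(shared)) stopf("gene panel has no overlap with the matrix")
  out <- keep_genes(m, shared)
  attr(out, "n_missing") <- length(setdiff(panel, colnames(m)))
  out
}

#' Inverse-class-frequency sample weights
#'
#' Weight of each sample is proportional to 1 / (size of its class), normalised
#' to sum to one, so sampling with replacement under these weights draws each
#' class with probability 1/2 in expectation.
#'
#' @param y Binary 0/1 label vector (both classes must be present).
#' @return Numeric weight vector summing to 1.
#' @export
balanced_sample_weights <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stopf("labels must be 0/1")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stopf("both classes must be present to rebalance")
  w <- 1 / as.numeric(counts[as.character(y)])
  w / sum(w)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority samples are drawn on segments between a minority sample
#' and one of its `k` nearest minority neighbours (Euclidean):
#' `x_new = x_i + u * (x_nn - x_i)`, `u ~ Uniform(0, 1)`. Original rows are
#' never modified; enough synthetic rows are added to balance the classes
#' exactly.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Binary 0/1 labels, minority class of size >= 2.
#' @param k Number of nearest neighbours (default 5); reduced to
#'   `minority size - 1` when the minority class is small.
#' @param seed Integer seed making the synthesis deterministic.
#' @return A list with `X` (original rows first, synthetic rows appended,
#'   rownames `smote_1`, ...) and `y`.
#' @export
smote_oversample <- function(X, y, k = 5L, seed = 1L) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stopf("labels must be 0/1")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stopf("both classes must be present")
  minority <- as.numeric(names(counts)[which.min(counts)])
  n_syn <- max(counts) - min(counts)
  if (n_syn == 0) return(list(X = X, y = y))
  idx_min <- which(y == minority)
  if (length(idx_min) < 2) {
    stopf("minority class has %d sample(s); SMOTE needs at least 2",
          length(idx_min))
  }
  Xm <- X[idx_min, , drop = FALSE]
  k <- min(k, nrow(Xm) - 1L)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  syn <- with_seed(seed, {
    base_i <- sample.int(nrow(Xm), n_syn, replace = TRUE)
    nbr_j <- nn[cbind(base_i, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    Xm[base_i, , drop = FALSE] +
      u * (Xm[nbr_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  rownames(syn) <- paste0("smote_", seq_len(n_syn))
  list(X = rbind(X, syn), y = c(y, rep(minority, n_syn)))
}
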