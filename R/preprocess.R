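# Single-cell quality control, normalisation, log transform and z-scoring.
#
# The bulk (source) pathway is assumed to arrive already array/RMA-normalised,
# so only zscore_genes() applies there; the single-cell (target) pathway is
# qc_filter() -> normalize_total() -> log1p_transform() -> zscore_genes().

#' Quality-control configuration
#'
#' Thresholds follow common single-cell practice: `min_*` keep cells/genes with
#' value >= threshold, `max_counts` keeps cells with total counts <= threshold.
#' The mitochondrial fraction of a cell is the count share of genes whose id
#' starts with `mito_prefix`; cells above `mito_fraction_max` are removed.
#'
#' @param min_genes_per_cell Minimum expressed genes per cell.
#' @param min_counts_per_cell Minimum total counts per cell.
#' @param max_counts_per_cell Maximum total counts per cell (`Inf` = none).
#' @param min_cells_per_gene Minimum cells in which a gene must be expressed.
#' @param mito_fraction_max Maximum mitochondrial count fraction (default 0.20).
#' @param mito_prefix Gene-id prefix marking mitochondrial genes (default "MT-").
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes_per_cell = 0L,
                      min_counts_per_cell = 0L,
                      max_counts_per_cell = Inf,
                      min_cells_per_gene = 0L,
                      mito_fraction_max = 0.20,
                      mito_prefix = "MT-") {
  stopifnot(min_genes_per_cell >= 0, min_counts_per_cell >= 0,
            min_cells_per_gene >= 0, max_counts_per_cell >= 0,
            mito_fraction_max >= 0, mito_fraction_max <= 1)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_counts_per_cell = min_counts_per_cell,
                 max_counts_per_cell = max_counts_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_fraction_max = mito_fraction_max,
                 mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Quality-control filter for raw single-cell counts
#'
#' Cell filters are applied first (expressed genes, total counts, mitochondrial
#' fraction), then genes expressed in fewer than `min_cells_per_gene` of the
#' remaining cells are removed.
#'
#' @param raw Raw-count [expr_matrix()] (cells x genes).
#' @param cfg A [qc_config()].
#' @return A list with `matrix` (filtered raw counts) and `log`, a data.frame
#'   counting removals per criterion.
#' @export
qc_filter <- function(raw, cfg = qc_config()) {
  if (expr_layer(raw) != "raw_counts") {
    stopf("qc_filter expects raw counts, got layer '%s'", expr_layer(raw))
  }
  totals <- rowSums(raw)
  n_genes <- rowSums(raw > 0)
  mito <- startsWith(colnames(raw), cfg$mito_prefix)
  mito_frac <- if (any(mito)) rowSums(raw[, mito, drop = FALSE]) / pmax(totals, 1) else
    rep(0, nrow(raw))

  fail_genes <- n_genes < cfg$min_genes_per_cell
  fail_min_counts <- totals < cfg$min_counts_per_cell
  fail_max_counts <- totals > cfg$max_counts_per_cell
  fail_mito <- mito_frac > cfg$mito_fraction_max
  keep_cell <- !(fail_genes | fail_min_counts | fail_max_counts | fail_mito)
  if (!any(keep_cell)) stopf("empty after QC: all %d cells removed", nrow(raw))

  filtered <- keep_samples(raw, which(keep_cell))
  cells_per_gene <- colSums(filtered > 0)
  keep_gene <- cells_per_gene >= cfg$min_cells_per_gene
  if (!any(keep_gene)) stopf("empty after QC: all genes removed")
  filtered <- keep_genes(filtered, which(keep_gene))

  log <- data.frame(
    criterion = c("min_genes_per_cell", "min_counts_per_cell",
                  "max_counts_per_cell", "mito_fraction_max",
                  "cells_removed_total", "min_cells_per_gene"),
    removed = c(sum(fail_genes), sum(fail_min_counts), sum(fail_max_counts),
                sum(fail_mito), sum(!keep_cell), sum(!keep_gene))
  )
  list(matrix = filtered, log = log)
}

#' Library-size normalisation
#'
#' Scales each cell so its total count equals `target_sum` (1e6 gives counts
#' per million, 1e4 the common single-cell default).
#'
#' @param raw Raw-count [expr_matrix()].
#' @param target_sum Positive target row total.
#' @return A `"normalized"`-layer expression matrix.
#' @export
normalize_total <- function(raw, target_sum = 1e4) {
  if (expr_layer(raw) != "raw_counts") {
    stopf("normalize_total expects raw counts, got layer '%s'", expr_layer(raw))
  }
  stopifnot(target_sum > 0)
  totals <- rowSums(raw)
  if (any(totals == 0)) {
    stopf("cell '%s' has zero total count; remove it in QC first",
          rownames(raw)[which(totals == 0)[1]])
  }
  expr_matrix(raw * (target_sum / totals), layer = "normalized")
}

#' Natural-log transform, log(1 + x)
#'
#' @param m A `"normalized"`-layer expression matrix (values >= 0).
#' @return A `"log_normalized"`-layer expression matrix.
#' @export
log1p_transform <- function(m) {
  if (any(m < 0)) stopf("log1p_transform requires non-negative values")
  out <- log1p(m)
  dimnames(out) <- dimnames(m)
  expr_matrix(out, layer = "log_normalized")
}

#' Per-gene z-score standardisation
#'
#' Centers and scales each gene to mean 0, standard deviation 1, using the
#' population standard deviation (divide by n), matching the usual
#' machine-learning scaler convention. Zero-variance genes map to all zeros so
#' the gene space stays aligned across domains.
#'
#' @param m Expression matrix with at least two samples.
#' @return A `"zscored"`-layer expression matrix.
#' @export
zscore_genes <- function(m) {
  if (nrow(m) < 2) stopf("z-scoring needs at least 2 samples")
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  centered <- sweep(unclass(m), 2, mu)
  out <- sweep(centered, 2, ifelse(sdev > 0, sdev, 1), "/")
  out[, sdev == 0] <- 0
  dimnames(out) <- dimnames(m)
  expr_matrix(out, layer = "zscored")
}

#' Full single-cell preprocessing chain
#'
#' Convenience wrapper: QC -> library-size normalisation -> log1p -> z-score.
#'
#' @param raw Raw-count cells x genes matrix.
#' @param cfg A [qc_config()].
#' @param target_sum Library-size normalisation target.
#' @return A list with `matrix` (z-scored) and `qc_log`.
#' @export
preprocess_target <- function(raw, cfg = qc_config(), target_sum = 1e4) {
  qc <- qc_filter(raw, cfg)
  z <- zscore_genes(log1p_transform(normalize_total(qc$matrix, target_sum)))
  list(matrix = z, qc_log = qc$log)
}
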