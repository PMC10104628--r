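# Ranking metrics (AUROC, AUPR) and the cross-validation metrics report.

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney formulation: the probability that a randomly
#' chosen positive scores higher than a randomly chosen negative, with tied
#' scores contributing 1/2.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) convention: the sum over descending score
#' thresholds of the recall increment times the precision at that threshold.
#' For random scores the expected value approaches the positive-class rate.
#'
#' @inheritParams auc
#' @return AUPR in `(0, 1]`, or `NA` if no positives are present.
#' @export
aupr <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels[called] == 1)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Assemble a cross-validation metrics report
#'
#' @param cells data.frame with columns `fold`, `seed`, `auc`, `aupr`.
#' @param config List snapshot of the configuration that produced the cells.
#' @return A `metrics_report` object; its summary holds the mean and SD of
#'   each metric over all defined (fold, seed) cells.
#' @export
metrics_report <- function(cells, config = list()) {
  stopifnot(all(c("fold", "seed", "auc", "aupr") %in% names(cells)))
  ok_auc <- is.na(cells$auc) | (cells$auc >= 0 & cells$auc <= 1)
  ok_aupr <- is.na(cells$aupr) | (cells$aupr >= 0 & cells$aupr <= 1)
  stopifnot(all(ok_auc), all(ok_aupr))
  structure(list(
    cells = cells,
    summary = data.frame(
      metric = c("auc", "aupr"),
      mean = c(mean(cells$auc, na.rm = TRUE), mean(cells$aupr, na.rm = TRUE)),
      sd = c(stats::sd(cells$auc[!is.na(cells$auc)]),
             stats::sd(cells$aupr[!is.na(cells$aupr)])),
      n_cells = c(sum(!is.na(cells$auc)), sum(!is.na(cells$aupr)))
    ),
    config = config
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Cross-validation metrics over %d (fold x seed) cells\n",
              nrow(x$cells)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  mean %-4s %.3f (SD %.3f, n = %d)\n",
                toupper(s$metric[i]), s$mean[i], s$sd[i], s$n_cells[i]))
  }
  n_miss <- sum(is.na(x$cells$auc))
  if (n_miss > 0) {
    cat(sprintf("  %d cell(s) undefined (single-class held-out fold), excluded\n",
                n_miss))
  }
  invisible(x)
}

#' Write / read a metrics report
#'
#' The report is written twice: a JSON file carrying the per-cell values,
#' summary and configuration, and a plain TSV of the per-cell table.
#'
#' @param report A [metrics_report()].
#' @param path Base output path; `.json` and `.tsv` are appended.
#' @return The JSON path (write) or the restored report (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  json_path <- paste0(path, ".json")
  jsonlite::write_json(list(cells = report$cells, summary = report$summary,
                            config = report$config),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$cells, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cells <- as.data.frame(obj$cells)
  for (col in c("auc", "aupr")) {
    cells[[col]] <- as.numeric(cells[[col]])
  }
  metrics_report(cells, as.list(obj$config))
}
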