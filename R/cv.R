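# Cross-validated training and evaluation, and hyperparameter grid search.
#
# Protocol: for each random seed, both domains are split into k folds
# (coupled by iteration). Each iteration trains on 4/5 of the source
# (labelled) plus 4/5 of the target (unlabelled), uses the held-out source
# fold as the validation set for hyperparameter selection, and measures
# AUROC/AUPR on the held-out target fold, whose labels are touched only at
# this final evaluation step. k folds x s seeds yields k*s metric cells
# (25 under the defaults).

#' Build k-fold cross-validation splits
#'
#' @param n Number of samples.
#' @param k Number of folds (`n >= k`).
#' @param labels Optional 0/1 labels; when given, folds are stratified so
#'   class proportions stay within one sample of the global ratio.
#' @param seed Integer seed; splits are deterministic under it.
#' @return List of `k` elements, each `list(train = , heldout = )`, the
#'   held-out index sets forming a disjoint partition of `1:n`.
#' @export
make_cv_splits <- function(n, k, labels = NULL, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  fold_of <- integer(n)
  with_seed(seed, {
    if (is.null(labels)) {
      fold_of <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      stopifnot(length(labels) == n)
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold_of[idx[sample.int(length(idx))]] <-
          rep_len(sample.int(k), length(idx))
      }
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), heldout = which(fold_of == f))
  })
}

#' Cross-validated adversarial transfer with repeated seeds
#'
#' Trains one model per (fold, seed) cell and evaluates it on the held-out
#' target fold. Target labels are used exclusively on held-out folds at
#' evaluation time; a held-out fold containing a single label class yields an
#' undefined AUC, which is recorded as `NA` and excluded from the aggregate
#' mean.
#'
#' @param x_source,y_source Labelled source expression and 0/1 labels.
#' @param x_target Target expression matrix (same gene columns).
#' @param y_target Target labels (0/1, `NA` = unknown), used only for
#'   held-out evaluation.
#' @param cv_folds Number of folds (default 5).
#' @param n_seeds Number of repeated random seeds (default 5).
#' @param seed Master seed; it spawns one independent sub-seed per repetition
#'   (controlling splits, initialisation, sampling and SMOTE).
#' @param return_models Keep the fitted model of every cell (memory-heavy;
#'   default `FALSE`).
#' @param ... Model/training arguments forwarded to [adda()] (`h_dim`,
#'   `z_dim`, `lambda`, `epochs`, `sampling`, ...).
#' @return A [metrics_report()]; when `return_models = TRUE`, the fitted
#'   models are attached as attribute `"models"`.
#' @export
cross_validate <- function(x_source, y_source, x_target, y_target,
                           cv_folds = 5L, n_seeds = 5L, seed = 1L,
                           return_models = FALSE, ...) {
  x_source <- as.matrix(x_source)
  x_target <- as.matrix(x_target)
  if (inherits(y_source, "response_labels")) {
    y_source <- align_labels(x_source, y_source)
  }
  if (inherits(y_target, "response_labels")) {
    y_target <- align_labels(x_target, y_target, require_known = FALSE)
  }
  y_target <- as.numeric(y_target)
  rep_seeds <- spawn_seeds(seed, n_seeds)
  cells <- expand.grid(fold = seq_len(cv_folds), seed = seq_len(n_seeds))
  cells$auc <- cells$aupr <- NA_real_
  models <- if (return_models) vector("list", nrow(cells))

  for (s in seq_len(n_seeds)) {
    sub <- spawn_seeds(rep_seeds[s], 2L + cv_folds)
    src_splits <- make_cv_splits(nrow(x_source), cv_folds,
                                 labels = y_source, seed = sub[1L])
    # target folds are split blind to labels: labels must not shape training
    tgt_splits <- make_cv_splits(nrow(x_target), cv_folds, seed = sub[2L])
    for (f in seq_len(cv_folds)) {
      fit <- adda(x_source[src_splits[[f]]$train, , drop = FALSE],
                  y_source[src_splits[[f]]$train],
                  x_target[tgt_splits[[f]]$train, , drop = FALSE],
                  validation = list(
                    x = x_source[src_splits[[f]]$heldout, , drop = FALSE],
                    y = y_source[src_splits[[f]]$heldout]),
                  seed = sub[2L + f], ...)
      held <- tgt_splits[[f]]$heldout
      yt <- y_target[held]
      known <- !is.na(yt)
      row <- which(cells$fold == f & cells$seed == s)
      if (sum(known) > 0 && length(unique(yt[known])) == 2) {
        scores <- predict(fit, x_target[held[known], , drop = FALSE])
        cells$auc[row] <- auc(yt[known], scores)
        cells$aupr[row] <- aupr(yt[known], scores)
      }
      if (return_models) models[[row]] <- fit
    }
  }
  report <- metrics_report(cells, config = c(list(cv_folds = cv_folds,
                                                  n_seeds = n_seeds,
                                                  seed = seed), list(...)))
  if (return_models) attr(report, "models") <- models
  report
}

#' Hyperparameter grid search on source-domain validation AUC
#'
#' Each candidate configuration is scored by the mean held-out source-fold
#' AUC across `cv_folds` training runs; target labels are never consulted.
#' Ties are broken in favour of the smaller model (`h_dim`, then `z_dim`).
#'
#' @param x_source,y_source Labelled source data.
#' @param x_target Unlabelled target matrix.
#' @param grid data.frame of candidate configurations; recognised columns are
#'   `h_dim`, `z_dim`, `lambda`, `learning_rate`, `batch_size` (missing
#'   columns fall back to the [adda()] defaults).
#' @param cv_folds Folds for the validation estimate (default 5).
#' @param seed Master seed.
#' @param ... Fixed arguments forwarded to every [adda()] call.
#' @return List with `best` (the winning configuration as a list) and
#'   `results` (the grid with a `val_auc` column).
#' @export
grid_search <- function(x_source, y_source, x_target, grid,
                        cv_folds = 5L, seed = 1L, ...) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1)
  x_source <- as.matrix(x_source)
  if (inherits(y_source, "response_labels")) {
    y_source <- align_labels(x_source, y_source)
  }
  sub <- spawn_seeds(seed, 1L + cv_folds)
  splits <- make_cv_splits(nrow(x_source), cv_folds, labels = y_source,
                           seed = sub[1L])
  fixed <- list(...)
  grid$val_auc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    cfg <- as.list(grid[gi, setdiff(names(grid), "val_auc"), drop = FALSE])
    fold_auc <- vapply(seq_len(cv_folds), function(f) {
      args <- c(list(x_source = x_source[splits[[f]]$train, , drop = FALSE],
                     y_source = y_source[splits[[f]]$train],
                     x_target = x_target,
                     seed = sub[1L + f]),
                cfg, fixed)
      fit <- do.call(adda, args)
      val_x <- x_source[splits[[f]]$heldout, , drop = FALSE]
      auc(y_source[splits[[f]]$heldout], predict(fit, val_x))
    }, numeric(1))
    grid$val_auc[gi] <- mean(fold_auc, na.rm = TRUE)
  }
  ord <- order(-grid$val_auc,
               if (!is.null(grid$h_dim)) grid$h_dim else seq_len(nrow(grid)),
               if (!is.null(grid$z_dim)) grid$z_dim else seq_len(nrow(grid)))
  best <- as.list(grid[ord[1L], setdiff(names(grid), "val_auc"), drop = FALSE])
  list(best = best, results = grid)
}
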