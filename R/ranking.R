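# Cell-level drug-resistance ranking: raw predictor scores, min-max scaling,
# median binarisation, percentile stratification, and cross-drug overlap of
# rank strata (the exploratory drug-combination view).

#' Score target cells with a fitted model
#'
#' Evaluation-mode predictor probabilities (deterministic); higher scores mean
#' predicted more drug-sensitive.
#'
#' @param model An [adda()] fit.
#' @param x_target Cells x genes matrix in the model's gene space.
#' @return Named numeric score vector.
#' @export
score_cells <- function(model, x_target) {
  predict(model, x_target, type = "response")
}

#' Min-max scale scores to the unit interval
#'
#' Constant input is mapped to 0.5 everywhere so downstream consumers never
#' see NaN.
#'
#' @param scores Numeric vector.
#' @return Scaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(scores) {
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Binarise scores at their median
#'
#' Scores strictly above the median are called `"sensitive"`, scores at or
#' below it `"resistant"` (ties side with resistant).
#'
#' @param scores Numeric vector.
#' @return Character vector of calls.
#' @export
binarize_median <- function(scores) {
  ifelse(scores > stats::median(scores), "sensitive", "resistant")
}

#' Stratify cells by score percentiles
#'
#' Cells above the `high_q` empirical quantile form the `rank_Sens` stratum
#' (putatively most sensitive), cells below the `low_q` quantile form
#' `rank_Res`; the rest are `neutral`. Quantiles use the linear-interpolation
#' convention; ties exactly at a boundary go to `neutral`. Strata are
#' invariant under any strictly increasing transform of the scores.
#'
#' @param scores Numeric vector.
#' @param low_q,high_q Quantile cutoffs (defaults 0.10 / 0.90; 0.15 / 0.85
#'   gives the relaxed view).
#' @return Factor with levels `rank_Res`, `neutral`, `rank_Sens`.
#' @export
stratify_quantiles <- function(scores, low_q = 0.10, high_q = 0.90) {
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  qs <- stats::quantile(scores, c(low_q, high_q), names = FALSE)
  out <- rep("neutral", length(scores))
  out[scores < qs[1]] <- "rank_Res"
  out[scores > qs[2]] <- "rank_Sens"
  factor(out, levels = c("rank_Res", "neutral", "rank_Sens"))
}

#' Build the full per-cell ranking table
#'
#' @param model An [adda()] fit.
#' @param x_target Cells x genes matrix.
#' @param low_q,high_q Stratification quantiles.
#' @return A `cell_ranking` data.frame with columns `cell_id`, `raw_score`,
#'   `scaled_score`, `binary_call`, `stratum`, sorted by decreasing score.
#' @export
rank_cells <- function(model, x_target, low_q = 0.10, high_q = 0.90) {
  s <- score_cells(model, x_target)
  out <- data.frame(cell_id = names(s) %||% as.character(seq_along(s)),
                    raw_score = as.numeric(s),
                    scaled_score = minmax_scale(s),
                    binary_call = binarize_median(s),
                    stratum = stratify_quantiles(s, low_q, high_q),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_score), ]
  rownames(out) <- NULL
  class(out) <- c("cell_ranking", "data.frame")
  out
}

#' Cross-drug overlap of rank strata
#'
#' Contingency of the two drugs' strata over the same cells, plus the Jaccard
#' index of (drug A resistant stratum, drug B sensitive stratum) — the
#' pattern where cells resistant to one drug are predicted sensitive to
#' another. The `combination_candidate` flag is exploratory only, not an
#' inferential claim of synergy.
#'
#' @param ranking_a,ranking_b `cell_ranking` tables over identical cells.
#' @param jaccard_threshold Flag threshold (default 0.5).
#' @return List with `table` (3x3 contingency), `jaccard_res_a_sens_b` and
#'   `combination_candidate`.
#' @export
cross_drug_overlap <- function(ranking_a, ranking_b, jaccard_threshold = 0.5) {
  if (!setequal(ranking_a$cell_id, ranking_b$cell_id)) {
    stopf("the two rankings cover different cells")
  }
  b_idx <- match(ranking_a$cell_id, ranking_b$cell_id)
  sa <- ranking_a$stratum
  sb <- ranking_b$stratum[b_idx]
  tab <- table(drug_a = sa, drug_b = sb)
  res_a <- ranking_a$cell_id[sa == "rank_Res"]
  sens_b <- ranking_b$cell_id[ranking_b$stratum == "rank_Sens"]
  jac <- if (length(res_a) == 0 && length(sens_b) == 0) 0 else
    length(intersect(res_a, sens_b)) / length(union(res_a, sens_b))
  list(table = tab,
       jaccard_res_a_sens_b = jac,
       combination_candidate = jac > jaccard_threshold)
}
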