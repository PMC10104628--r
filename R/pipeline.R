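# Run configuration and the staged pipeline entry point.
#
# The configuration is a nested YAML file; unknown keys are rejected rather
# than silently ignored, so misspelt options fail loudly. Every run writes
# the fully resolved configuration and master seed next to its artifacts.

CONFIG_SCHEMA <- list(
  seed = NULL,
  out_dir = NULL,
  paths = c("source_expr", "source_labels", "target_expr", "target_mtx_dir",
            "target_labels", "gene_panel", "checkpoint"),
  sim = c("n_genes", "n_signal_genes", "n_source", "n_target",
          "source_sensitive_frac", "target_sensitive_frac", "effect_size",
          "shift_magnitude", "dropout_rate", "library_size_mean",
          "library_size_dispersion", "n_mito_genes", "mito_count_share"),
  qc = c("min_genes_per_cell", "min_counts_per_cell", "max_counts_per_cell",
         "min_cells_per_gene", "mito_fraction_max", "mito_prefix"),
  preprocess = c("target_sum"),
  features = c("feature_mode", "n_top", "n_bins"),
  model = c("h_dim", "z_dim", "lambda", "dropout", "epochs", "batch_size",
            "learning_rate", "sampling", "smote_k", "adv_mode",
            "adv_batch_mult", "d_dim", "d_dropout", "d_lr_mult"),
  evaluate = c("cv_folds", "n_seeds"),
  rank = c("low_q", "high_q"),
  attribute = c("steps", "tail_q", "alpha", "group_mode"),
  fisher = c("table")
)

#' Load and validate a pipeline run configuration
#'
#' @param path YAML file, or a named list given directly.
#' @return Validated `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stopf("configuration must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown)) stopf("unknown config key '%s'", unknown[[1]])
  for (sec in intersect(names(cfg), names(CONFIG_SCHEMA))) {
    allowed <- CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad)) stopf("unknown config key '%s.%s'", sec, bad[[1]])
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

load_domains <- function(cfg) {
  p <- cfg$paths %||% list()
  src <- read_expression_matrix(p$source_expr, layer = "normalized")
  y_src <- read_labels(p$source_labels)
  tgt <- if (!is.null(p$target_mtx_dir)) {
    read_mtx_triplet(p$target_mtx_dir)
  } else {
    read_expression_matrix(p$target_expr, layer = "raw_counts")
  }
  y_tgt <- if (!is.null(p$target_labels)) read_labels(p$target_labels)
  list(source = src, y_source = y_src, target = tgt, y_target = y_tgt)
}

prepare_domains <- function(cfg, dom) {
  qc <- do.call(qc_config, cfg$qc %||% list())
  target_sum <- (cfg$preprocess %||% list())$target_sum %||% 1e4
  qcres <- qc_filter(dom$target, qc)
  tgt_log <- log1p_transform(normalize_total(qcres$matrix, target_sum))
  feat <- cfg$features %||% list()
  mode <- feat$feature_mode %||% "all"
  if (mode == "tp4k") {
    panel <- select_hvg(tgt_log, n_top = feat$n_top %||% 4000L,
                        n_bins = feat$n_bins %||% 20L)
    tgt_log <- apply_panel(tgt_log, panel)
  } else if (mode == "ppi") {
    panel <- read_gene_panel(cfg$paths$gene_panel)
    tgt_log <- apply_panel(tgt_log, panel)
  } else if (mode != "all") {
    stopf("unknown feature_mode '%s'", mode)
  }
  tgt_z <- zscore_genes(tgt_log)
  src_z <- zscore_genes(dom$source)
  shared <- intersect_genes(src_z, tgt_z)
  list(source = shared$source, target = shared$target,
       y_source = align_labels(shared$source, dom$y_source),
       y_target = if (!is.null(dom$y_target)) {
         align_labels(shared$target, dom$y_target, require_known = FALSE)
       },
       qc_log = qcres$log, n_shared = shared$n_shared)
}

model_args <- function(cfg) {
  m <- cfg$model %||% list()
  names(m)[names(m) == "lambda"] <- "lambda"
  m
}

#' Run one stage of the transfer pipeline
#'
#' Commands: `"simulate"` writes a synthetic paired study in the formats the
#' readers consume; `"train"` preprocesses both domains, fits the model and
#' saves a checkpoint; `"evaluate"` runs the cross-validated protocol and
#' writes the metrics report; `"rank"` scores and stratifies target cells;
#' `"attribute"` computes integrated-gradients attributions and biomarker
#' sets; `"fisher"` tests a lineage contingency table.
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @param command One of the stage names above.
#' @param out_dir Output directory (defaults to the config's `out_dir`).
#' @return The stage's main artifact, invisibly; files are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "train", "evaluate", "rank",
                                     "attribute", "fisher"),
                         out_dir = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))

  result <- switch(command,
    simulate = {
      sim <- simulate_domain_pair(do.call(sim_config,
                                          c(cfg$sim %||% list(),
                                            list(seed = cfg$seed))))
      write_expression_matrix(sim$source$matrix,
                              file.path(out_dir, "source_expr.tsv"))
      write_labels(sim$source$labels, file.path(out_dir, "source_labels.tsv"))
      write_expression_matrix(sim$target$matrix,
                              file.path(out_dir, "target_expr.tsv"))
      write_labels(sim$target$labels, file.path(out_dir, "target_labels.tsv"))
      sim
    },
    train = {
      prep <- prepare_domains(cfg, load_domains(cfg))
      fit <- do.call(adda, c(list(x_source = prep$source,
                                  y_source = prep$y_source,
                                  x_target = prep$target,
                                  seed = cfg$seed),
                             model_args(cfg)))
      save_checkpoint(fit, file.path(out_dir, "model.rds"))
      utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    },
    evaluate = {
      prep <- prepare_domains(cfg, load_domains(cfg))
      if (is.null(prep$y_target)) {
        stopf("evaluate needs target labels (paths.target_labels)")
      }
      ev <- cfg$evaluate %||% list()
      report <- do.call(cross_validate,
                        c(list(x_source = prep$source,
                               y_source = prep$y_source,
                               x_target = prep$target,
                               y_target = prep$y_target,
                               cv_folds = ev$cv_folds %||% 5L,
                               n_seeds = ev$n_seeds %||% 5L,
                               seed = cfg$seed),
                          model_args(cfg)))
      write_report(report, file.path(out_dir, "metrics"))
      report
    },
    rank = {
      fit <- load_checkpoint(cfg$paths$checkpoint)
      prep <- prepare_domains(cfg, load_domains(cfg))
      rk <- cfg$rank %||% list()
      ranking <- rank_cells(fit, prep$target,
                            low_q = rk$low_q %||% 0.10,
                            high_q = rk$high_q %||% 0.90)
      utils::write.table(ranking, file.path(out_dir, "ranks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ranking
    },
    attribute = {
      fit <- load_checkpoint(cfg$paths$checkpoint)
      prep <- prepare_domains(cfg, load_domains(cfg))
      at <- cfg$attribute %||% list()
      res <- discover_biomarkers(list(fit), list(prep$target), prep$target,
                                 group_mode = at$group_mode %||% "median",
                                 steps = at$steps %||% 50L,
                                 tail_q = at$tail_q %||% 0.05,
                                 alpha = at$alpha %||% 0.05)
      utils::write.table(
        data.frame(gene = names(res$mean_attribution),
                   mean_attribution = res$mean_attribution),
        file.path(out_dir, "attributions.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$de_table, file.path(out_dir, "biomarkers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    fisher = {
      tab <- as.numeric(cfg$fisher$table)
      if (length(tab) != 4) stopf("fisher.table must hold 4 counts a,b,c,d")
      ft <- fisher_exact(tab)
      jsonlite::write_json(
        list(odds_ratio = ft$odds_ratio, p_value = ft$p_value,
             sensitive_fraction_row1 = sensitive_fraction(tab, 1L),
             sensitive_fraction_row2 = sensitive_fraction(tab, 2L)),
        file.path(out_dir, "fisher.json"), auto_unbox = TRUE, digits = NA)
      ft
    })
  invisible(result)
}
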