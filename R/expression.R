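# Expression matrices, response label tables, gene panels and their file I/O.
#
# The common currency of the pipeline is a plain numeric matrix oriented
# samples x genes, with unique rownames (samples/cells) and colnames (genes)
# and a "layer" attribute recording how far along the preprocessing chain the
# values are: raw_counts -> normalized -> log_normalized -> zscored.

EXPR_LAYERS <- c("raw_counts", "normalized", "log_normalized", "zscored")

#' Construct an expression matrix
#'
#' Validates and tags a samples x genes numeric matrix. All pipeline stages
#' exchange matrices built by this constructor: rownames are sample (cell)
#' identifiers, colnames are gene identifiers, and the `layer` attribute
#' records the processing state of the values.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   unique non-empty dimnames.
#' @param layer One of `"raw_counts"`, `"normalized"`, `"log_normalized"`,
#'   `"zscored"`.
#' @return The validated matrix with a `layer` attribute.
#' @export
#' @examples
#' m <- matrix(rpois(6, 5), 2, 3,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' x <- expr_matrix(m, "raw_counts")
#' expr_layer(x)
expr_matrix <- function(values, layer = "raw_counts") {
  layer <- match.arg(layer, EXPR_LAYERS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("expression values must be a numeric matrix")
  }
  ids <- dimnames(values)
  if (is.null(ids) || is.null(ids[[1]]) || is.null(ids[[2]])) {
    stopf("expression matrix needs sample rownames and gene colnames")
  }
  dup_s <- ids[[1]][duplicated(ids[[1]])]
  if (length(dup_s)) stopf("duplicated sample id: '%s'", dup_s[[1]])
  dup_g <- ids[[2]][duplicated(ids[[2]])]
  if (length(dup_g)) stopf("duplicated gene id: '%s'", dup_g[[1]])
  if (layer == "raw_counts" && (any(!is.finite(values)) || any(values < 0))) {
    stopf("raw counts must be finite and non-negative")
  }
  if (layer == "zscored" && any(!is.finite(values))) {
    stopf("z-scored values must be finite")
  }
  structure(values, layer = layer)
}

#' Query or set the processing layer of an expression matrix
#' @param x Expression matrix.
#' @return The layer tag string.
#' @export
expr_layer <- function(x) attr(x, "layer") %||% "raw_counts"

set_layer <- function(x, layer) {
  attr(x, "layer") <- match.arg(layer, EXPR_LAYERS)
  x
}

# Subset columns while keeping the layer attribute (plain `[` would drop it).
keep_genes <- function(x, genes) {
  set_layer(x[, genes, drop = FALSE], expr_layer(x))
}

keep_samples <- function(x, samples) {
  set_layer(x[samples, , drop = FALSE], expr_layer(x))
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV matrix with an identifier column and a header row and
#' returns it oriented samples x genes regardless of the on-disk orientation.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`;
#'   how the file on disk is laid out.
#' @param delimiter Field delimiter, default tab.
#' @param layer Layer tag to attach (the file does not record it).
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples"),
                                   delimiter = "\t",
                                   layer = "raw_counts") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    col <- colnames(df)[bad[[1]]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad[[1]]]]))))[1]
    stopf("non-numeric value in column '%s', row %d of %s", col, row %||% 1L, path)
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  expr_matrix(m, layer = layer)
}

#' Write an expression matrix to a delimited file
#'
#' @param x Expression matrix (samples x genes).
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (genes x cells coordinate MatrixMarket, the 10x
#' convention), a barcodes file (one cell barcode per line) and a features
#' file (one or two tab-separated columns; the gene identifier is taken from
#' the first column).
#'
#' @param dir Directory containing the three files.
#' @param matrix_file,barcodes_file,features_file File names within `dir`.
#' @return A dense cells x genes [expr_matrix()] with layer `"raw_counts"`.
#' @export
read_mtx_triplet <- function(dir,
                             matrix_file = "matrix.mtx",
                             barcodes_file = "barcodes.tsv",
                             features_file = "features.tsv") {
  paths <- file.path(dir, c(matrix_file, barcodes_file, features_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing file: %s", missing[[1]])
  mm <- Matrix::readMM(paths[[1]])
  barcodes <- readLines(paths[[2]])
  feats <- utils::read.table(paths[[3]], sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- as.character(feats[[1]])
  if (nrow(mm) != length(genes)) {
    stopf("matrix has %d rows but features file lists %d genes",
          nrow(mm), length(genes))
  }
  if (ncol(mm) != length(barcodes)) {
    stopf("matrix has %d columns but barcodes file lists %d cells",
          ncol(mm), length(barcodes))
  }
  m <- t(as.matrix(mm))          # cells x genes
  if (any(m < 0)) stopf("negative raw count in %s", paths[[1]])
  dimnames(m) <- list(barcodes, genes)
  expr_matrix(m, layer = "raw_counts")
}

#' Restrict two expression matrices to their shared genes
#'
#' Both domains must live in the same gene space before training; this keeps
#' only genes present in both matrices, in identical lexicographic order.
#'
#' @param source,target Expression matrices.
#' @return A list with elements `source`, `target` (column-aligned) and
#'   `n_shared`.
#' @export
intersect_genes <- function(source, target) {
  shared <- sort(intersect(colnames(source), colnames(target)))
  if (!length(shared)) stopf("source and target share no genes")
  list(source = keep_genes(source, shared),
       target = keep_genes(target, shared),
       n_shared = length(shared))
}

#' Read a per-sample binary response label table
#'
#' Two-column delimited file (`sample_id`, `label`), labels in `{0, 1, NA}`;
#' 1 = sensitive, 0 = resistant, NA = unknown. Unknown labels are kept: whether
#' to drop them is a training-time decision, not an I/O one.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter.
#' @return A `response_labels` data.frame with columns `sample_id`, `label`.
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  response_labels(as.character(df[[1]]), df[[2]])
}

#' Construct a response label table
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Vector coercible to 0/1/NA.
#' @return A `response_labels` data.frame.
#' @export
response_labels <- function(sample_ids, labels) {
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicated sample id: '%s'", dup[[1]])
  lab <- suppressWarnings(as.numeric(labels))
  bad <- which(!is.na(labels) & (is.na(lab) | !lab %in% c(0, 1)))
  if (length(bad)) {
    stopf("label '%s' for sample '%s' is not 0, 1 or NA",
          as.character(labels[bad[[1]]]), sample_ids[bad[[1]]])
  }
  structure(data.frame(sample_id = sample_ids, label = lab,
                       stringsAsFactors = FALSE),
            class = c("response_labels", "data.frame"))
}

#' @rdname read_labels
#' @param labels A `response_labels` table to write.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  utils::write.table(labels, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene panel file (one gene symbol per line)
#'
#' @param path Path to the panel file.
#' @param name Panel name; defaults to the file name.
#' @return Character vector of unique gene ids with a `name` attribute.
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stopf("gene panel '%s' is empty", name)
  dup <- genes[duplicated(genes)]
  if (length(dup)) stopf("duplicated gene id in panel: '%s'", dup[[1]])
  structure(genes, name = name)
}

# Align a label table to a matrix's samples (by id), returning the 0/1 vector.
align_labels <- function(x, labels, require_known = TRUE) {
  idx <- match(rownames(x), labels$sample_id)
  if (anyNA(idx)) {
    stopf("no label row for sample '%s'", rownames(x)[which(is.na(idx))[1]])
  }
  y <- labels$label[idx]
  if (require_known && anyNA(y)) {
    stopf("sample '%s' has unknown label; drop unknowns before training",
          rownames(x)[which(is.na(y))[1]])
  }
  y
}
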