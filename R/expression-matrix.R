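#' Expression matrix with per-sample metadata
#'
#' The central container of the expression pipeline: a genes x samples
#' matrix of nonnegative FPKM-scale values (or log10 values after
#' [log_transform()]) plus a metadata row per sample.
#'
#' @param values Numeric matrix, genes as rows (rownames are gene ids),
#'   samples as columns (colnames are sample names). Values must be
#'   nonnegative and finite unless `scale = "log10"`.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample`, `species`, `lab`, `condition`, `replicate`, `day` and
#'   logical `reference_group`. Missing optional columns are filled with
#'   defaults (`day = NA`, `reference_group = FALSE`).
#' @param scale Either `"fpkm"` (linear, nonnegative) or `"log10"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `sample_meta` and `scale`.
#' @export
expression_matrix <- function(values, sample_meta = NULL, scale = c("fpkm", "log10")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_input("values must be numeric")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop_input("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop_input("values must have sample names as colnames")
  if (anyDuplicated(rownames(values))) stop_input("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop_input("sample names must be unique")
  if (any(!is.finite(values))) stop_input("values must be finite")
  if (scale == "fpkm" && any(values < 0))
    stop_input("FPKM-scale values must be nonnegative")

  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = colnames(values), species = NA_character_,
                              lab = NA_character_, condition = NA_character_,
                              replicate = NA_integer_, day = NA_real_,
                              reference_group = FALSE, stringsAsFactors = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!"sample" %in% names(sample_meta)) stop_input("sample_meta needs a 'sample' column")
  if (!"day" %in% names(sample_meta)) sample_meta$day <- NA_real_
  if (!"reference_group" %in% names(sample_meta)) sample_meta$reference_group <- FALSE
  required <- c("sample", "species", "lab", "condition", "replicate")
  miss <- setdiff(required, names(sample_meta))
  if (length(miss)) stop_input("sample_meta is missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(sample_meta$sample, colnames(values)) ||
      nrow(sample_meta) != ncol(values))
    stop_input("sample_meta must describe exactly the samples in 'values'")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL

  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("conditions:", paste(unique(x$sample_meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values) %||% character(0)
sample_names <- function(x) colnames(x$values)

# Subset genes (character ids or indices), keeping metadata intact.
subset_genes <- function(x, genes) {
  expression_matrix(x$values[genes, , drop = FALSE], x$sample_meta, scale = x$scale)
}

#' Read / write expression matrices as TSV
#'
#' The on-disk dialect is a values TSV (first column `gene_id`, then one
#' column per sample) plus a companion metadata TSV with columns
#' `sample`, `species`, `lab`, `condition`, `replicate`, `day`,
#' `reference_group`.
#'
#' @param values_path,meta_path Paths to the two TSV files.
#' @param scale Scale of the stored values, see [expression_matrix()].
#' @return `read_expression_tsv` returns an `expression_matrix`;
#'   `write_expression_tsv` returns its input invisibly.
#' @export
read_expression_tsv <- function(values_path, meta_path, scale = c("fpkm", "log10")) {
  tab <- utils::read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = match.arg(scale))
}

#' @param x An `expression_matrix`.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, values_path, meta_path) {
  tab <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(tab, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a two-column homolog mapping table
#'
#' @param path TSV with two columns: gene id in species A, gene id in
#'   species B. Duplicate pairs are dropped.
#' @return A `homolog_map` data frame with columns `a` and `b`.
#' @export
read_homolog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  homolog_map(tab[[1]], tab[[2]])
}

#' Construct a homolog map from paired gene-id vectors
#'
#' @param a,b Equal-length character vectors of paired gene ids.
#' @return A `homolog_map` data frame with columns `a` and `b`;
#'   duplicate pairs are removed.
#' @export
homolog_map <- function(a, b) {
  if (length(a) != length(b)) stop_input("homolog id vectors must have equal length")
  map <- unique(data.frame(a = as.character(a), b = as.character(b),
                           stringsAsFactors = FALSE))
  rownames(map) <- NULL
  class(map) <- c("homolog_map", "data.frame")
  map
}
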