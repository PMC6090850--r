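#' Pairwise Spearman correlation matrix of samples
#'
#' Rank correlation (average ranks for ties) between every pair of
#' sample columns over the shared gene rows. Constant columns have no
#' rank variance; their coefficients are reported as `NA` with a
#' warning rather than a fabricated value.
#'
#' @param x An `expression_matrix` (typically log10 scale) or a plain
#'   numeric matrix with samples as columns.
#' @return A `correlation_matrix`: symmetric numeric matrix with unit
#'   diagonal and sample names on both dimensions.
#' @export
spearman_matrix <- function(x) {
  values <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (ncol(values) < 2L) stop_input("need at least 2 samples")
  constant <- apply(values, 2, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(values, method = "spearman"))
  if (any(constant)) {
    warning("constant sample column(s): ",
            paste(colnames(values)[constant], collapse = ", "),
            "; their correlations are undefined (NA)", call. = FALSE)
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
  }
  diag(rho) <- 1
  class(rho) <- c("correlation_matrix", class(rho))
  rho
}

#' Average-linkage clustering on correlation distance
#'
#' Samples are clustered with one minus the Spearman rank correlation
#' as the distance and average (UPGMA) linkage. Samples are processed
#' in lexicographic label order, so equal-distance merges resolve to
#' the lexicographically earliest pair, making the dendrogram
#' reproducible.
#'
#' @param corr A complete `correlation_matrix` (no `NA` entries).
#' @return An [stats::hclust] tree; merge heights lie in \[0, 2\].
#' @export
cluster_samples <- function(corr) {
  if (!isTRUE(all.equal(unname(corr), unname(t(corr))))) stop_input("correlation matrix must be symmetric")
  if (anyNA(corr)) {
    idx <- which(is.na(corr) & upper.tri(corr), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i) paste0(rownames(corr)[i[1]], "/", colnames(corr)[i[2]]))
    stop_input("missing correlations for pair(s): ", paste(pairs, collapse = ", "))
  }
  ord <- order(rownames(corr))
  d <- stats::as.dist(1 - corr[ord, ord])
  stats::hclust(d, method = "average")
}

#' Principal-component embedding with a noise floor
#'
#' Log10 expression values below `floor` are set to `floor` before the
#' decomposition to limit the influence of noise in lowly expressed
#' genes; samples are then embedded by PCA on the gene dimensions
#' (centered, unscaled).
#'
#' @param x An `expression_matrix` on the log10 scale.
#' @param floor Pre-decomposition floor (default -2).
#' @return A `pca_embedding`: list with `coords` (samples x components),
#'   `var_explained` (fractions, non-increasing) and `sdev`.
#' @export
pca_embed <- function(x, floor = -2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$values) < 2L) stop_input("need at least 2 samples")
  values <- pmax(x$values, floor)
  nonconstant <- apply(values, 1, function(v) length(unique(v)) > 1L)
  if (sum(nonconstant) < 2L) stop_input("need at least 2 non-constant genes")
  fit <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(coords = fit$x, var_explained = ve, sdev = fit$sdev, floor = floor),
            class = "pca_embedding")
}

#' Fold-change reproducibility between replicate experiments
#'
#' For two independent replicates of a (treated, control) protocol
#' pair — e.g. Nutridoma vs DMSO-only differentiation — computes the
#' per-gene log10 fold change within each replicate and correlates the
#' two fold-change profiles across genes. Genes whose mean log10
#' expression over the four samples falls below `min_mean` are excluded
#' to avoid noise from lowly expressed genes.
#'
#' @param x An `expression_matrix` on the log10 scale.
#' @param treated,control Length-2 character vectors of sample names:
#'   replicate 1 and 2 of the treated and the control protocol.
#' @param min_mean Mean-expression inclusion threshold (default -1).
#' @return List with `pearson`, `spearman`, and `table` (gene, fc_rep1,
#'   fc_rep2, mean_expr for the surviving genes).
#' @export
fold_change_reproducibility <- function(x, treated, control, min_mean = -1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log10") stop_input("log10-scale input required")
  if (length(treated) != 2L || length(control) != 2L)
    stop_input("treated and control must each name two replicate samples")
  samp <- c(treated, control)
  if (!all(samp %in% sample_names(x))) stop_input("unknown sample name(s)")

  fc1 <- x$values[, treated[1]] - x$values[, control[1]]
  fc2 <- x$values[, treated[2]] - x$values[, control[2]]
  mean_expr <- rowMeans(x$values[, samp, drop = FALSE])
  keep <- mean_expr >= min_mean
  if (sum(keep) < 3L) stop_input("fewer than 3 genes pass the mean-expression filter")

  tab <- data.frame(gene = gene_ids(x)[keep], fc_rep1 = fc1[keep], fc_rep2 = fc2[keep],
                    mean_expr = mean_expr[keep], stringsAsFactors = FALSE)
  list(pearson = stats::cor(tab$fc_rep1, tab$fc_rep2),
       spearman = stats::cor(tab$fc_rep1, tab$fc_rep2, method = "spearman"),
       table = tab)
}

#' Select genes consistently upregulated by a supplement
#'
#' A gene is retained iff its mean log10 expression across all the
#' differentiation samples involved is at least `min_mean` AND it is at
#' least `min_fold`-fold up in *every* matched (treated, control) pair
#' — the conjunction mirrors requiring the effect in each cell line and
#' replicate. Both bounds are inclusive; fold changes are compared on
#' the log scale with a 1e-9 tolerance so an exact `min_fold`-fold gene
#' is retained despite floating-point rounding.
#'
#' @param x An `expression_matrix` on the log10 scale (floored, so zero
#'   expression enters as the floor value, never as -Inf).
#' @param pairs Data frame with columns `treated` and `control` naming
#'   matched samples (one row per matched pair).
#' @param min_mean Mean log10 expression threshold (default -1).
#' @param min_fold Fold-change threshold on the linear scale (default 3).
#' @return Character vector of retained gene ids.
#' @export
select_upregulated_genes <- function(x, pairs, min_mean = -1, min_fold = 3) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log10") stop_input("log10-scale input required")
  pairs <- as.data.frame(pairs)
  if (!all(c("treated", "control") %in% names(pairs)))
    stop_input("pairs needs 'treated' and 'control' columns")
  samp <- unique(c(pairs$treated, pairs$control))
  if (anyNA(samp) || !all(samp %in% sample_names(x)))
    stop_input("every treated sample must have a matched control present in the matrix")

  mean_expr <- rowMeans(x$values[, samp, drop = FALSE])
  log_fc <- sapply(seq_len(nrow(pairs)), function(i) {
    x$values[, pairs$treated[i]] - x$values[, pairs$control[i]]
  })
  log_fc <- matrix(log_fc, nrow = nrow(x$values))
  keep <- mean_expr >= min_mean &
    apply(log_fc >= log10(min_fold) - 1e-9, 1, all)
  gene_ids(x)[keep]
}

#' Export a correlation matrix as TSV
#' @param corr A `correlation_matrix`.
#' @param path Output path.
#' @export
write_correlation_tsv <- function(corr, path) {
  tab <- data.frame(sample = rownames(corr), unclass(corr), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(corr)
}

#' Export a sample dendrogram in Newick format
#' @param tree An [stats::hclust] tree from [cluster_samples()].
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(tree)
}
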