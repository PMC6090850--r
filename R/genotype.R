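#' Genotype call table for sample-identity checks
#'
#' Post-variant-calling genotype calls at a set of loci for several
#' samples, with per-sample read depth and a per-locus site quality —
#' the inputs of the concordance analysis that authenticates cell
#' lines by their SNP profile.
#'
#' @param loci Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`; positions must be unique within a chromosome.
#' @param gt Character matrix (loci x samples) of unphased genotype
#'   calls such as `"0/1"`; `NA` for missing.
#' @param dp Integer matrix (loci x samples) of read depths (>= 0).
#' @return A `genotype_table` object.
#' @export
genotype_table <- function(loci, gt, dp) {
  loci <- as.data.frame(loci)
  need <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(loci))) stop_input("loci needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(loci[c("chrom", "pos")])) stop_input("positions must be unique per chromosome")
  gt <- as.matrix(gt); dp <- as.matrix(dp)
  if (is.null(colnames(gt))) stop_input("gt needs sample names as colnames")
  if (!identical(dim(gt), dim(dp)) || nrow(gt) != nrow(loci))
    stop_input("loci, gt and dp dimensions disagree")
  if (any(dp < 0, na.rm = TRUE)) stop_input("read depth must be >= 0")
  structure(list(loci = loci, gt = gt, dp = dp), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d loci x %d samples\n", nrow(x$gt), ncol(x$gt)))
  invisible(x)
}

#' Filter loci by read depth and site quality
#'
#' A locus is retained iff its read depth is at least `min_depth` in
#' *every* sample and its site quality is strictly greater than
#' `min_qual`. Raising either threshold can only shrink the retained
#' set.
#'
#' @param x A `genotype_table`.
#' @param min_depth Minimum per-sample depth (inclusive, default 10).
#' @param min_qual Site-quality bound (exclusive, default 100).
#' @return The filtered `genotype_table`; the number of retained loci
#'   is reported via `message()`.
#' @export
filter_loci <- function(x, min_depth = 10, min_qual = 100) {
  stopifnot(inherits(x, "genotype_table"))
  if (nrow(x$gt) == 0L) stop_input("empty genotype table")
  keep <- apply(x$dp >= min_depth, 1, all) & x$loci$qual > min_qual
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop_input("no loci pass depth >= ", min_depth, " and quality > ", min_qual,
               "; consider relaxing the thresholds")
  message(sum(keep), " of ", length(keep), " loci retained")
  genotype_table(x$loci[keep, , drop = FALSE],
                 x$gt[keep, , drop = FALSE], x$dp[keep, , drop = FALSE])
}

# Canonical unphased form: allele multiset sorted, "1/0" -> "0/1".
canonical_gt <- function(g) {
  vapply(strsplit(g, "[/|]"), function(a) paste(sort(a), collapse = "/"),
         character(1))
}

#' Pairwise genotype concordance matrix
#'
#' For each pair of samples, the fraction of loci at which the two
#' unphased genotypes are identical as allele multisets (`0/1` equals
#' `1/0`). Fractions near 1 indicate a shared genetic origin, as when a
#' cell line and its sub-line are compared.
#'
#' @param x A filtered `genotype_table` with no missing genotypes.
#' @return A `concordance_matrix`: symmetric matrix of fractions in
#'   \[0, 1\] with unit diagonal, plus attribute `n_loci`.
#' @export
pairwise_identity <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (nrow(x$gt) < 1L) stop_input("no loci")
  if (ncol(x$gt) < 2L) stop_input("need at least 2 samples")
  if (anyNA(x$gt)) stop_input("missing genotypes present; filter loci first")
  canon <- apply(x$gt, 2, canonical_gt)
  canon <- matrix(canon, nrow = nrow(x$gt), dimnames = dimnames(x$gt))
  n <- ncol(canon)
  m <- diag(1, n)
  dimnames(m) <- list(colnames(canon), colnames(canon))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- mean(canon[, i] == canon[, j])
  }
  attr(m, "n_loci") <- nrow(canon)
  class(m) <- c("concordance_matrix", class(m))
  m
}

#' Read / write genotype tables as TSV
#'
#' Dialect: columns `chrom, pos, ref, alt, qual`, then one `GT:DP`
#' column per sample (e.g. `0/1:23`).
#'
#' @param path TSV path.
#' @return `read_genotype_tsv` returns a `genotype_table`.
#' @export
read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  fixed <- c("chrom", "pos", "ref", "alt", "qual")
  samples <- setdiff(names(tab), fixed)
  loci <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos), ref = tab$ref,
                     alt = tab$alt, qual = as.numeric(tab$qual),
                     stringsAsFactors = FALSE)
  parts <- lapply(tab[samples], function(col) do.call(rbind, strsplit(col, ":", fixed = TRUE)))
  gt <- sapply(parts, function(p) p[, 1])
  dp <- sapply(parts, function(p) as.integer(p[, 2]))
  gt <- matrix(gt, nrow = nrow(tab), dimnames = list(NULL, samples))
  dp <- matrix(dp, nrow = nrow(tab), dimnames = list(NULL, samples))
  genotype_table(loci, gt, dp)
}

#' @param x A `genotype_table`.
#' @rdname read_genotype_tsv
#' @export
write_genotype_tsv <- function(x, path) {
  out <- x$loci[c("chrom", "pos", "ref", "alt", "qual")]
  for (s in colnames(x$gt)) out[[s]] <- paste0(x$gt[, s], ":", x$dp[, s])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Export a concordance matrix as TSV
#' @param m A `concordance_matrix`.
#' @param path Output path.
#' @export
write_concordance_tsv <- function(m, path) {
  tab <- data.frame(sample = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
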