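#' Build a merged, queryable expression catalog
#'
#' Combines per-group averaged log10 expression profiles (cell states
#' and species, e.g. undifferentiated, DMSO-differentiated,
#' Nutridoma-differentiated, primary human, primary mouse) into one
#' table keyed by gene id, with optional gene symbols, homolog links
#' and protein-domain annotations — the static form of a searchable
#' expression database.
#'
#' Groups are outer-joined on gene id: a gene absent from a group gets
#' `NA` there (never a silent zero or floor value).
#'
#' @param groups Named list; each element is either a named numeric
#'   vector (gene id -> averaged log10 value) or a one-column
#'   `expression_matrix`. Duplicate gene ids within a group are an
#'   error.
#' @param symbols Optional named character vector, gene id -> symbol.
#' @param homologs Optional `homolog_map`; the `b` id of a pair is
#'   recorded as the homolog of gene `a` and vice versa.
#' @param domains Optional data frame with columns `gene_id` and
#'   `domain` (one row per annotation; a gene may have several).
#' @return A `catalog_table` data frame: columns `gene_id`, `symbol`,
#'   one expression column per group, `homolog`, `domains`
#'   (`;`-separated).
#' @export
build_catalog <- function(groups, symbols = NULL, homologs = NULL, domains = NULL) {
  if (length(groups) == 0L || is.null(names(groups)) || any(names(groups) == ""))
    stop_input("groups must be a nonempty named list")
  vecs <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (inherits(v, "expression_matrix")) {
      if (ncol(v$values) != 1L) stop_input("group '", g, "' must have a single column")
      v <- stats::setNames(v$values[, 1], gene_ids(v))
    }
    if (is.null(names(v))) stop_input("group '", g, "' values must be named by gene id")
    if (anyDuplicated(names(v)))
      stop_input("duplicate gene id(s) in group '", g, "': ",
                 paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
    v
  })
  names(vecs) <- names(groups)

  ids <- sort(unique(unlist(lapply(vecs, names))))
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  out$symbol <- if (is.null(symbols)) NA_character_ else unname(symbols[ids])
  for (g in names(vecs)) out[[g]] <- unname(vecs[[g]][ids])

  out$homolog <- NA_character_
  if (!is.null(homologs)) {
    hm <- stats::setNames(c(homologs$b, homologs$a), c(homologs$a, homologs$b))
    hm <- hm[!duplicated(names(hm))]
    hit <- ids %in% names(hm)
    out$homolog[hit] <- unname(hm[ids[hit]])
  }

  out$domains <- NA_character_
  if (!is.null(domains)) {
    domains <- as.data.frame(domains)
    if (!all(c("gene_id", "domain") %in% names(domains)))
      stop_input("domains needs 'gene_id' and 'domain' columns")
    agg <- tapply(domains$domain, domains$gene_id, function(d) paste(unique(d), collapse = ";"))
    hit <- ids %in% names(agg)
    out$domains[hit] <- unname(agg[ids[hit]])
  }
  rownames(out) <- NULL
  structure(out, class = c("catalog_table", "data.frame"),
            group_columns = names(vecs))
}

#' Query the expression catalog
#'
#' Exact-match filter by gene symbol, gene id, or protein-domain label,
#' optionally sorted by one expression column (stable sort: ties keep
#' catalog order) and truncated to the top rows — e.g. "the ten
#' kinase-domain genes with the highest expression in primary
#' neutrophils".
#'
#' @param catalog A `catalog_table`.
#' @param gene Exact gene symbol to match.
#' @param gene_id Exact gene id to match.
#' @param domain Domain label; matches rows whose annotation contains
#'   it. An unknown domain yields an empty result, not an error.
#' @param sort_by Name of an expression column to sort by.
#' @param descending Sort direction (default `TRUE`); `NA` values sort
#'   last either way.
#' @param top Optional row-count truncation after sorting.
#' @return The matching rows of the catalog (a data frame).
#' @export
query_catalog <- function(catalog, gene = NULL, gene_id = NULL, domain = NULL,
                          sort_by = NULL, descending = TRUE, top = NULL) {
  stopifnot(inherits(catalog, "catalog_table"))
  rows <- rep(TRUE, nrow(catalog))
  if (!is.null(gene)) rows <- rows & !is.na(catalog$symbol) & catalog$symbol == gene
  if (!is.null(gene_id)) rows <- rows & catalog$gene_id == gene_id
  if (!is.null(domain)) {
    has <- vapply(strsplit(catalog$domains, ";", fixed = TRUE),
                  function(d) domain %in% d, logical(1))
    rows <- rows & !is.na(catalog$domains) & has
  }
  res <- catalog[rows, , drop = FALSE]
  if (!is.null(sort_by)) {
    if (!sort_by %in% names(res)) stop_input("unknown sort column '", sort_by, "'")
    ord <- order(res[[sort_by]], decreasing = descending,
                 na.last = TRUE, method = "radix")
    res <- res[ord, , drop = FALSE]
  }
  if (!is.null(top)) res <- utils::head(res, top)
  rownames(res) <- NULL
  res
}

#' Read / write the catalog as CSV
#'
#' Missing expression values are stored as the literal token `NA`,
#' never as a numeric floor.
#'
#' @param path CSV path.
#' @return `read_catalog_csv` returns a `catalog_table`.
#' @export
read_catalog_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("gene_id", "symbol", "homolog", "domains")
  structure(tab, class = c("catalog_table", "data.frame"),
            group_columns = setdiff(names(tab), fixed))
}

#' @param catalog A `catalog_table`.
#' @rdname read_catalog_csv
#' @export
write_catalog_csv <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, na = "NA")
  invisible(catalog)
}
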