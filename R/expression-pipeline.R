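#' Identify "uniform genes" for cross-dataset scaling
#'
#' Uniform genes are genes whose expression lies between the lower and
#' upper percentile (by default the 50th and 90th) in *every* sample.
#' Their geometric mean anchors the scaling factor of each dataset.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) and interval membership is inclusive at
#' both bounds. Percentiles are computed over all genes, zeros
#' included; when a sample's lower percentile is 0, membership in that
#' sample additionally requires a strictly positive value so that
#' geometric means stay defined.
#'
#' @param x An `expression_matrix` on the FPKM scale.
#' @param lower,upper Percentile bounds as fractions (defaults 0.5, 0.9).
#' @return A `uniform_gene_set`: list with `gene_ids` and a `bounds`
#'   matrix (samples x c(lower, upper)). Empty sets are allowed and
#'   signalled with a warning.
#' @export
identify_uniform_genes <- function(x, lower = 0.5, upper = 0.9) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$values) < 1L) stop_input("matrix has no samples")
  if (nrow(x$values) < 10L) stop_input("matrix needs at least 10 genes")
  if (lower >= upper) stop_input("lower percentile must be below upper")

  bounds <- t(apply(x$values, 2, stats::quantile, probs = c(lower, upper),
                    names = FALSE, type = 7))
  colnames(bounds) <- c("lower", "upper")

  keep <- rep(TRUE, nrow(x$values))
  for (j in seq_len(ncol(x$values))) {
    v <- x$values[, j]
    in_band <- v >= bounds[j, 1] & v <= bounds[j, 2]
    if (bounds[j, 1] <= 0) in_band <- in_band & v > 0
    keep <- keep & in_band
  }
  ids <- gene_ids(x)[keep]
  if (length(ids) == 0L)
    warning("no uniform genes found; scaling factors cannot be computed", call. = FALSE)
  structure(list(gene_ids = ids, bounds = bounds,
                 percentiles = c(lower = lower, upper = upper)),
            class = "uniform_gene_set")
}

#' Per-sample scaling factors from the uniform-gene set
#'
#' The factor of a sample is the geometric mean of its uniform-gene
#' expression values; the reference mean is the mean of the factors
#' over the reference-group samples (the datasets all samples are
#' scaled to, e.g. the human datasets of a cross-species comparison).
#'
#' @param x An `expression_matrix` on the FPKM scale.
#' @param uniform A `uniform_gene_set` from [identify_uniform_genes()].
#' @param reference_samples Character vector of sample names forming the
#'   reference group; defaults to the samples flagged
#'   `reference_group = TRUE` in the metadata.
#' @param reference_average `"arithmetic"` (default) or `"geometric"`
#'   mean of the reference-group factors.
#' @return A `scaling_factors` object: list with per-sample `factors`
#'   (named, all > 0) and `reference_mean`.
#' @export
compute_scaling_factors <- function(x, uniform, reference_samples = NULL,
                                    reference_average = c("arithmetic", "geometric")) {
  stopifnot(inherits(x, "expression_matrix"), inherits(uniform, "uniform_gene_set"))
  reference_average <- match.arg(reference_average)
  if (length(uniform$gene_ids) == 0L) stop_input("uniform gene set is empty")
  if (!all(uniform$gene_ids %in% gene_ids(x)))
    stop_input("uniform genes missing from the matrix")

  sub <- x$values[uniform$gene_ids, , drop = FALSE]
  zero <- which(sub <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0L)
    stop_input(sprintf("nonpositive uniform-gene value: gene '%s' in sample '%s'",
                       rownames(sub)[zero[1, 1]], colnames(sub)[zero[1, 2]]))
  factors <- apply(sub, 2, geomean)

  if (is.null(reference_samples))
    reference_samples <- x$sample_meta$sample[x$sample_meta$reference_group]
  if (length(reference_samples) == 0L)
    stop_input("no reference samples given and none flagged in sample_meta")
  if (!all(reference_samples %in% names(factors)))
    stop_input("unknown reference sample(s)")
  ref <- factors[reference_samples]
  reference_mean <- if (reference_average == "arithmetic") mean(ref) else geomean(ref)

  structure(list(factors = factors, reference_mean = reference_mean,
                 reference_samples = reference_samples,
                 reference_average = reference_average),
            class = "scaling_factors")
}

#' Normalize an FPKM matrix by its scaling factors
#'
#' Each sample is divided by its own scaling factor and multiplied by
#' the reference mean factor, so that after normalization the geometric
#' mean of the uniform genes equals the reference mean in every sample.
#'
#' @param x An `expression_matrix` on the FPKM scale.
#' @param factors A `scaling_factors` object covering every sample.
#' @return The normalized `expression_matrix` (same shape and scale).
#' @export
normalize_expression <- function(x, factors) {
  stopifnot(inherits(x, "expression_matrix"), inherits(factors, "scaling_factors"))
  miss <- setdiff(sample_names(x), names(factors$factors))
  if (length(miss)) stop_input("missing scaling factor for: ", paste(miss, collapse = ", "))
  f <- factors$factors[sample_names(x)]
  values <- sweep(x$values, 2, f, "/") * factors$reference_mean
  expression_matrix(values, x$sample_meta, scale = "fpkm")
}

#' Log10-transform with a floor for zeros and tiny values
#'
#' Zero FPKM values (zero read counts) are assigned `zero_value` to
#' avoid infinities; positive values map to `max(log10(v), floor)`, so
#' the image of the transform is bounded below by the floor.
#'
#' @param x An `expression_matrix` on the FPKM scale.
#' @param zero_value Log10 value assigned to zeros (default -4).
#' @param floor Lower bound applied to log10 of positive values
#'   (default -4).
#' @return An `expression_matrix` with `scale = "log10"`.
#' @export
log_transform <- function(x, zero_value = -4, floor = -4) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "fpkm") stop_input("input is already on the log scale")
  if (any(x$values < 0)) stop_input("negative values cannot be log-transformed")
  values <- x$values
  pos <- values > 0
  values[pos] <- pmax(log10(values[pos]), floor)
  values[!pos] <- zero_value
  expression_matrix(values, x$sample_meta, scale = "log10")
}

#' Average replicates with equal weight per laboratory
#'
#' A two-stage arithmetic mean on the log10 scale (equivalently, a
#' geometric mean of the raw values): replicate samples are first
#' averaged within each lab, then the lab-level profiles are averaged
#' with equal weight, so a lab contributing many replicates does not
#' dominate the final profile.
#'
#' @param x An `expression_matrix` on the log10 scale.
#' @param groups Character vector naming the final group of each sample,
#'   either named by sample or in column order.
#' @return An `expression_matrix` (log10 scale) with one column per
#'   final group; metadata keeps the group's constant fields.
#' @export
average_replicates <- function(x, groups) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log10") stop_input("average_replicates expects log10-scale input")
  if (!is.null(names(groups))) {
    miss <- setdiff(sample_names(x), names(groups))
    if (length(miss)) stop_input("no group for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[sample_names(x)]
  }
  if (length(groups) != ncol(x$values)) stop_input("one group label per sample required")
  if (any(is.na(groups) | groups == "")) stop_input("group labels must be non-missing")
  labs <- x$sample_meta$lab
  if (any(is.na(labs))) stop_input("every sample needs a lab assignment")

  group_levels <- unique(groups)
  out <- sapply(group_levels, function(g) {
    cols <- which(groups == g)
    lab_means <- sapply(unique(labs[cols]), function(l) {
      rowMeans(x$values[, cols[labs[cols] == l], drop = FALSE])
    })
    rowMeans(as.matrix(lab_means))
  })
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(gene_ids(x), group_levels))

  pick <- function(v) if (length(u <- unique(v)) == 1L) u else NA
  meta <- do.call(rbind, lapply(group_levels, function(g) {
    m <- x$sample_meta[groups == g, , drop = FALSE]
    data.frame(sample = g, species = pick(m$species), lab = pick(m$lab),
               condition = pick(m$condition), replicate = NA_integer_,
               day = pick(m$day), reference_group = all(m$reference_group),
               stringsAsFactors = FALSE)
  }))
  expression_matrix(out, meta, scale = "log10")
}

#' Restrict two matrices to homologous gene pairs
#'
#' Aligns a species-A matrix and a species-B matrix row-by-row through a
#' homolog map so that cross-species correlations compare like with
#' like. Genes without a retained mapping are dropped. Under the
#' default `"one_to_one"` policy any gene participating in more than
#' one pair is discarded; `"first"` keeps the first listed pair per
#' gene.
#'
#' @param a,b `expression_matrix` objects for the two species.
#' @param map A `homolog_map` with columns `a` (ids in `a`) and `b`.
#' @param policy Multi-mapping policy, `"one_to_one"` or `"first"`.
#' @return List with elements `a` and `b`: matrices with rows aligned
#'   pairwise and sorted by species-A gene id, plus the retained `pairs`.
#' @export
restrict_to_homologs <- function(a, b, map, policy = c("one_to_one", "first")) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  policy <- match.arg(policy)
  if (nrow(map) == 0L) stop_input("homolog map is empty")

  if (policy == "one_to_one") {
    map <- map[!(map$a %in% map$a[duplicated(map$a)]) &
               !(map$b %in% map$b[duplicated(map$b)]), , drop = FALSE]
  } else {
    map <- map[!duplicated(map$a), , drop = FALSE]
    map <- map[!duplicated(map$b), , drop = FALSE]
  }
  map <- map[map$a %in% gene_ids(a) & map$b %in% gene_ids(b), , drop = FALSE]
  if (nrow(map) == 0L) stop_input("no homolog pairs overlap the two matrices")
  map <- map[order(map$a), , drop = FALSE]

  list(a = subset_genes(a, map$a), b = subset_genes(b, map$b), pairs = map)
}

#' Filter a matrix by gene-type annotation
#'
#' Keeps only genes annotated with the requested type (e.g.
#' protein-coding per NCBI "Gene type"); unannotated genes are dropped
#' and their count reported.
#'
#' @param x An `expression_matrix`.
#' @param annotation Data frame with columns `gene_id` and `type` (or a
#'   named character vector, names = gene ids).
#' @param keep Type label to retain (default `"protein-coding"`).
#' @return The filtered `expression_matrix`; may be empty (warning).
#' @export
filter_gene_type <- function(x, annotation, keep = "protein-coding") {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.data.frame(annotation)) {
    types <- stats::setNames(as.character(annotation$type), annotation$gene_id)
  } else {
    types <- annotation
  }
  ids <- gene_ids(x)
  unannotated <- sum(!ids %in% names(types))
  if (unannotated > 0L)
    message(unannotated, " gene(s) without annotation dropped")
  retain <- ids[ids %in% names(types) & types[ids] %in% keep]
  if (length(retain) == 0L) {
    warning("no genes of type '", paste(keep, collapse = "/"), "' retained", call. = FALSE)
    return(expression_matrix(x$values[retain, , drop = FALSE], x$sample_meta,
                             scale = x$scale))
  }
  subset_genes(x, retain)
}
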