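test_that("uniform genes of a shared 1..100 profile are the 50th-90th percentile band", {
  values <- matrix(rep(1:100, 3), ncol = 3)
  x <- toy_expression(values)
  u <- identify_uniform_genes(x)
  # type-7 percentiles of 1..100 are 50.5 and 90.1; inclusive band
  expect_identical(u$gene_ids, rownames(x$values)[51:90])
  expect_equal(unname(u$bounds[1, ]), c(50.5, 90.1))
})

test_that("uniform-gene selection matches the brute-force interval intersection", {
  set.seed(11)
  for (rep in 1:5) {
    values <- matrix(rexp(10 * 3, 0.1), nrow = 10)
    x <- toy_expression(values)
    u <- suppressWarnings(identify_uniform_genes(x))  # empty sets are legitimate
    expect_identical(u$gene_ids, oracle_uniform_genes(x$values))
  }
})

test_that("an all-zero sample yields an empty uniform set with a warning", {
  values <- cbind(s1 = c(rep(0, 12)), s2 = 1:12)
  x <- toy_expression(values)
  expect_warning(u <- identify_uniform_genes(x), "no uniform genes")
  expect_length(u$gene_ids, 0)
})

test_that("scaling factors are uniform-gene geometric means", {
  values <- cbind(s1 = c(4, 4, 4, 1, 50), s2 = c(1, 100, 10, 2, 60))
  x <- toy_expression(values)
  u <- structure(list(gene_ids = rownames(x$values)[1:2]), class = "uniform_gene_set")
  sf <- compute_scaling_factors(x, u, reference_samples = "s1")
  expect_equal(unname(sf$factors["s1"]), 4)        # constant set
  expect_equal(unname(sf$factors["s2"]), 10)       # geomean(1, 100)
  expect_equal(sf$reference_mean, 4)

  set.seed(7)
  values <- matrix(rlnorm(5 * 4), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  x <- toy_expression(values)
  u <- structure(list(gene_ids = rownames(values)), class = "uniform_gene_set")
  sf <- compute_scaling_factors(x, u, reference_samples = c("s1", "s2"))
  for (j in 1:4)
    expect_equal(unname(sf$factors[j]), exp(mean(log(values[, j]))), tolerance = 1e-12)
  expect_equal(sf$reference_mean, mean(sf$factors[c("s1", "s2")]))
})

test_that("a zero among uniform genes is an error naming gene and sample", {
  values <- cbind(s1 = c(0, 2, 3, 4, 5), s2 = 1:5)
  x <- toy_expression(values)
  u <- structure(list(gene_ids = rownames(x$values)[1:2]), class = "uniform_gene_set")
  expect_error(compute_scaling_factors(x, u, reference_samples = "s1"),
               "g01.*s1")
})

test_that("normalization equalizes uniform-gene geometric means and is scale-invariant", {
  set.seed(21)
  values <- matrix(rlnorm(5000 * 4, meanlog = 1), nrow = 5000)
  x <- toy_expression(values)
  u <- identify_uniform_genes(x)
  sf <- compute_scaling_factors(x, u, reference_samples = c("s1", "s2"))
  norm <- normalize_expression(x, sf)
  gm <- apply(norm$values[u$gene_ids, ], 2, function(v) exp(mean(log(v))))
  expect_equal(unname(gm), rep(sf$reference_mean, 4), tolerance = 1e-9)

  # multiplying one sample by a constant changes nothing after normalization
  scaled <- x
  scaled$values[, 3] <- scaled$values[, 3] * 37.5
  u2 <- identify_uniform_genes(scaled)
  sf2 <- compute_scaling_factors(scaled, u2, reference_samples = c("s1", "s2"))
  norm2 <- normalize_expression(scaled, sf2)
  expect_equal(norm2$values, norm$values, tolerance = 1e-9)
})

test_that("normalizing an already-normalized matrix is the identity", {
  set.seed(22)
  values <- matrix(rlnorm(2000 * 3), nrow = 2000)
  x <- toy_expression(values)
  u <- identify_uniform_genes(x)
  sf <- compute_scaling_factors(x, u, reference_samples = "s1")
  norm <- normalize_expression(x, sf)
  sf2 <- compute_scaling_factors(norm, u, reference_samples = "s1")
  expect_equal(unname(sf2$factors), rep(sf2$reference_mean, 3), tolerance = 1e-12)
  norm2 <- normalize_expression(norm, sf2)
  expect_equal(norm2$values, norm$values, tolerance = 1e-9)
})

test_that("all-equal scaling factors leave the matrix unchanged", {
  values <- cbind(s1 = c(2, 8, 1, 9, 5), s2 = c(8, 2, 9, 1, 5))
  x <- toy_expression(values)
  u <- structure(list(gene_ids = rownames(x$values)), class = "uniform_gene_set")
  # same multiset of values in both samples -> equal factors
  sf <- compute_scaling_factors(x, u, reference_samples = c("s1", "s2"))
  norm <- normalize_expression(x, sf)
  expect_equal(norm$values, x$values, tolerance = 1e-12)
})

test_that("log transform floors zeros at -4 and is monotone with image [floor, Inf)", {
  x <- toy_expression(cbind(s1 = c(0, 1, 100, 1e-7, 0.5)))
  lg <- log_transform(x)
  expect_identical(lg$scale, "log10")
  expect_equal(unname(lg$values[, 1]), c(-4, 0, 2, -4, log10(0.5)))

  set.seed(5)
  v <- sort(c(0, rexp(50)))
  lx <- log_transform(toy_expression(cbind(s = v)))$values[, 1]
  expect_true(all(diff(lx) >= 0))
  expect_true(all(lx >= -4))
  expect_error(log_transform(lg), "already")
})

test_that("replicate averaging is a two-stage equal-lab-weight mean on the log scale", {
  # lab A replicates 1 and 3, lab B single replicate 8 -> A: 2, B: 8 -> 5
  values <- rbind(g1 = c(a1 = 1, a2 = 3, b1 = 8),
                  g2 = c(a1 = 2, a2 = 4, b1 = 9))
  x <- expression_matrix(values,
                         data.frame(sample = colnames(values), species = "human",
                                    lab = c("A", "A", "B"), condition = "c",
                                    replicate = c(1, 2, 1)),
                         scale = "log10")
  avg <- average_replicates(x, c(a1 = "grp", a2 = "grp", b1 = "grp"))
  expect_equal(unname(avg$values[1, 1]), 5)
  expect_equal(unname(avg$values[2, 1]), 6)

  # permuting samples within a lab does not change the result
  perm <- expression_matrix(x$values[, c(2, 1, 3)], x$sample_meta[c(2, 1, 3), ],
                            scale = "log10")
  avg2 <- average_replicates(perm, c(a2 = "grp", a1 = "grp", b1 = "grp"))
  expect_equal(avg2$values, avg$values)

  # single lab, single sample -> identity; constant input -> constant
  single <- toy_expression(cbind(s1 = c(1.5, -2)), scale = "log10")
  expect_equal(average_replicates(single, "only")$values[, 1],
               single$values[, 1], ignore_attr = TRUE)
})

test_that("homolog restriction aligns rows and applies the one-to-one policy", {
  a <- toy_expression(matrix(1:12, nrow = 4, dimnames = list(c("hA", "hB", "hC", "hD"), NULL)))
  b <- toy_expression(matrix(1:9, nrow = 3, dimnames = list(c("mA", "mB", "mC"), NULL)))
  map <- homolog_map(c("hA", "hB", "hB", "hD"), c("mA", "mB", "mC", "mZ"))
  # hB is multi-mapped -> dropped; hD maps to a gene absent from b
  res <- restrict_to_homologs(a, b, map)
  expect_identical(rownames(res$a$values), "hA")
  expect_identical(rownames(res$b$values), "mA")
  expect_equal(nrow(res$a$values), nrow(res$b$values))

  # "first" policy keeps the first listed pair of hB
  res2 <- restrict_to_homologs(a, b, map, policy = "first")
  expect_identical(rownames(res2$a$values), c("hA", "hB"))
  expect_identical(rownames(res2$b$values), c("mA", "mB"))

  expect_error(restrict_to_homologs(a, b, homolog_map("hX", "mX")), "overlap")
})

test_that("gene-type filtering keeps the requested type and warns on empty result", {
  x <- toy_expression(matrix(1:10, nrow = 5,
                             dimnames = list(paste0("g", 1:5), NULL)))
  ann <- data.frame(gene_id = paste0("g", 1:5),
                    type = c("protein-coding", "lncRNA", "protein-coding",
                             "protein-coding", "pseudogene"))
  kept <- filter_gene_type(x, ann)
  expect_identical(rownames(kept$values), c("g1", "g3", "g4"))

  all_coding <- filter_gene_type(x, data.frame(gene_id = paste0("g", 1:5),
                                               type = "protein-coding"))
  expect_equal(all_coding$values, x$values)

  expect_warning(empty <- filter_gene_type(x, data.frame(gene_id = "g1", type = "lncRNA")),
                 "retained")
  expect_equal(nrow(empty$values), 0)
})

test_that("expression TSV round-trips values and metadata", {
  x <- gen_expression(expression_gen_spec(
    50, data.frame(species = "human", lab = c("L1", "L2"),
                   condition = c("undiff", "diff"), replicate = 1), seed = 9))
  vp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_expression_tsv(x, vp, mp)
  y <- read_expression_tsv(vp, mp)
  expect_equal(y$values, x$values, tolerance = 1e-9)
  expect_identical(y$sample_meta$lab, x$sample_meta$lab)
})
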