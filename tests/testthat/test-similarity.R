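test_that("spearman matrix matches rank-then-Pearson and handles degenerate columns", {
  set.seed(31)
  values <- matrix(rnorm(6 * 4), nrow = 6)
  x <- toy_expression(values, scale = "log10")
  rho <- spearman_matrix(x)
  # brute force: average ranks, then Pearson
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(rho[i, j], cor(rank(values[, i]), rank(values[, j])),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_equal(rho, t(rho))

  dup <- toy_expression(cbind(a = values[, 1], b = values[, 1]), scale = "log10")
  expect_equal(spearman_matrix(dup)["a", "b"], 1)
  rev <- toy_expression(cbind(a = 1:6, b = 6:1), scale = "log10")
  expect_equal(spearman_matrix(rev)["a", "b"], -1)
  con <- toy_expression(cbind(a = 1:6, b = rep(2, 6)), scale = "log10")
  expect_warning(r <- spearman_matrix(con), "constant")
  expect_true(is.na(r["a", "b"]))
  expect_equal(r["b", "b"], 1)
})

test_that("spearman matrix is invariant under strictly monotone column transforms", {
  set.seed(32)
  values <- matrix(rnorm(30 * 3), nrow = 30)
  x <- toy_expression(values, scale = "log10")
  y <- values
  y[, 1] <- exp(y[, 1]); y[, 2] <- y[, 2]^3; y[, 3] <- 5 * y[, 3] + 2
  expect_equal(spearman_matrix(toy_expression(y, scale = "log10")),
               spearman_matrix(x), tolerance = 1e-12)
})

test_that("average-linkage heights equal brute-force UPGMA on correlation distance", {
  set.seed(33)
  values <- matrix(rnorm(40 * 5), nrow = 40)
  rho <- spearman_matrix(toy_expression(values, scale = "log10"))
  tree <- cluster_samples(rho)
  expect_equal(sort(tree$height), oracle_upgma_heights(as.dist(1 - rho)),
               tolerance = 1e-12)
  expect_true(all(tree$height >= 0 & tree$height <= 2))
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("identical samples merge first at height zero", {
  set.seed(30)
  base <- rnorm(20)
  values <- cbind(a = base, b = base, c = -base + rnorm(20, sd = 0.01))
  rho <- spearman_matrix(toy_expression(values, scale = "log10"))
  tree <- cluster_samples(rho)
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  first <- tree$labels[-tree$merge[1, ]]
  expect_setequal(first, c("a", "b"))
})

test_that("missing correlations abort clustering with the offending pair named", {
  rho <- diag(3); dimnames(rho) <- list(letters[1:3], letters[1:3])
  rho[1, 2] <- rho[2, 1] <- NA
  rho[1, 3] <- rho[3, 1] <- 0.5; rho[2, 3] <- rho[3, 2] <- 0.2
  class(rho) <- c("correlation_matrix", class(rho))
  expect_error(cluster_samples(rho), "a/b")
})

test_that("synthetic condition structure is recovered by clustering (ARI > 0.9)", {
  skip_if_not_installed("mclust")
  samples <- data.frame(species = "human", lab = "L1",
                        condition = rep(c("undiff", "diff", "neutro"), each = 3),
                        replicate = rep(1:3, 3))
  spec <- expression_gen_spec(2000, samples,
                              differentiation_shift = c(diff = 0.5, neutro = 1),
                              noise_sd = 0.1, seed = 17)
  x <- log_transform(gen_expression(spec))
  tree <- cluster_samples(spearman_matrix(x))
  k3 <- cutree(tree, k = 3)
  truth <- x$sample_meta$condition[match(names(k3), x$sample_meta$sample)]
  expect_gt(mclust::adjustedRandIndex(k3, truth), 0.9)
})

test_that("PCA floors sub-threshold values, and matches a 2x2 eigendecomposition", {
  set.seed(34)
  values <- matrix(rnorm(100 * 3, sd = 2), nrow = 100)
  x <- toy_expression(values, scale = "log10")
  emb <- pca_embed(x, floor = -2)
  expect_true(min(pmax(values, -2)) >= -2)

  dup <- toy_expression(cbind(a = values[, 1], b = values[, 1], c = values[, 2]),
                        scale = "log10")
  emb2 <- pca_embed(dup)
  expect_equal(emb2$coords["a", ], emb2$coords["b", ], tolerance = 1e-9)

  # 2-gene toy: variance fractions from the covariance eigenvalues
  two <- toy_expression(matrix(c(1, 2, 3, 1, 5, 4, 2, 3, 7, 0, 2, 1), nrow = 2,
                               dimnames = list(c("g1", "g2"), paste0("s", 1:6))),
                        scale = "log10")
  emb3 <- pca_embed(two, floor = -2)
  ev <- eigen(cov(t(two$values)))$values
  expect_equal(emb3$var_explained, ev / sum(ev), tolerance = 1e-12)
  expect_true(all(diff(emb3$var_explained) <= 1e-12))
})

test_that("PCA coordinates are invariant to a constant shift of every gene", {
  set.seed(35)
  values <- matrix(rnorm(50 * 4), nrow = 50)
  x <- toy_expression(values, scale = "log10")
  y <- toy_expression(values + 0.5, scale = "log10")  # stays above the floor
  a <- pca_embed(x, floor = -10); b <- pca_embed(y, floor = -10)
  expect_equal(abs(a$coords), abs(b$coords), tolerance = 1e-9)
})

test_that("fold-change reproducibility is 1 for copied replicates and filters by mean", {
  set.seed(36)
  n <- 20
  base <- rnorm(n, 1)
  fc <- rnorm(n)
  values <- cbind(t1 = base + fc, c1 = base, t2 = base + fc + 0.1, c2 = base + 0.1)
  rownames(values) <- sprintf("g%02d", 1:n)
  # push 5 genes below the mean filter
  values[1:5, ] <- values[1:5, ] - 8
  x <- toy_expression(values, scale = "log10")
  res <- fold_change_reproducibility(x, treated = c("t1", "t2"), control = c("c1", "c2"))
  expect_equal(nrow(res$table), 15)   # hand count of survivors
  expect_equal(res$pearson, 1, tolerance = 1e-9)   # fc_rep2 == fc_rep1
  expect_equal(res$spearman, 1, tolerance = 1e-9)

  # independent noise decorrelates
  set.seed(37)
  big <- cbind(t1 = rnorm(3000, 2), c1 = rnorm(3000, 2),
               t2 = rnorm(3000, 2), c2 = rnorm(3000, 2))
  rownames(big) <- sprintf("g%04d", 1:3000)
  res2 <- fold_change_reproducibility(toy_expression(big, scale = "log10"),
                                      c("t1", "t2"), c("c1", "c2"))
  expect_lt(abs(res2$pearson), 0.1)
  expect_error(fold_change_reproducibility(x, c("t1", "t2"), c("c1", "c2"),
                                           min_mean = 99), "fewer than 3")
})

test_that("upregulated-gene selection enforces every pair and inclusive bounds", {
  lf3 <- log10(3)
  # g1: exactly 3-fold in both pairs; g2: 3-fold in one pair only;
  # g3: high fold but fails mean filter; g4: clear hit; g5: no change
  values <- rbind(
    g1 = c(t1 = 0 + lf3, c1 = 0, t2 = 1 + lf3, c2 = 1),
    g2 = c(2 + lf3, 2, 2 + 0.2, 2),
    g3 = c(-3 + 2, -3, -3 + 2, -3),
    g4 = c(1 + 1, 1, 2 + 1, 2),
    g5 = c(1, 1, 1, 1))
  x <- toy_expression(values, scale = "log10")
  pairs <- data.frame(treated = c("t1", "t2"), control = c("c1", "c2"))
  got <- select_upregulated_genes(x, pairs)
  expect_setequal(got, c("g1", "g4"))

  # brute-force check on a random toy
  set.seed(38)
  rv <- matrix(rnorm(10 * 4, 1), nrow = 10,
               dimnames = list(sprintf("r%02d", 1:10), c("t1", "c1", "t2", "c2")))
  rx <- toy_expression(rv, scale = "log10")
  got2 <- select_upregulated_genes(rx, pairs)
  manual <- rownames(rv)[rowMeans(rv) >= -1 &
                         rv[, "t1"] - rv[, "c1"] >= lf3 - 1e-9 &
                         rv[, "t2"] - rv[, "c2"] >= lf3 - 1e-9]
  expect_setequal(got2, manual)
  expect_error(select_upregulated_genes(x, data.frame(treated = "t1", control = "nope")),
               "matched control")
})

test_that("correlation and dendrogram exports round-trip through TSV and Newick", {
  set.seed(39)
  rho <- spearman_matrix(toy_expression(matrix(rnorm(30 * 4), 30), scale = "log10"))
  p <- tempfile(fileext = ".tsv")
  write_correlation_tsv(rho, p)
  back <- utils::read.delim(p, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(rho), tolerance = 1e-6,
               ignore_attr = TRUE)
  np <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cluster_samples(rho), np)
  expect_true(grepl("^\\(", readLines(np)[1]))
})
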