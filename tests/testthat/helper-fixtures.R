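# Shared fixture builders and independent oracles.

# Tiny expression matrix with explicit values.
toy_expression <- function(values, scale = "fpkm", labs = NULL, conditions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  meta <- data.frame(sample = colnames(values), species = "human",
                     lab = labs %||% "L1",
                     condition = conditions %||% "c",
                     replicate = seq_len(ncol(values)),
                     stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force uniform-gene selection: explicit per-sample interval
# membership, intersected over samples.
oracle_uniform_genes <- function(values, lower = 0.5, upper = 0.9) {
  keep <- rep(TRUE, nrow(values))
  for (j in seq_len(ncol(values))) {
    lo <- quantile(values[, j], lower, type = 7, names = FALSE)
    hi <- quantile(values[, j], upper, type = 7, names = FALSE)
    ok <- values[, j] >= lo & values[, j] <= hi
    if (lo <= 0) ok <- ok & values[, j] > 0
    keep <- keep & ok
  }
  rownames(values)[keep]
}

# Brute-force UPGMA: average linkage recomputed from the full distance
# matrix at every merge (O(n^3), fine for toys). Returns sorted merge
# heights.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Simple tracks fixture: one cell per row-list of positions.
tracks_from_positions <- function(pos_list, dt = 1, source = c(0, 0), stimulus_time = 0) {
  tracks <- do.call(rbind, lapply(seq_along(pos_list), function(i) {
    p <- pos_list[[i]]
    data.frame(cell = sprintf("c%02d", i), time = (seq_len(nrow(p)) - 1) * dt,
               x = p[, 1], y = p[, 2])
  }))
  track_set(tracks, source = source, stimulus_time = stimulus_time)
}

# Straight-line track aimed at the source from a given start.
aimed_track <- function(start, source, n_steps, step = 2) {
  dir <- (source - start) / sqrt(sum((source - start)^2))
  t(sapply(0:n_steps, function(k) start + k * step * dir))
}
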