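#' Segment nuclei by intensity threshold
#'
#' Foreground is every pixel strictly above `intensity_threshold`;
#' connected foreground components (8-connected by default) become
#' candidate nuclei, and components smaller than `min_area_px` pixels
#' are discarded as debris. The number of discarded objects is
#' reported via `message()`.
#'
#' @param image 2-D numeric matrix, the nuclear-stain channel.
#' @param intensity_threshold Foreground threshold (required; see
#'   [otsu_threshold()] for an automatic convenience).
#' @param min_area_px Minimum object area in pixels, inclusive
#'   (default 100).
#' @param connectivity 8 (default) or 4.
#' @return A `labeled_objects`: list with `objects` (data frame label,
#'   area_px, centroid_x, centroid_y) and the integer `labels` matrix
#'   (0 = background).
#' @export
segment_nuclei <- function(image, intensity_threshold, min_area_px = 100,
                           connectivity = 8) {
  image <- as.matrix(image)
  if (!is.numeric(image) || length(dim(image)) != 2L)
    stop_input("image must be a 2-D numeric matrix")
  if (!connectivity %in% c(4, 8)) stop_input("connectivity must be 4 or 8")
  if (intensity_threshold >= max(image)) {
    warning("threshold at or above the image maximum; no objects found", call. = FALSE)
    return(empty_objects(dim(image)))
  }
  bw <- image > intensity_threshold
  labels <- EBImage::imageData(EBImage::bwlabel(bw))
  labels <- matrix(as.integer(round(labels)), nrow = nrow(image))
  if (connectivity == 8) labels <- merge_diagonal(labels)

  areas <- tabulate(labels)
  small <- which(areas > 0 & areas < min_area_px)
  if (length(small) > 0L) {
    message(length(small), " object(s) below ", min_area_px, " px discarded as debris")
    labels[labels %in% small] <- 0L
  }
  kept <- which(tabulate(labels) >= min_area_px)
  if (length(kept) == 0L) return(empty_objects(dim(image)))

  # compact labels to 1..n
  relab <- integer(max(labels))
  relab[kept] <- seq_along(kept)
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]

  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  objects <- data.frame(
    label = seq_along(kept),
    area_px = as.vector(tabulate(lab, nbins = length(kept))),
    centroid_x = as.vector(tapply(cols, lab, mean)),
    centroid_y = as.vector(tapply(rows, lab, mean)))
  structure(list(objects = objects, labels = labels), class = "labeled_objects")
}

empty_objects <- function(dims) {
  structure(list(objects = data.frame(label = integer(0), area_px = integer(0),
                                      centroid_x = numeric(0), centroid_y = numeric(0)),
                 labels = matrix(0L, dims[1], dims[2])),
            class = "labeled_objects")
}

# Union labels that touch only diagonally (bwlabel is 4-connected).
merge_diagonal <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  if (nr < 2L || nc < 2L || max(labels) == 0L) return(labels)
  p1 <- rbind(cbind(as.vector(labels[-nr, -nc]), as.vector(labels[-1, -1])),
              cbind(as.vector(labels[-nr, -1]), as.vector(labels[-1, -nc])))
  p1 <- p1[p1[, 1] > 0L & p1[, 2] > 0L & p1[, 1] != p1[, 2], , drop = FALSE]
  if (nrow(p1) == 0L) return(labels)
  parent <- seq_len(max(labels))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(p1))) {
    a <- find(p1[k, 1]); b <- find(p1[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  pos <- labels > 0L
  labels[pos] <- root[labels[pos]]
  labels
}

#' Otsu automatic threshold (convenience extension)
#'
#' Maximizes between-class variance over a 256-level quantization of
#' the image range. Provided as a convenience where no manual
#' threshold is available; the core segmentation takes an explicit
#' threshold.
#'
#' @param image 2-D numeric matrix.
#' @return A scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(as.matrix(image))
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(floor((v - r[1]) / diff(r) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  k <- which.max(replace(sigma_b, !is.finite(sigma_b), -Inf))
  r[1] + k / 256 * diff(r)
}

#' Exclude dead cells from segmented nuclei
#'
#' Dead cells are identified on a co-registered viability channel
#' (a membrane-impermeable DNA stain): objects whose mean viability
#' intensity exceeds the threshold are removed.
#'
#' @param seg A `labeled_objects` from [segment_nuclei()].
#' @param viability_image 2-D matrix, same shape as the segmented image.
#' @param viability_threshold Objects with mean viability intensity
#'   strictly above this are dropped.
#' @return A `labeled_objects` with dead objects removed; the `objects`
#'   table gains a `mean_viability` column.
#' @export
exclude_dead <- function(seg, viability_image, viability_threshold) {
  stopifnot(inherits(seg, "labeled_objects"))
  viability_image <- as.matrix(viability_image)
  if (!identical(dim(viability_image), dim(seg$labels)))
    stop_input("viability image shape differs from the segmented image")
  if (nrow(seg$objects) == 0L) return(seg)
  idx <- which(seg$labels > 0L)
  mv <- tapply(viability_image[idx], seg$labels[idx], mean)
  objects <- seg$objects
  objects$mean_viability <- as.vector(mv[as.character(objects$label)])
  alive <- objects$mean_viability <= viability_threshold
  labels <- seg$labels
  labels[labels %in% objects$label[!alive]] <- 0L
  structure(list(objects = objects[alive, , drop = FALSE], labels = labels),
            class = "labeled_objects")
}

#' Convert pixel areas to square micrometres
#'
#' @param objects A `labeled_objects` or its `objects` data frame.
#' @param pixel_size_um Physical pixel size in micrometres (default
#'   0.4389).
#' @return Numeric vector of per-object areas in um^2
#'   (`area_px * pixel_size_um^2`).
#' @export
areas_um2 <- function(objects, pixel_size_um = 0.4389) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be positive")
  tab <- if (inherits(objects, "labeled_objects")) objects$objects else objects
  tab$area_px * pixel_size_um^2
}
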