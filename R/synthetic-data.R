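#' Seeded synthetic-data generators
#'
#' Every downstream stage of the toolkit can be exercised without any
#' download: these generators produce expression matrices, cytometry
#' event tables, cell tracks, genotype tables and nuclei images with
#' the statistical structure the analyses assume, and carry hidden
#' truth labels so tests can check parameter recovery. All generators
#' are deterministic for a fixed seed.
#'
#' @name synthetic-data
NULL

#' Specification for a synthetic expression matrix
#'
#' Expression is drawn log-normal on the log10 scale and
#' exponentiated: each gene gets a baseline log10 level, each lab an
#' optional systematic offset, and a designated "neutrophil signature"
#' gene subset is shifted per condition by `differentiation_shift`, so
#' that the rank correlation of a condition with a strongly shifted
#' template condition grows with its own shift. Zeros are injected by
#' masking the lowest-expressed genes of each sample, mimicking
#' dropout of lowly expressed genes.
#'
#' @param n_genes Number of genes.
#' @param samples Data frame with one row per sample: columns
#'   `species`, `lab`, `condition`, `replicate`, `day` (and optionally
#'   `sample` names and a `reference_group` flag).
#' @param baseline_logmean,baseline_logsd Location/scale of the per-gene
#'   baseline log10-FPKM distribution.
#' @param differentiation_shift Named numeric vector of log10 effects
#'   per condition, applied to the signature genes; conditions absent
#'   from the vector get 0.
#' @param signature_fraction Fraction of genes in the signature subset.
#' @param zero_fraction Proportion of zero-expression genes per sample.
#' @param lab_effect_sd Log10 SD of lab-level systematic offsets.
#' @param noise_sd Log10 SD of residual per-measurement noise.
#' @param seed Integer seed.
#' @return An `expression_gen_spec` list.
#' @export
expression_gen_spec <- function(n_genes, samples, baseline_logmean = 0.5,
                                baseline_logsd = 1, differentiation_shift = NULL,
                                signature_fraction = 0.2, zero_fraction = 0,
                                lab_effect_sd = 0, noise_sd = 0.15, seed = 1) {
  check_count(n_genes, "n_genes")
  samples <- as.data.frame(samples)
  need <- c("species", "lab", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop_input("samples needs columns ", paste(need, collapse = ", "))
  if (!is.numeric(zero_fraction) || zero_fraction < 0 || zero_fraction >= 1)
    stop_input("zero_fraction must lie in [0, 1)")
  check_fraction(signature_fraction, "signature_fraction")
  if (baseline_logsd < 0 || lab_effect_sd < 0 || noise_sd < 0)
    stop_input("scale parameters must be nonnegative")
  structure(list(n_genes = as.integer(n_genes), samples = samples,
                 baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
                 differentiation_shift = differentiation_shift %||% numeric(0),
                 signature_fraction = signature_fraction,
                 zero_fraction = zero_fraction, lab_effect_sd = lab_effect_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "expression_gen_spec")
}

#' Generate a synthetic expression matrix
#'
#' @param spec An [expression_gen_spec()].
#' @return An `expression_matrix` (FPKM scale). The signature gene ids
#'   are attached as attribute `"signature_genes"` (hidden truth).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_gen_spec"))
  s <- spec$samples
  if (is.null(s$sample))
    s$sample <- make.unique(paste0(s$condition, "_", s$lab, "_r", s$replicate), sep = "_")
  if (is.null(s$day)) s$day <- NA_real_
  if (is.null(s$reference_group)) s$reference_group <- FALSE

  withr::with_seed(spec$seed, {
    ids <- sprintf("gene%05d", seq_len(spec$n_genes))
    mu <- stats::rnorm(spec$n_genes, spec$baseline_logmean, spec$baseline_logsd)
    n_sig <- round(spec$signature_fraction * spec$n_genes)
    signature <- sort(sample.int(spec$n_genes, n_sig))
    labs <- unique(s$lab)
    lab_off <- stats::setNames(stats::rnorm(length(labs), 0, spec$lab_effect_sd), labs)
    shift <- spec$differentiation_shift

    logv <- sapply(seq_len(nrow(s)), function(j) {
      v <- mu + lab_off[[s$lab[j]]] +
        stats::rnorm(spec$n_genes, 0, spec$noise_sd)
      sh <- if (s$condition[j] %in% names(shift)) shift[[s$condition[j]]] else 0
      v[signature] <- v[signature] + sh
      v
    })
    values <- 10^matrix(logv, nrow = spec$n_genes,
                        dimnames = list(ids, s$sample))
    n_zero <- round(spec$zero_fraction * spec$n_genes)
    if (n_zero > 0L) {
      for (j in seq_len(ncol(values)))
        values[order(values[, j])[seq_len(n_zero)], j] <- 0
    }
  })
  out <- expression_matrix(values, s, scale = "fpkm")
  attr(out, "signature_genes") <- ids[signature]
  out
}

#' Specification for a synthetic cytometry sample
#'
#' A two-component log-normal intensity mixture on the marker channel
#' (negative and positive populations, separation
#' `pos_location - neg_location` on the log10 scale) plus a viability
#' channel in which a fraction `f_dead` of events come from a bright
#' "dead" component. A matched unstained control is drawn from the
#' negative component. Both channels receive the additive
#' `autofluorescence_mean` offset on the intensity scale.
#'
#' @param n_events Events per sample.
#' @param f_positive Fraction of marker-positive events.
#' @param neg_location,neg_scale,pos_location,pos_scale Log10-intensity
#'   mixture parameters of the marker channel.
#' @param autofluorescence_mean Additive intensity offset.
#' @param f_dead Fraction of dead events on the viability channel.
#' @param live_location,dead_location,viability_scale Log10-intensity
#'   parameters of the viability channel components.
#' @param seed Integer seed.
#' @return A `cytometry_gen_spec` list.
#' @export
cytometry_gen_spec <- function(n_events = 10000, f_positive = 0.5,
                               neg_location = 1, neg_scale = 0.3,
                               pos_location = 2.5, pos_scale = 0.3,
                               autofluorescence_mean = 0, f_dead = 0,
                               live_location = 1, dead_location = 3,
                               viability_scale = 0.25, seed = 1) {
  check_count(n_events, "n_events")
  check_fraction(f_positive, "f_positive")
  check_fraction(f_dead, "f_dead")
  if (neg_scale <= 0 || pos_scale <= 0 || viability_scale <= 0)
    stop_input("scale parameters must be positive")
  structure(list(n_events = as.integer(n_events), f_positive = f_positive,
                 neg_location = neg_location, neg_scale = neg_scale,
                 pos_location = pos_location, pos_scale = pos_scale,
                 autofluorescence_mean = autofluorescence_mean, f_dead = f_dead,
                 live_location = live_location, dead_location = dead_location,
                 viability_scale = viability_scale, seed = seed),
            class = "cytometry_gen_spec")
}

#' Generate a synthetic stained sample and its unstained control
#'
#' @param spec A [cytometry_gen_spec()].
#' @return List with `stained` and `unstained` `cytometry_table`s
#'   (channels `"marker"` and `"viability"`); the stained table's
#'   `truth` records per-event `positive` and `dead` flags.
#' @export
gen_cytometry <- function(spec) {
  stopifnot(inherits(spec, "cytometry_gen_spec"))
  n <- spec$n_events
  withr::with_seed(spec$seed, {
    positive <- stats::runif(n) < spec$f_positive
    dead <- stats::runif(n) < spec$f_dead
    marker <- 10^stats::rnorm(n, ifelse(positive, spec$pos_location, spec$neg_location),
                              ifelse(positive, spec$pos_scale, spec$neg_scale))
    viability <- 10^stats::rnorm(n, ifelse(dead, spec$dead_location, spec$live_location),
                                 spec$viability_scale)
    # the unstained control carries neither stain: both channels show
    # only the negative/live-level signal, so gates derived from it sit
    # just above the corresponding negative component
    ctrl_marker <- 10^stats::rnorm(n, spec$neg_location, spec$neg_scale)
    ctrl_viability <- 10^stats::rnorm(n, spec$live_location, spec$viability_scale)
  })
  af <- spec$autofluorescence_mean
  stained <- cytometry_table(
    cbind(marker = marker + af, viability = viability + af),
    role = "stained",
    truth = data.frame(positive = positive, dead = dead))
  unstained <- cytometry_table(
    cbind(marker = ctrl_marker + af, viability = ctrl_viability + af),
    role = "unstained_control")
  list(stained = stained, unstained = unstained)
}

#' Specification for synthetic chemotaxis tracks
#'
#' Cells start scattered around the gradient source and take steps of
#' Gaussian length. Before the stimulus every step direction is
#' uniform; afterwards, responder cells draw step angles from a von
#' Mises distribution centred on the instantaneous direction to the
#' source (concentration `directional_concentration`; 0 degenerates to
#' uniform), while non-responders keep moving with uniform random
#' directions. With `angle_mode = "cell"` each responder instead keeps
#' one persistent post-stimulus heading drawn once from the same
#' distribution.
#'
#' @param n_cells,n_frames Track-set size (`n_frames >= 2`).
#' @param frame_interval Seconds between frames.
#' @param speed_mean,speed_sd Step displacement per interval, um.
#' @param directional_concentration Nonnegative von Mises
#'   concentration of responder step angles.
#' @param f_responder Fraction of responder cells.
#' @param source Gradient-source (x, y), um.
#' @param stimulus_time Uncaging time in seconds; defaults to half the
#'   track duration.
#' @param arena_radius Cells start uniformly in an annulus between
#'   `min_start_distance` and this radius around the source, um.
#' @param min_start_distance Minimum starting distance from the source.
#' @param angle_mode `"step"` (default) or `"cell"`, see above.
#' @param seed Integer seed.
#' @return A `track_gen_spec` list.
#' @export
track_gen_spec <- function(n_cells = 100, n_frames = 20, frame_interval = 30,
                           speed_mean = 5, speed_sd = 1.5,
                           directional_concentration = 2, f_responder = 1,
                           source = c(0, 0), stimulus_time = NULL,
                           arena_radius = 300, min_start_distance = 100,
                           angle_mode = c("step", "cell"), seed = 1) {
  check_count(n_cells, "n_cells")
  check_count(n_frames, "n_frames", min = 2L)
  check_fraction(f_responder, "f_responder")
  if (directional_concentration < 0) stop_input("directional_concentration must be >= 0")
  if (frame_interval <= 0) stop_input("frame_interval must be positive")
  angle_mode <- match.arg(angle_mode)
  stimulus_time <- stimulus_time %||% (floor(n_frames / 2) * frame_interval)
  structure(list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, speed_mean = speed_mean,
                 speed_sd = speed_sd,
                 directional_concentration = directional_concentration,
                 f_responder = f_responder, source = as.numeric(source),
                 stimulus_time = stimulus_time, arena_radius = arena_radius,
                 min_start_distance = min_start_distance,
                 angle_mode = angle_mode, seed = seed),
            class = "track_gen_spec")
}

#' Generate synthetic chemotaxis tracks
#'
#' @param spec A [track_gen_spec()].
#' @return A `track_set`; `truth` is a data frame with the per-cell
#'   `responder` flag.
#' @export
gen_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_gen_spec"))
  nc <- spec$n_cells; nf <- spec$n_frames
  withr::with_seed(spec$seed, {
    responder <- stats::runif(nc) < spec$f_responder
    r0 <- sqrt(stats::runif(nc, spec$min_start_distance^2, spec$arena_radius^2))
    th0 <- stats::runif(nc, 0, 2 * pi)
    x <- matrix(NA_real_, nc, nf); y <- matrix(NA_real_, nc, nf)
    x[, 1] <- spec$source[1] + r0 * cos(th0)
    y[, 1] <- spec$source[2] + r0 * sin(th0)
    persistent <- rep(NA_real_, nc)
    times <- (seq_len(nf) - 1) * spec$frame_interval
    for (k in seq_len(nf - 1)) {
      post <- times[k] >= spec$stimulus_time
      to_src <- atan2(spec$source[2] - y[, k], spec$source[1] - x[, k])
      ang <- stats::runif(nc, -pi, pi)
      if (post) {
        biased <- which(responder)
        if (length(biased) > 0L && spec$directional_concentration > 0) {
          if (spec$angle_mode == "step") {
            err <- rvonmises(length(biased), 0, spec$directional_concentration)
            ang[biased] <- to_src[biased] + err
          } else {
            new_head <- is.na(persistent[biased])
            if (any(new_head)) {
              err <- rvonmises(sum(new_head), 0, spec$directional_concentration)
              persistent[biased[new_head]] <- to_src[biased[new_head]] + err
            }
            ang[biased] <- persistent[biased]
          }
        }
      }
      step <- pmax(stats::rnorm(nc, spec$speed_mean, spec$speed_sd), 0)
      x[, k + 1] <- x[, k] + step * cos(ang)
      y[, k + 1] <- y[, k] + step * sin(ang)
    }
  })
  tracks <- data.frame(cell = rep(sprintf("cell%04d", seq_len(nc)), each = nf),
                       time = rep(times, nc),
                       x = as.vector(t(x)), y = as.vector(t(y)))
  track_set(tracks, source = spec$source, stimulus_time = spec$stimulus_time,
            truth = data.frame(cell = sprintf("cell%04d", seq_len(nc)),
                               responder = responder))
}

#' Specification for a synthetic genotype table
#'
#' Samples are partitioned into identity groups; samples in the same
#' group receive identical genotypes at every locus. Each non-first
#' group differs from the first group at a random
#' `discordance_between_groups` fraction of loci, so the pairwise
#' identity between the first group and any other is about
#' `1 - discordance_between_groups`.
#'
#' @param n_loci Number of loci.
#' @param sample_groups Named list partitioning sample names into
#'   identity groups, e.g. `list(hl60 = c("a", "b"), donor = "c")`.
#' @param depth_mean Expected per-sample read depth (Poisson).
#' @param qual_range Length-2 bounds for uniform site quality.
#' @param discordance_between_groups Fraction of loci at which a
#'   non-reference group's genotype differs from the first group's.
#' @param seed Integer seed.
#' @return A `genotype_gen_spec` list.
#' @export
genotype_gen_spec <- function(n_loci = 1000, sample_groups, depth_mean = 30,
                              qual_range = c(150, 3000),
                              discordance_between_groups = 0, seed = 1) {
  check_count(n_loci, "n_loci")
  if (!is.list(sample_groups) || length(sample_groups) == 0L)
    stop_input("sample_groups must be a nonempty list")
  if (any(lengths(sample_groups) == 0L)) stop_input("empty identity group")
  if (anyDuplicated(unlist(sample_groups))) stop_input("duplicate sample names")
  check_fraction(discordance_between_groups, "discordance_between_groups")
  if (depth_mean <= 0) stop_input("depth_mean must be positive")
  structure(list(n_loci = as.integer(n_loci), sample_groups = sample_groups,
                 depth_mean = depth_mean, qual_range = qual_range,
                 discordance_between_groups = discordance_between_groups,
                 seed = seed),
            class = "genotype_gen_spec")
}

#' Generate a synthetic genotype table
#'
#' @param spec A [genotype_gen_spec()].
#' @return A `genotype_table`; the group partition is attached as
#'   attribute `"groups"` (hidden truth).
#' @export
gen_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_gen_spec"))
  groups <- spec$sample_groups
  samples <- unlist(groups, use.names = FALSE)
  codes <- c("0/0", "0/1", "1/1")
  n <- spec$n_loci
  withr::with_seed(spec$seed, {
    base <- sample(codes, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    group_gt <- list(base)
    if (length(groups) > 1L) {
      for (g in 2:length(groups)) {
        gt <- base
        flip <- stats::runif(n) < spec$discordance_between_groups
        gt[flip] <- vapply(base[flip], function(b) sample(setdiff(codes, b), 1),
                           character(1))
        group_gt[[g]] <- gt
      }
    }
    gt <- matrix(NA_character_, n, length(samples),
                 dimnames = list(NULL, samples))
    for (g in seq_along(groups)) gt[, groups[[g]]] <- group_gt[[g]]
    dp <- matrix(stats::rpois(n * length(samples), spec$depth_mean), n,
                 dimnames = list(NULL, samples))
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
    loci <- data.frame(chrom = "chr1", pos = sort(sample.int(n * 100, n)),
                       ref = ref, alt = alt,
                       qual = stats::runif(n, spec$qual_range[1], spec$qual_range[2]),
                       stringsAsFactors = FALSE)
  })
  out <- genotype_table(loci, gt, dp)
  attr(out, "groups") <- groups
  out
}

#' Specification for a synthetic nuclei image pair
#'
#' Elliptical nuclei with log-normal pixel areas are placed without
#' overlap (a one-pixel separation margin keeps objects disconnected);
#' a fraction `f_dead` of nuclei is additionally painted on the
#' viability channel, emulating a membrane-impermeable DNA stain.
#' Intensities are on a 16-bit scale.
#'
#' @param image_size Side length in pixels (square image).
#' @param n_nuclei Number of nuclei (0 gives a blank image).
#' @param area_logmean,area_logsd Log10 pixel-area distribution.
#' @param f_dead Fraction of dead nuclei.
#' @param background,foreground Intensity levels (0..65535).
#' @param max_tries Placement retries per nucleus before giving up.
#' @param seed Integer seed.
#' @return A `nuclei_image_spec` list.
#' @export
nuclei_image_spec <- function(image_size = 256, n_nuclei = 20,
                              area_logmean = log10(300), area_logsd = 0.12,
                              f_dead = 0, background = 500, foreground = 20000,
                              max_tries = 200, seed = 1) {
  check_count(image_size, "image_size", min = 8L)
  check_count(n_nuclei, "n_nuclei", min = 0L)
  check_fraction(f_dead, "f_dead")
  if (background < 0 || foreground > 65535 || foreground <= background)
    stop_input("need 0 <= background < foreground <= 65535")
  structure(list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
                 area_logmean = area_logmean, area_logsd = area_logsd,
                 f_dead = f_dead, background = background, foreground = foreground,
                 max_tries = max_tries, seed = seed),
            class = "nuclei_image_spec")
}

#' Generate a synthetic two-channel nuclei image
#'
#' @param spec A [nuclei_image_spec()].
#' @return List with `nuclear` and `viability` image matrices and a
#'   `truth` data frame (id, area_px, centroid_x, centroid_y, dead).
#' @export
gen_nuclei_image <- function(spec) {
  stopifnot(inherits(spec, "nuclei_image_spec"))
  sz <- spec$image_size
  nuclear <- matrix(spec$background, sz, sz)
  viability <- matrix(spec$background, sz, sz)
  truth <- data.frame(id = integer(0), area_px = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      dead = logical(0))
  if (spec$n_nuclei == 0L)
    return(list(nuclear = nuclear, viability = viability, truth = truth))

  withr::with_seed(spec$seed, {
    dead <- stats::runif(spec$n_nuclei) < spec$f_dead
    occupied <- matrix(FALSE, sz, sz)
    colgrid <- matrix(rep(seq_len(sz), each = sz), sz, sz)
    rowgrid <- matrix(rep(seq_len(sz), sz), sz, sz)
    placed <- 0L
    for (i in seq_len(spec$n_nuclei)) {
      target_area <- 10^stats::rnorm(1, spec$area_logmean, spec$area_logsd)
      ratio <- stats::runif(1, 0.6, 1)
      a <- sqrt(target_area / (pi * ratio)); b <- a * ratio
      phi <- stats::runif(1, 0, pi)
      ok <- FALSE
      for (try in seq_len(spec$max_tries)) {
        cx <- stats::runif(1, a + 2, sz - a - 2)
        cy <- stats::runif(1, a + 2, sz - a - 2)
        dx <- colgrid - cx; dy <- rowgrid - cy
        u <- dx * cos(phi) + dy * sin(phi)
        v <- -dx * sin(phi) + dy * cos(phi)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        # 1-px dilation margin so neighbouring objects never touch
        margin <- (u / (a + 1.6))^2 + (v / (b + 1.6))^2 <= 1
        if (!any(margin & occupied)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place nucleus ", i, " without overlap after ",
                    spec$max_tries, " tries; reduce n_nuclei or area", call. = FALSE)
      occupied <- occupied | margin
      nuclear[inside] <- spec$foreground
      if (dead[i]) viability[inside] <- spec$foreground
      placed <- placed + 1L
      truth <- rbind(truth, data.frame(
        id = placed, area_px = sum(inside),
        centroid_x = mean(colgrid[inside]), centroid_y = mean(rowgrid[inside]),
        dead = dead[i]))
    }
  })
  list(nuclear = nuclear, viability = viability, truth = truth)
}
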