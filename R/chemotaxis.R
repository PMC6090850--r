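#' Cell trajectory set for under-agarose chemotaxis
#'
#' Time-ordered positions per cell together with the gradient-source
#' point (the chemoattractant uncaging spot) and the stimulus time.
#' Spatial units are micrometres, time is seconds.
#'
#' @param tracks Data frame with columns `cell`, `time`, `x`, `y`.
#'   Times must be strictly increasing within each cell and every
#'   retained cell needs at least two points.
#' @param source Numeric length-2 vector, the (x, y) of the gradient
#'   source.
#' @param stimulus_time Time of gradient generation (uncaging).
#' @param truth Optional per-cell hidden labels (synthetic data only).
#' @return A `track_set` object.
#' @export
track_set <- function(tracks, source, stimulus_time, truth = NULL) {
  tracks <- as.data.frame(tracks)
  need <- c("cell", "time", "x", "y")
  if (!all(need %in% names(tracks))) stop_input("tracks needs columns cell, time, x, y")
  if (length(source) != 2L || !is.numeric(source)) stop_input("source must be (x, y)")
  split_times <- split(tracks$time, tracks$cell)
  if (any(vapply(split_times, function(t) any(diff(t) <= 0), logical(1))))
    stop_input("time must be strictly increasing within each cell")
  if (any(vapply(split_times, length, integer(1)) < 2L))
    stop_input("each cell needs at least two points")
  structure(list(tracks = tracks, source = as.numeric(source),
                 stimulus_time = stimulus_time, truth = truth),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d cells, %d points, stimulus at t = %g s\n",
              length(unique(x$tracks$cell)), nrow(x$tracks), x$stimulus_time))
  invisible(x)
}

#' Convenience windows around the stimulus
#'
#' Steps are assigned to a window by their start time; the pre-stimulus
#' window is \[-Inf, stimulus_time) and the post-stimulus window is
#' \[stimulus_time, Inf\], so the step beginning at the uncaging frame
#' itself belongs to "after".
#'
#' @param x A `track_set`.
#' @return Numeric length-2 window (start, end).
#' @export
pre_window <- function(x) c(-Inf, x$stimulus_time)

#' @rdname pre_window
#' @export
post_window <- function(x) c(x$stimulus_time, Inf)

# Internal: per-step table with start time, displacement and the
# direction to the source from the step's start point.
step_table <- function(x, window) {
  tr <- x$tracks[order(x$tracks$cell, x$tracks$time), , drop = FALSE]
  same <- tr$cell[-1] == tr$cell[-nrow(tr)]
  i <- which(same)
  steps <- data.frame(
    cell = tr$cell[i], t0 = tr$time[i], dt = tr$time[i + 1] - tr$time[i],
    dx = tr$x[i + 1] - tr$x[i], dy = tr$y[i + 1] - tr$y[i],
    sx = x$source[1] - tr$x[i], sy = x$source[2] - tr$y[i])
  steps[steps$t0 >= window[1] & steps$t0 < window[2], , drop = FALSE]
}

#' Per-step angles to the gradient source
#'
#' For each consecutive position pair whose start time lies in the
#' window, the absolute angle (degrees, in \[0, 180\]) between the
#' displacement vector and the vector from the step's start point to
#' the source: 0 means straight at the source, 180 straight away.
#' Zero-length displacements carry no direction and are skipped, as are
#' steps starting exactly at the source.
#'
#' @param x A `track_set`.
#' @param window Length-2 numeric (start, end); steps are included when
#'   `start <= t0 < end`. Defaults to the post-stimulus window.
#' @return Numeric vector of angles with the cell id as names; empty
#'   (with a warning) if no step falls in the window.
#' @export
step_angles <- function(x, window = post_window(x)) {
  stopifnot(inherits(x, "track_set"))
  st <- step_table(x, window)
  if (nrow(st) == 0L) {
    warning("no steps inside the window", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  dn <- sqrt(st$dx^2 + st$dy^2)
  sn <- sqrt(st$sx^2 + st$sy^2)
  ok <- dn > 0 & sn > 0
  st <- st[ok, , drop = FALSE]
  cosang <- (st$dx * st$sx + st$dy * st$sy) / (dn[ok] * sn[ok])
  # snap numerically (anti)parallel steps so they score exactly 0 / 180
  cosang[cosang > 1 - 1e-12] <- 1
  cosang[cosang < -1 + 1e-12] <- -1
  stats::setNames(degrees(acos(cosang)), st$cell)
}

#' Angular bias of movement towards the gradient source
#'
#' The directionality statistic: each step scores `90 - angle` degrees
#' (angle as in [step_angles()]), scores are averaged within each cell,
#' and the population value is the mean over cells (`per = "step"`
#' pools all steps instead). Movement straight at the source scores
#' exactly 90, straight away -90, and uniformly random directions have
#' expectation 0.
#'
#' @param x A `track_set`.
#' @param window Analysis window, defaults to post-stimulus.
#' @param per `"cell"` (default): average per cell, then over cells;
#'   `"step"`: average over all pooled steps.
#' @return A `directionality_summary`: list with `angular_bias`
#'   (degrees in \[-90, 90\]), `per_cell` (named per-cell biases),
#'   `n_cells`, `n_steps`, `sem` and the `window` used.
#' @export
angular_bias <- function(x, window = post_window(x), per = c("cell", "step")) {
  per <- match.arg(per)
  ang <- step_angles(x, window)
  if (length(ang) == 0L) stop_input("no usable steps in the window")
  scores <- 90 - ang
  per_cell <- tapply(scores, names(scores), mean)
  bias <- if (per == "cell") mean(per_cell) else mean(scores)
  n <- if (per == "cell") length(per_cell) else length(scores)
  sem <- if (per == "cell") stats::sd(per_cell) / sqrt(n) else stats::sd(scores) / sqrt(n)
  structure(list(angular_bias = unname(bias), per_cell = per_cell,
                 n_cells = length(per_cell), n_steps = length(scores),
                 sem = unname(sem), window = window, per = per),
            class = "directionality_summary")
}

#' @export
print.directionality_summary <- function(x, ...) {
  cat(sprintf("angular bias: %.2f degrees (SEM %.2f; %d cells, %d steps)\n",
              x$angular_bias, x$sem, x$n_cells, x$n_steps))
  invisible(x)
}

#' Mean cell speed in a time window
#'
#' Per-cell speed is the total path length of the cell's steps in the
#' window divided by the elapsed time of those steps, converted to
#' micrometres per minute; the population value is the mean over cells.
#' Zero-displacement steps contribute zero length but full elapsed
#' time.
#'
#' @param x A `track_set`.
#' @param window Analysis window, defaults to post-stimulus.
#' @return List with `mean_speed` (um/min), `per_cell` and `n_cells`.
#' @export
mean_speed <- function(x, window = post_window(x)) {
  stopifnot(inherits(x, "track_set"))
  st <- step_table(x, window)
  if (nrow(st) == 0L) stop_input("no steps inside the window")
  if (any(tapply(st$dt, st$cell, sum) <= 0)) stop_input("zero elapsed time")
  len <- tapply(sqrt(st$dx^2 + st$dy^2), st$cell, sum)
  dur <- tapply(st$dt, st$cell, sum)
  per_cell <- 60 * len / dur
  list(mean_speed = mean(per_cell), per_cell = per_cell, n_cells = length(per_cell))
}

#' Histogram of instantaneous direction angles
#'
#' Equal-width bins covering \[0, 180\] degrees; bins are left-closed,
#' with the last bin closed on the right so 180 is counted.
#'
#' @param angles Numeric vector of step angles in \[0, 180\].
#' @param n_bins Number of bins (default 18, i.e. 10-degree bins).
#' @return List with integer `counts` (sums to `length(angles)`),
#'   `breaks` and bin `mids`.
#' @export
direction_histogram <- function(angles, n_bins = 18) {
  check_count(n_bins, "n_bins")
  if (length(angles) == 0L) stop_input("empty angle vector")
  if (any(angles < 0 | angles > 180)) stop_input("angles must lie in [0, 180]")
  width <- 180 / n_bins
  idx <- pmin(floor(angles / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  breaks <- seq(0, 180, length.out = n_bins + 1)
  list(counts = counts, breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}

#' Simulate the step angles of a mixed responder population
#'
#' Models a population in which only a fraction of cells express the
#' chemoattractant receptor: each simulated cell is a responder with
#' probability `f_responder`; responder step angles are resampled with
#' replacement from an empirical responder angle sample (e.g. primary
#' neutrophil steps), non-responder angles are uniform on \[0, 180\].
#' The closed-form expected histogram of the mixture is returned
#' alongside the simulated sample.
#'
#' @param responder_angles Nonempty numeric vector of empirical
#'   responder step angles (degrees in \[0, 180\]).
#' @param f_responder Fraction of responder cells in \[0, 1\].
#' @param n_cells,steps_per_cell Simulated population size.
#' @param seed Integer seed (deterministic output).
#' @param n_bins Bins for the returned histograms.
#' @return List with `angles` (data frame cell, angle, responder),
#'   `histogram` (simulated counts), `expected` (expected counts under
#'   the mixture: `f * empirical + (1 - f) * uniform`), and `breaks`.
#' @export
simulate_mixed_population <- function(responder_angles, f_responder, n_cells,
                                      steps_per_cell, seed, n_bins = 18) {
  if (length(responder_angles) == 0L) stop_input("responder_angles is empty")
  check_fraction(f_responder, "f_responder")
  check_count(n_cells, "n_cells")
  check_count(steps_per_cell, "steps_per_cell")
  withr::with_seed(seed, {
    responder <- stats::runif(n_cells) < f_responder
    n_steps <- n_cells * steps_per_cell
    is_resp <- rep(responder, each = steps_per_cell)
    ang <- numeric(n_steps)
    ang[is_resp] <- sample(responder_angles, sum(is_resp), replace = TRUE)
    ang[!is_resp] <- stats::runif(sum(!is_resp), 0, 180)
  })
  hist_sim <- direction_histogram(ang, n_bins)
  hist_emp <- direction_histogram(responder_angles, n_bins)
  p_emp <- hist_emp$counts / sum(hist_emp$counts)
  expected <- n_steps * (f_responder * p_emp + (1 - f_responder) / n_bins)
  list(angles = data.frame(cell = rep(seq_len(n_cells), each = steps_per_cell),
                           angle = ang, responder = is_resp),
       histogram = hist_sim$counts, expected = expected, breaks = hist_sim$breaks)
}

#' Read / write cell track tables as CSV
#'
#' Column dialect: `cell_id, frame, time_s, x_um, y_um`. The gradient
#' source and stimulus time travel as arguments, not in the file.
#'
#' @param path CSV path.
#' @param source,stimulus_time See [track_set()].
#' @return `read_tracks_csv` returns a `track_set`.
#' @export
read_tracks_csv <- function(path, source, stimulus_time) {
  tab <- utils::read.csv(path)
  track_set(data.frame(cell = tab$cell_id, time = tab$time_s, x = tab$x_um, y = tab$y_um),
            source = source, stimulus_time = stimulus_time)
}

#' @param x A `track_set`.
#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(x, path) {
  tr <- x$tracks[order(x$tracks$cell, x$tracks$time), , drop = FALSE]
  frame <- stats::ave(tr$time, tr$cell, FUN = seq_along) - 1
  out <- data.frame(cell_id = tr$cell, frame = frame, time_s = tr$time,
                    x_um = tr$x, y_um = tr$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
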