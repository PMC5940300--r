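#' Simulate one cell's licensing trajectory through G1
#'
#' Deterministic trajectory of the origin-licensing fraction of a single
#' cell moving through G1. The cell enters G1, waits through any unlicensed
#' G1 period, then licenses origins at a fixed rate; it exits G1 only when
#' it has reached the checkpoint threshold and the minimum G1 period has
#' elapsed. The licensing fraction is recorded at the end of every step
#' (step duration = 1/`n_steps` minimum-G1 units) from G1 entry until exit,
#' so slow-licensing parameter sets yield more than `n_steps` samples.
#'
#' Because an asynchronous population feeds cells into G1 at a constant
#' rate, the time a single cell spends at each licensing level is, by the
#' ergodic principle, proportional to the number of cells observed at that
#' level in a population snapshot; the recorded trajectory therefore doubles
#' as the steady-state G1 population profile
#' (see [population_snapshot_oracle()]).
#'
#' @param params A [licensing_params()] object.
#' @return An object of class `licensing_trajectory`: list with `samples`
#'   (licensing fractions in \[0, 1\], nondecreasing), `step_duration`
#'   (minimum-G1 units) and `params`.
#' @examples
#' traj <- simulate_trajectory(licensing_params(rate = 1, n_steps = 10))
#' traj$samples  # 0.1, 0.2, ..., 1.0
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "licensing_params"))
  dt <- 1 / params$n_steps
  t_exit <- g1_exit_time(params)
  # record at the end of each step until G1 exit; the step during which the
  # cell exits is included
  n_samples <- ceiling(t_exit * params$n_steps - 1e-9)
  t <- seq_len(n_samples) * dt
  samples <- pmin(
    params$checkpoint_threshold,
    params$rate * pmax(0, t - params$unlicensed_fraction)
  )
  structure(
    list(samples = samples, step_duration = dt, params = params),
    class = "licensing_trajectory"
  )
}

#' @export
print.licensing_trajectory <- function(x, ...) {
  cat(sprintf(
    "G1 licensing trajectory: %d samples, step %.2g minimum-G1 units, final licensing %.4g\n",
    length(x$samples), x$step_duration, x$samples[length(x$samples)]
  ))
  invisible(x)
}

new_licensing_histogram <- function(counts, n_bins, stage) {
  structure(
    list(
      bin_centers = seq(0, 100, length.out = n_bins),
      counts = as.numeric(counts),
      stage = stage,
      n_bins = as.integer(n_bins),
      total = sum(counts)
    ),
    class = "licensing_histogram"
  )
}

#' @export
print.licensing_histogram <- function(x, ...) {
  cat(sprintf(
    "Licensing histogram (%s): %d bins 0..100%%, total count %.6g\n",
    x$stage, x$n_bins, x$total
  ))
  occ <- which(x$counts > 0)
  if (length(occ)) {
    cat(sprintf("  occupied bins: %d..%d; modal bin at %g%%\n",
                min(occ) - 1L, max(occ) - 1L,
                x$bin_centers[which.max(x$counts)]))
  }
  invisible(x)
}

#' Bin a licensing trajectory into a frequency histogram
#'
#' Distributes the contents of the licensing trajectory into `n_bins`
#' frequency bins ranging from 0 (no licensing) to 100% (maximal
#' licensing). Each sample is assigned to the nearest bin centre (half-up
#' rounding), so with the default 101 bins samples are rounded to whole
#' percent. By the ergodic principle this raw histogram is the steady-state
#' snapshot of a G1 population with unsynchronised cell cycles.
#'
#' @param traj A `licensing_trajectory`.
#' @param n_bins Integer >= 2; defaults to the trajectory's own `n_bins`.
#' @return A `licensing_histogram` with `stage = "raw"`.
#' @export
build_histogram <- function(traj, n_bins = NULL) {
  stopifnot(inherits(traj, "licensing_trajectory"))
  if (is.null(n_bins)) n_bins <- traj$params$n_bins
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2 ||
      n_bins != as.integer(n_bins)) {
    stop("n_bins must be an integer >= 2")
  }
  n_bins <- as.integer(n_bins)
  if (!length(traj$samples)) stop("trajectory is empty")
  idx <- floor(traj$samples * (n_bins - 1) + 0.5) + 1L  # half-up rounding
  counts <- tabulate(idx, nbins = n_bins)
  new_licensing_histogram(counts, n_bins, "raw")
}

#' Add the flow-cytometry background signal to a licensing histogram
#'
#' Models the background signal recorded by flow cytometry by increasing
#' all licensing values by `background` (default +5 percentage points on
#' the 0-100% scale): every count moves `round(background * (n_bins - 1))`
#' bins toward the top, and mass that would exceed the top bin accumulates
#' there. The total count is conserved.
#'
#' @param hist A raw `licensing_histogram`.
#' @param background Number in [0, 1).
#' @return A `licensing_histogram` with `stage = "background_adjusted"`.
#' @export
apply_background <- function(hist, background = 0.05) {
  stopifnot(inherits(hist, "licensing_histogram"))
  if (!is.numeric(background) || length(background) != 1L ||
      background < 0 || background >= 1) {
    stop("background must be in [0, 1)")
  }
  if (hist$stage != "raw") {
    stop("apply_background expects a raw histogram, got stage '",
         hist$stage, "'")
  }
  n <- hist$n_bins
  shift <- as.integer(round(background * (n - 1)))
  counts <- numeric(n)
  if (shift == 0L) {
    counts <- hist$counts
  } else {
    src <- seq_len(n)
    dest <- pmin(src + shift, n)  # clip at the top bin: licensing <= 100%
    for (i in src) counts[dest[i]] <- counts[dest[i]] + hist$counts[i]
  }
  out <- new_licensing_histogram(counts, n, "background_adjusted")
  attr(out, "background") <- background
  out
}

#' Smooth a licensing histogram by sequential neighbour pushes
#'
#' Models flow-cytometry measurement error with two sequential in-place
#' passes: a forward pass visits bins in ascending order and, at each bin,
#' moves `push_fraction` of its current count into the next-larger bin (the
#' top bin keeps its count); a backward pass then does the symmetric sweep
#' in descending order (the bottom bin keeps its count). Because the passes
#' act on the running counts, pushed mass cascades; total count is
#' conserved exactly.
#'
#' @param hist A `licensing_histogram` (raw or background-adjusted).
#' @param push_fraction Number in [0, 1); default 0.8.
#' @return A `licensing_histogram` with `stage = "smoothed"`.
#' @export
smooth_histogram <- function(hist, push_fraction = 0.8) {
  stopifnot(inherits(hist, "licensing_histogram"))
  if (!is.numeric(push_fraction) || length(push_fraction) != 1L ||
      push_fraction < 0 || push_fraction >= 1) {
    stop("push_fraction must be in [0, 1)")
  }
  if (!hist$stage %in% c("raw", "background_adjusted")) {
    stop("smooth_histogram expects a raw or background_adjusted histogram")
  }
  n <- hist$n_bins
  counts <- hist$counts
  for (i in seq_len(n - 1L)) {                 # forward, ascending
    moved <- push_fraction * counts[i]
    counts[i] <- counts[i] - moved
    counts[i + 1L] <- counts[i + 1L] + moved
  }
  for (i in seq.int(n, 2L)) {                  # backward, descending
    moved <- push_fraction * counts[i]
    counts[i] <- counts[i] - moved
    counts[i - 1L] <- counts[i - 1L] + moved
  }
  out <- new_licensing_histogram(counts, n, "smoothed")
  attr(out, "background") <- attr(hist, "background")
  out
}

#' Run the full simulator pipeline for one parameter set
#'
#' Convenience wrapper: simulate a trajectory, bin it, add the
#' flow-cytometry background and smooth, using the values stored in
#' `params`.
#'
#' @param params A [licensing_params()] object.
#' @param stage Processing stage at which to stop: `"raw"`,
#'   `"background_adjusted"` or `"smoothed"` (default).
#' @return A `licensing_histogram`.
#' @examples
#' h <- simulate_licensing_histogram(
#'   licensing_params(rate = 4, unlicensed_fraction = 0.5))
#' detect_unlicensed_peak(h)
#' @export
simulate_licensing_histogram <- function(params, stage = "smoothed") {
  stage <- match.arg(stage, c("raw", "background_adjusted", "smoothed"))
  h <- build_histogram(simulate_trajectory(params))
  if (stage == "raw") return(h)
  h <- apply_background(h, params$background)
  if (stage == "background_adjusted") return(h)
  smooth_histogram(h, params$push_fraction)
}

#' Brute-force steady-state population snapshot (ergodic oracle)
#'
#' Explicit simulation of the motorway picture behind ergodic rate
#' analysis: cells enter G1 at a constant rate (a Poisson stream over a
#' warm-up window at least as long as the G1 transit time), each cell
#' progresses deterministically, and a snapshot records the current
#' licensing fraction of every cell still in G1. The occupancy of each
#' licensing level is then inversely proportional to the speed at which
#' cells move through it, which is what [build_histogram()] of a single
#' recorded trajectory asserts; this function is the independent
#' brute-force oracle for that equivalence.
#'
#' @param params A [licensing_params()] object.
#' @param n_cells Number of cells entering G1 during the warm-up window.
#' @param seed Integer seed for the entry-time stream.
#' @return A raw `licensing_histogram` of the cells captured in G1 at the
#'   snapshot, with attribute `n_in_g1` (number of cells captured).
#' @export
population_snapshot_oracle <- function(params, n_cells = 100000L, seed = 1L) {
  stopifnot(inherits(params, "licensing_params"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop("n_cells must be >= 1")
  }
  t_exit <- g1_exit_time(params)
  window <- 2 * t_exit  # warm-up longer than one full G1 transit
  ages <- withr::with_seed(seed, stats::runif(n_cells, 0, window))
  ages <- ages[ages < t_exit]  # cells that have not yet exited G1
  lic <- pmin(
    params$checkpoint_threshold,
    params$rate * pmax(0, ages - params$unlicensed_fraction)
  )
  n <- params$n_bins
  idx <- floor(lic * (n - 1) + 0.5) + 1L
  counts <- tabulate(idx, nbins = n)
  out <- new_licensing_histogram(counts, n, "raw")
  attr(out, "n_in_g1") <- length(ages)
  out
}

#' Detect a discrete peak of unlicensed cells in a licensing histogram
#'
#' A discrete unlicensed peak - mass parked at the minimum-licensing
#' position, clearly exceeding the occupancy of the licensing ramp next to
#' it - distinguishes a paused unlicensed-G1 state from mere slow
#' licensing, in which cells are spread evenly across licensing levels.
#' The peak window comprises the bins within one background-width of the
#' minimum-licensing position (the background offset itself for
#' background-adjusted or smoothed histograms, 0 for raw ones). A peak is
#' reported when the window holds more than `abs_threshold` of the total
#' mass and its mean bin occupancy exceeds `neighbor_factor` times the mean
#' occupancy of the adjacent ramp bins.
#'
#' @param hist A `licensing_histogram`.
#' @param background Background offset used to locate and size the peak
#'   window; defaults to the value recorded by [apply_background()], or
#'   0.05 if the histogram carries none (0 for raw histograms).
#' @param abs_threshold Minimum fraction of total mass in the window.
#' @param neighbor_factor Required ratio of window mean occupancy to the
#'   mean occupancy of the adjacent ramp bins.
#' @return List with `present` (logical), `peak_fraction` (window mass /
#'   total), `window_bins` and `ramp_bins` (0-based bin indices).
#' @export
detect_unlicensed_peak <- function(hist, background = NULL,
                                   abs_threshold = 0.10,
                                   neighbor_factor = 3) {
  stopifnot(inherits(hist, "licensing_histogram"))
  if (hist$total <= 0) stop("histogram is empty")
  n <- hist$n_bins
  if (is.null(background)) {
    background <- if (!is.null(attr(hist, "background"))) {
      attr(hist, "background")
    } else if (hist$stage == "raw") 0 else 0.05
  }
  bw <- as.integer(round(background * (n - 1)))
  center <- bw  # the minimum-licensing position sits at the background
  window <- seq.int(max(0L, center - bw), min(n - 1L, center + bw))
  ramp <- if (max(window) >= n - 1L) integer(0)
  else seq.int(max(window) + 1L,
               min(n - 1L, max(window) + length(window)))
  wmass <- sum(hist$counts[window + 1L])
  wmean <- wmass / length(window)
  rmean <- if (length(ramp)) mean(hist$counts[ramp + 1L]) else 0
  peak_fraction <- wmass / hist$total
  present <- peak_fraction > abs_threshold &&
    (if (rmean > 0) wmean > neighbor_factor * rmean else wmean > 0)
  list(present = present, peak_fraction = peak_fraction,
       window_bins = window, ramp_bins = ramp)
}

#' Build a parameter lattice for grid-search fitting
#'
#' @param rate,unlicensed_fraction,checkpoint_threshold Numeric vectors of
#'   candidate values; their Cartesian product forms the lattice.
#' @return A data frame with one row per lattice point, ordered
#'   lexicographically by (rate, unlicensed_fraction, checkpoint_threshold).
#' @export
licensing_grid <- function(rate, unlicensed_fraction,
                           checkpoint_threshold = 1) {
  grid <- expand.grid(
    checkpoint_threshold = sort(unique(checkpoint_threshold)),
    unlicensed_fraction = sort(unique(unlicensed_fraction)),
    rate = sort(unique(rate)),
    KEEP.OUT.ATTRS = FALSE
  )[, c("rate", "unlicensed_fraction", "checkpoint_threshold")]
  grid <- grid[order(grid$rate, grid$unlicensed_fraction,
                     grid$checkpoint_threshold), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Fit licensing-model parameters to an observed histogram
#'
#' For every lattice point the full pipeline (simulate, bin, background,
#' smooth, normalise) is run and compared with the observed normalised
#' histogram by L2 distance; the minimising point is returned. Ties break
#' deterministically to the lexicographically smallest lattice point (by
#' rate, then unlicensed_fraction, then checkpoint_threshold).
#'
#' @param observed A `licensing_histogram` (any stage; it is normalised to
#'   frequencies internally and compared against smoothed model output).
#' @param grid Data frame from [licensing_grid()], or any data frame with
#'   columns `rate`, `unlicensed_fraction` and optionally
#'   `checkpoint_threshold`.
#' @param n_steps,background,push_fraction Simulator settings used for
#'   every lattice point.
#' @return An object of class `licensing_fit`: list with `best_rate`,
#'   `best_unlicensed_fraction`, `best_checkpoint_threshold`, `distance`
#'   and `grid` (the lattice with a `distance` column appended).
#' @export
fit_params <- function(observed, grid, n_steps = 10000L,
                       background = 0.05, push_fraction = 0.8) {
  stopifnot(inherits(observed, "licensing_histogram"))
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("grid must be nonempty")
  if (!all(c("rate", "unlicensed_fraction") %in% names(grid))) {
    stop("grid needs columns rate and unlicensed_fraction")
  }
  if (is.null(grid$checkpoint_threshold)) grid$checkpoint_threshold <- 1
  if (observed$total <= 0) stop("observed histogram is empty")
  obs <- observed$counts / observed$total
  grid <- grid[order(grid$rate, grid$unlicensed_fraction,
                     grid$checkpoint_threshold), , drop = FALSE]
  rownames(grid) <- NULL
  grid$distance <- vapply(seq_len(nrow(grid)), function(i) {
    p <- licensing_params(
      rate = grid$rate[i],
      unlicensed_fraction = grid$unlicensed_fraction[i],
      checkpoint_threshold = grid$checkpoint_threshold[i],
      n_steps = n_steps, background = background,
      push_fraction = push_fraction, n_bins = observed$n_bins
    )
    h <- simulate_licensing_histogram(p, stage = "smoothed")
    sqrt(sum((h$counts / h$total - obs)^2))
  }, numeric(1))
  best <- which.min(grid$distance)  # first minimum = lexicographic tie-break
  structure(
    list(
      best_rate = grid$rate[best],
      best_unlicensed_fraction = grid$unlicensed_fraction[best],
      best_checkpoint_threshold = grid$checkpoint_threshold[best],
      distance = grid$distance[best],
      grid = grid
    ),
    class = "licensing_fit"
  )
}

#' @export
print.licensing_fit <- function(x, ...) {
  cat("Licensing-model grid fit\n")
  cat(sprintf("  best rate: %g  unlicensed_fraction: %g  checkpoint: %g\n",
              x$best_rate, x$best_unlicensed_fraction,
              x$best_checkpoint_threshold))
  cat(sprintf("  L2 distance: %.4g over %d lattice points\n",
              x$distance, nrow(x$grid)))
  invisible(x)
}
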