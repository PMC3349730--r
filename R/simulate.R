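#' Simulation parameters for the S-phase forward model
#'
#' @param fork_velocity Replication fork velocity in bp/minute (> 0).
#' @param s_entry_mean Mean delay (minutes after release) before a cycling
#'   cell enters S phase.
#' @param s_entry_sd Cell-to-cell SD of the S-entry delay (minutes).
#' @param fraction_cycling Fraction of cells that enter (and complete) S
#'   phase at all; the rest contribute permanently unreplicated DNA, which is
#'   why population kinetic curves plateau below 100%.
#' @param n_cells Number of cells per simulated population.
#' @param seed Optional integer seed; when non-`NULL`, population-level
#'   operations seed the RNG before drawing.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(fork_velocity = 1500, s_entry_mean = 35,
                       s_entry_sd = 4, fraction_cycling = 0.8,
                       n_cells = 500, seed = NULL) {
  if (fork_velocity <= 0) stop("fork_velocity must be > 0")
  if (fraction_cycling < 0 || fraction_cycling > 1)
    stop("fraction_cycling must be in [0, 1]")
  if (n_cells <= 0) stop("n_cells must be a positive integer")
  structure(list(fork_velocity = fork_velocity, s_entry_mean = s_entry_mean,
                 s_entry_sd = s_entry_sd, fraction_cycling = fraction_cycling,
                 n_cells = as.integer(n_cells), seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> fork %.0f bp/min, S entry %.0f+/-%.0f min, ",
                     "%.0f%% cycling, %d cells\n"),
              x$fork_velocity, x$s_entry_mean, x$s_entry_sd,
              100 * x$fraction_cycling, x$n_cells))
  invisible(x)
}

## normal truncated at zero, exact inverse-CDF sampling
rtnorm0 <- function(n, mean, sd) {
  if (all(sd == 0)) return(pmax(0, rep_len(mean, n)))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Sample one cell's origin-firing realization
#'
#' Each origin fires independently with probability `efficiency`; fired
#' origins draw a firing time from a normal distribution truncated at zero.
#' Realizations in which no origin fires are rejected and resampled (a
#' chromosome must eventually finish replication). Uses the current RNG
#' stream.
#'
#' @param chrom A [chromosome_model()] with at least one origin.
#' @param params A [sim_params()].
#' @return A list of class `cell_realization` with `s_entry_delay`, logical
#'   `fired`, and `firing_times` (NA where unfired).
#' @export
sample_cell <- function(chrom, params) {
  ors <- chrom$origins
  if (nrow(ors) == 0L) stop("chromosome has no origins")
  if (all(ors$efficiency == 0))
    stop("all origins have efficiency 0: chromosome can never replicate")
  repeat {
    fired <- stats::runif(nrow(ors)) < ors$efficiency
    if (any(fired)) break
  }
  ft <- rep(NA_real_, nrow(ors))
  ft[fired] <- rtnorm0(sum(fired), ors$mean_firing_time[fired],
                       ors$firing_sd[fired])
  structure(list(s_entry_delay = rtnorm0(1, params$s_entry_mean,
                                         params$s_entry_sd),
                 fired = fired, firing_times = ft),
            class = "cell_realization")
}

#' Replication time of a locus in one cell
#'
#' Standard bidirectional-fork kinematics: the locus is replicated by the
#' first fork to arrive, i.e. `min_i(firing_time_i + |x - position_i| /
#' fork_velocity)` over fired origins. Time is measured from the start of S
#' phase in that cell (the S-entry delay is not included).
#'
#' @param cell A `cell_realization` from [sample_cell()].
#' @param chrom The corresponding [chromosome_model()].
#' @param x Position in bp, within `[0, chrom$length]`.
#' @param params A [sim_params()] (supplies the fork velocity).
#' @return Replication time in minutes.
#' @export
locus_replication_time <- function(cell, chrom, x, params) {
  if (x < 0 || x > chrom$length) stop("x outside chromosome")
  if (!any(cell$fired)) stop("cell has no fired origin")
  pos <- chrom$origins$position[cell$fired]
  ft <- cell$firing_times[cell$fired]
  min(ft + abs(x - pos) / params$fork_velocity)
}

## Vectorized population sampler: one draw of n_cells cells for one
## chromosome. Cycling cells with zero fired origins are resampled.
sample_population <- function(chrom, params) {
  n <- params$n_cells
  ors <- chrom$origins
  if (nrow(ors) == 0L) stop("chromosome has no origins")
  if (all(ors$efficiency == 0))
    stop("all origins have efficiency 0: chromosome can never replicate")
  cycling <- stats::runif(n) < params$fraction_cycling
  entry <- rtnorm0(n, params$s_entry_mean, params$s_entry_sd)
  no <- nrow(ors)
  fired <- matrix(stats::runif(n * no), n, no) <
    matrix(ors$efficiency, n, no, byrow = TRUE)
  none <- which(rowSums(fired) == 0L)
  while (length(none) > 0L) {
    fired[none, ] <- matrix(stats::runif(length(none) * no),
                            length(none), no) <
      matrix(ors$efficiency, length(none), no, byrow = TRUE)
    none <- none[rowSums(fired[none, , drop = FALSE]) == 0L]
  }
  firing <- matrix(rtnorm0(n * no,
                           rep(ors$mean_firing_time, each = n),
                           rep(ors$firing_sd, each = n)), n, no)
  firing[!fired] <- Inf
  list(cycling = cycling, entry = entry, firing = firing,
       positions = ors$position, n = n)
}

## cells x positions matrix of per-cell replication times (S-phase clock)
population_rep_times <- function(pop, x, fork_velocity) {
  out <- matrix(Inf, pop$n, length(x))
  for (j in seq_along(pop$positions)) {
    travel <- abs(x - pop$positions[j]) / fork_velocity
    out <- pmin(out, outer(pop$firing[, j], travel, `+`))
  }
  out
}

#' Fraction of a cell population that has replicated a locus by time t
#'
#' Monte-Carlo population model: simulates `n_cells` cells (each cycling
#' with probability `fraction_cycling`) and returns the fraction whose
#' `s_entry_delay + locus replication time` is at most `t`. Non-cycling
#' cells never replicate, so the curve plateaus at `fraction_cycling`.
#'
#' @param chrom A [chromosome_model()].
#' @param x Position in bp.
#' @param t Time (minutes after release); may be a vector.
#' @param params A [sim_params()]; `params$seed` (if set) seeds the draw.
#' @param population Optional pre-drawn population from the internal sampler,
#'   so that several loci/times share one coherent cell population.
#' @return Fraction(s) in `[0, 1]`, one per element of `t`.
#' @export
fraction_replicated <- function(chrom, x, t, params, population = NULL) {
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(population)) {
    if (!is.null(params$seed)) set.seed(params$seed)
    population <- sample_population(chrom, params)
  }
  rt <- population$entry +
    population_rep_times(population, x, params$fork_velocity)[, 1]
  rt[!population$cycling] <- Inf
  vapply(t, function(tt) mean(rt <= tt), numeric(1))
}

#' Ground-truth replication profile along a chromosome
#'
#' Evaluates [fraction_replicated()] on a regular grid, sharing a single
#' simulated cell population across all positions so that spatial structure
#' is coherent within each cell.
#'
#' @param chrom A [chromosome_model()].
#' @param t Time in minutes after release (scalar).
#' @param grid_spacing Grid spacing in bp (> 0).
#' @param params A [sim_params()].
#' @param population Optional pre-drawn population (see
#'   [fraction_replicated()]).
#' @return A `data.frame` of class `true_profile` with columns `position`
#'   and `fraction`, plus attributes `chrom` and `time`.
#' @export
true_profile <- function(chrom, t, grid_spacing, params, population = NULL) {
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  if (is.null(population)) {
    if (!is.null(params$seed)) set.seed(params$seed)
    population <- sample_population(chrom, params)
  }
  x <- seq(0, chrom$length, by = grid_spacing)
  rt <- population$entry + population_rep_times(population, x,
                                                params$fork_velocity)
  rt[!population$cycling, ] <- Inf
  frac <- colMeans(rt <= t)
  structure(data.frame(position = x, fraction = frac),
            chrom = chrom$name, time = t,
            class = c("true_profile", "data.frame"))
}

#' Export a ground-truth profile as bedGraph
#'
#' Intervals are 0-based half-open, one per grid point, closed at the
#' chromosome end.
#'
#' @param profile A `true_profile` from [true_profile()].
#' @param file Output path.
#' @param chrom_length Chromosome length in bp (caps the last interval).
#' @return The path, invisibly.
#' @export
export_bedgraph <- function(profile, file, chrom_length = NULL) {
  pos <- profile$position
  spacing <- if (length(pos) > 1) diff(pos)[1] else 1
  end <- pos + spacing
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  gr <- GenomicRanges::GRanges(attr(profile, "chrom"),
                               IRanges::IRanges(start = pos + 1, end = end),
                               score = profile$fraction)
  rtracklayer::export.bedGraph(gr, file)
  invisible(file)
}
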