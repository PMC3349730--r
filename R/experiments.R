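#' CsCl gradient geometry for the slot-blot simulator
#'
#' Unreplicated (HH) DNA is denser and sits lower in the gradient, i.e. at
#' a higher fraction index than hybrid-density (HL) DNA; each density class
#' spreads across fractions as a Gaussian peak.
#'
#' @param n_fractions Number of drip fractions.
#' @param hh_peak_fraction,hl_peak_fraction Peak fraction indices
#'   (`hh_peak_fraction > hl_peak_fraction`).
#' @param peak_sd Peak SD in fraction units; peaks must be separated by at
#'   least `4 * peak_sd`.
#' @return An object of class `gradient_geometry`.
#' @export
gradient_geometry <- function(n_fractions = 25, hh_peak_fraction = 17,
                              hl_peak_fraction = 9, peak_sd = 1.2) {
  if (hh_peak_fraction <= hl_peak_fraction)
    stop("HH (denser) peak must be at a higher fraction index than HL")
  if (hh_peak_fraction - hl_peak_fraction < 4 * peak_sd)
    stop("HH and HL peaks overlap: separation < 4 * peak_sd")
  if (hh_peak_fraction > n_fractions || hl_peak_fraction < 1)
    stop("peak fractions outside the gradient")
  structure(list(n_fractions = as.integer(n_fractions),
                 hh_peak_fraction = hh_peak_fraction,
                 hl_peak_fraction = hl_peak_fraction, peak_sd = peak_sd),
            class = "gradient_geometry")
}

#' Measurement-noise model
#'
#' @param signal_cv Coefficient of variation of multiplicative lognormal
#'   signal noise (0 disables it).
#' @param background Additive non-negative background level per fraction
#'   (slot blots) in units of one unreplicated genome equivalent.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(signal_cv = 0.05, background = 0.005) {
  if (signal_cv < 0) stop("signal_cv must be >= 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(signal_cv = signal_cv, background = background),
            class = "noise_model")
}

## mean-1 multiplicative lognormal noise
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## One cell population per chromosome, shared by every locus and the
## genomic probe of one simulated experiment.
scenario_populations <- function(scenario) {
  lapply(scenario$chromosomes, sample_population, params = scenario$params)
}

## fraction replicated for positions (bp, named) on one chromosome at each
## time; returns times x positions matrix
population_fractions <- function(pop, positions, times, params) {
  rt <- population_rep_times(pop, positions, params$fork_velocity)
  rt <- pop$entry + rt
  rt[!pop$cycling, ] <- Inf
  t(vapply(seq_along(positions),
           function(j) vapply(times, function(tt) mean(rt[, j] <= tt),
                              numeric(1)),
           numeric(length(times))))
}

## genome-wide fraction replicated (uniform dense grid over every
## chromosome) at each time
genomic_fractions <- function(scenario, populations, times,
                              grid_spacing = 5000) {
  tot <- rep(0, length(times))
  n <- 0L
  for (ch in names(scenario$chromosomes)) {
    chrom <- scenario$chromosomes[[ch]]
    x <- seq(0, chrom$length, by = grid_spacing)
    f <- population_fractions(populations[[ch]], x, times, scenario$params)
    tot <- tot + colSums(f)
    n <- n + length(x)
  }
  tot / n
}

#' Simulate a slot-blot density-transfer experiment
#'
#' For every named locus of the scenario (plus a total-genomic probe
#' averaged over a dense grid of loci) and every sample time, computes the
#' fraction of molecules replicated `f` from one shared simulated cell
#' population, places `1 - f` mass at the HH gradient peak and `2 f` mass
#' (two hybrid daughters per replicated molecule) at the HL peak, spreads
#' each as a Gaussian over fractions, and applies multiplicative lognormal
#' noise plus additive background.
#'
#' @param scenario A [build_scenario()] result.
#' @param times Sample times in minutes (increasing; default 0-140 by 10).
#' @param geometry A [gradient_geometry()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed (defaults to `scenario$params$seed`).
#' @param genomic_grid_spacing Grid spacing (bp) of the genomic probe.
#' @return A long `data.frame` with columns `fragment_id`, `time_min`,
#'   `fraction`, `signal`; the genomic probe has `fragment_id "genomic"`.
#' @export
simulate_slotblot_experiment <- function(scenario,
                                         times = seq(0, 140, by = 10),
                                         geometry = gradient_geometry(),
                                         noise = noise_model(),
                                         seed = NULL,
                                         genomic_grid_spacing = 5000) {
  stopifnot(inherits(scenario, "scenario"))
  if (length(times) == 0L || is.unsorted(times, strictly = TRUE))
    stop("times must be non-empty and increasing")
  seed <- if (!is.null(seed)) seed else scenario$params$seed
  if (!is.null(seed)) set.seed(seed)
  pops <- scenario_populations(scenario)

  fr <- seq_len(geometry$n_fractions)
  shape_hh <- stats::dnorm(fr, geometry$hh_peak_fraction, geometry$peak_sd)
  shape_hh <- shape_hh / sum(shape_hh)
  shape_hl <- stats::dnorm(fr, geometry$hl_peak_fraction, geometry$peak_sd)
  shape_hl <- shape_hl / sum(shape_hl)

  fmat <- matrix(NA_real_, length(times), nrow(scenario$loci) + 1L,
                 dimnames = list(NULL, c(scenario$loci$locus, "genomic")))
  for (i in seq_len(nrow(scenario$loci))) {
    l <- scenario$loci[i, ]
    fmat[, l$locus] <- population_fractions(pops[[l$chrom]], l$position,
                                            times, scenario$params)[1, ]
  }
  fmat[, "genomic"] <- genomic_fractions(scenario, pops, times,
                                         genomic_grid_spacing)

  rows <- vector("list", ncol(fmat) * length(times))
  k <- 0L
  for (fragment in colnames(fmat)) {
    for (ti in seq_along(times)) {
      f <- fmat[ti, fragment]
      sig <- (1 - f) * shape_hh + 2 * f * shape_hl
      sig <- sig * lognoise(length(sig), noise$signal_cv) + noise$background
      k <- k + 1L
      rows[[k]] <- data.frame(fragment_id = fragment, time_min = times[ti],
                              fraction = fr, signal = sig,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a two-channel array experiment
#'
#' Places probes on a regular grid along every chromosome (probe midpoints
#' at half-spacing offsets), computes per-probe replicated fractions `f`
#' from one shared cell population per chromosome, and emits channel
#' intensities `hh = (1 - f) * scale_hh * noise` and
#' `hl = 2 f * scale_hl * noise` with independent lognormal noise per
#' channel. The global channel scale factors emulate labelling/scanning
#' differences and are removed downstream by median normalization.
#'
#' @param scenario A [build_scenario()] result.
#' @param times Sample times in minutes (default mid-S samples 60, 65, 70).
#' @param probe_spacing Probe spacing in bp (> 0).
#' @param noise A [noise_model()] (`background` is ignored for arrays).
#' @param channel_scales Named numeric `c(hh = , hl = )` global scales.
#' @param seed Optional integer seed.
#' @return A long `data.frame` with columns `chrom`, `position`,
#'   `time_min`, `hh_intensity`, `hl_intensity`.
#' @export
simulate_array_experiment <- function(scenario, times = c(60, 65, 70),
                                      probe_spacing = 1000,
                                      noise = noise_model(),
                                      channel_scales = c(hh = 1, hl = 1.3),
                                      seed = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (probe_spacing <= 0) stop("probe_spacing must be > 0")
  seed <- if (!is.null(seed)) seed else scenario$params$seed
  if (!is.null(seed)) set.seed(seed)
  pops <- scenario_populations(scenario)
  out <- list()
  for (ch in names(scenario$chromosomes)) {
    chrom <- scenario$chromosomes[[ch]]
    pos <- seq(probe_spacing / 2, chrom$length, by = probe_spacing)
    if (length(pos) == 0L) stop("zero probes on ", ch)
    f <- population_fractions(pops[[ch]], pos, times, scenario$params)
    for (ti in seq_along(times)) {
      hh <- (1 - f[, ti]) * channel_scales[["hh"]] *
        lognoise(length(pos), noise$signal_cv)
      hl <- 2 * f[, ti] * channel_scales[["hl"]] *
        lognoise(length(pos), noise$signal_cv)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, position = pos, time_min = times[ti],
        hh_intensity = hh, hl_intensity = hl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a complete fixture set for a scenario
#'
#' Emits, under `out_dir`: one gradient TSV per locus per timepoint plus
#' the combined `scans.tsv`, the array probe table `probes.tsv`, the
#' scenario config `scenario.yaml`, and the truth table `truth.tsv`
#' (locus, true T_rep, true RI). Deterministic for a fixed seed.
#'
#' @param scenario A [build_scenario()] result.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the simulated experiments.
#' @param times Slot-blot sample times.
#' @param array_times Array sample times.
#' @param geometry,noise Simulator settings.
#' @return Invisibly, a `data.frame` manifest with columns `file`, `kind`.
#' @export
write_fixture_set <- function(scenario, out_dir, seed = 1,
                              times = seq(0, 140, by = 10),
                              array_times = c(60, 65, 70),
                              geometry = gradient_geometry(),
                              noise = noise_model()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scans <- simulate_slotblot_experiment(scenario, times = times,
                                        geometry = geometry, noise = noise,
                                        seed = seed)
  manifest <- list()
  add <- function(file, kind) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, kind = kind, stringsAsFactors = FALSE)
  }
  for (fragment in unique(scans$fragment_id)) {
    for (tt in times) {
      sub <- scans[scans$fragment_id == fragment & scans$time_min == tt, ]
      f <- file.path(out_dir, sprintf("gradient_%s_t%03d.tsv", fragment, tt))
      write_gradient_tsv(sub, f)
      add(f, "gradient")
    }
  }
  f <- file.path(out_dir, "scans.tsv")
  write_gradient_tsv(scans, f)
  add(f, "scans")

  probes <- simulate_array_experiment(scenario, times = array_times,
                                      noise = noise, seed = seed + 1L)
  f <- file.path(out_dir, "probes.tsv")
  write_probe_tsv(probes, f)
  add(f, "probes")

  f <- file.path(out_dir, "scenario.yaml")
  write_scenario_config(scenario, f)
  add(f, "config")

  f <- file.path(out_dir, "truth.tsv")
  utils::write.table(scenario_truth_table(scenario), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add(f, "truth")
  invisible(do.call(rbind, manifest))
}
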