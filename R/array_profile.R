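#' Construct a replication profile for one chromosome and timepoint
#'
#' @param chrom Chromosome label.
#' @param positions Strictly increasing probe positions (bp).
#' @param values Percent replication per probe, in `[0, 100]`.
#' @param time Sample time (minutes).
#' @param smoothed Logical; whether `values` have been window-smoothed.
#' @return An object of class `replication_profile`.
#' @export
replication_profile <- function(chrom, positions, values, time,
                                smoothed = FALSE) {
  if (length(positions) != length(values))
    stop("positions and values lengths differ")
  if (length(positions) == 0L) stop("empty profile")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (any(values < -1e-9 | values > 100 + 1e-9))
    stop("percent values must be in [0, 100]")
  structure(list(chrom = chrom, positions = as.numeric(positions),
                 values = pmin(100, pmax(0, values)),
                 time = time, smoothed = smoothed),
            class = "replication_profile")
}

#' @export
print.replication_profile <- function(x, ...) {
  cat(sprintf("<replication_profile> %s @ %g min: %d probes%s, mean %.1f%%\n",
              x$chrom, x$time, length(x$positions),
              if (x$smoothed) " (smoothed)" else "", mean(x$values)))
  invisible(x)
}

#' Per-probe percent replication from two-channel intensities
#'
#' Converts raw HH (unreplicated) and HL (replicated) channel intensities to
#' percent replication. With `norm = "median"` each sample's channels are
#' first rescaled so both have equal genome-wide median (removing global
#' labelling/scanning scale factors), then the molecule-counting formula
#' `100 * hl / (hl + 2 * hh)` is applied. Probes with both intensities zero
#' are dropped and recorded in the `dropped` attribute.
#'
#' @param probes Long-format `data.frame` with columns `chrom`, `position`,
#'   `time_min`, `hh_intensity`, `hl_intensity`.
#' @param norm `"median"` (default) or `"none"`.
#' @return A named list over timepoints (`"t<min>"`); each element is a
#'   named list of [replication_profile()]s, one per chromosome.
#' @export
probe_percent_replication <- function(probes, norm = c("median", "none")) {
  norm <- match.arg(norm)
  need <- c("chrom", "position", "time_min", "hh_intensity", "hl_intensity")
  if (!all(need %in% names(probes)))
    stop("probes must have columns ", paste(need, collapse = ", "))
  if (any(probes$hh_intensity < 0 | probes$hl_intensity < 0))
    stop("intensities must be >= 0")
  dropped <- probes[probes$hh_intensity == 0 & probes$hl_intensity == 0, ]
  times <- sort(unique(probes$time_min))
  out <- lapply(times, function(tt) {
    s <- probes[probes$time_min == tt &
                  !(probes$hh_intensity == 0 & probes$hl_intensity == 0), ]
    hh <- s$hh_intensity
    hl <- s$hl_intensity
    if (norm == "median") {
      mh <- stats::median(hh[hh > 0])
      ml <- stats::median(hl[hl > 0])
      if (is.na(mh) || is.na(ml) || mh == 0 || ml == 0)
        stop("cannot median-normalize a channel with zero median")
      hh <- hh / mh
      hl <- hl / ml
    }
    pct <- 100 * hl / (hl + 2 * hh)
    chroms <- unique(s$chrom)
    profs <- lapply(chroms, function(ch) {
      i <- which(s$chrom == ch)
      i <- i[order(s$position[i])]
      replication_profile(ch, s$position[i], pct[i], tt)
    })
    stats::setNames(profs, chroms)
  })
  names(out) <- paste0("t", times)
  attr(out, "dropped") <- dropped
  out
}

#' Smooth a replication profile with a sliding window
#'
#' Each probe's value is replaced by the unweighted mean of all probes
#' within half a window on either side (`position +/- window_bp / 2`); the
#' window is truncated at chromosome ends. The default 18 kb full width is
#' the standard choice for yeast replication profiles.
#'
#' @param profile A [replication_profile()].
#' @param window_bp Full window width in bp (> 0).
#' @return A smoothed [replication_profile()].
#' @export
smooth_profile <- function(profile, window_bp = 18000) {
  stopifnot(inherits(profile, "replication_profile"))
  if (window_bp <= 0) stop("window_bp must be > 0")
  pos <- profile$positions
  half <- window_bp / 2
  ## probes are sorted: a two-pointer pass gives O(n) windowed means
  cs <- c(0, cumsum(profile$values))
  lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + half, pos)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  replication_profile(profile$chrom, pos, sm, profile$time, smoothed = TRUE)
}

#' Z-score normalize replication profiles for one timed sample
#'
#' Converts each probe's percent replication X to `Z = (X - mu) / sigma`,
#' where `mu` and `sigma` are the mean and *population* standard deviation
#' of X over all probes genome-wide for that sample.
#'
#' @param profiles Named list of [replication_profile()]s (all chromosomes,
#'   one timepoint).
#' @return An object of class `zprofile_set`: list with `profiles` (each a
#'   list of `chrom`, `positions`, `zvalues`, `time`), `mu`, `sigma`,
#'   `time`.
#' @export
zscore_profile <- function(profiles) {
  if (inherits(profiles, "replication_profile")) profiles <- list(profiles)
  x <- unlist(lapply(profiles, `[[`, "values"))
  if (length(x) < 2L) stop("need at least 2 probes to Z-normalize")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate profile: zero variance")
  zp <- lapply(profiles, function(p) {
    list(chrom = p$chrom, positions = p$positions,
         zvalues = (p$values - mu) / sigma, time = p$time)
  })
  structure(list(profiles = zp, mu = mu, sigma = sigma,
                 time = profiles[[1]]$time),
            class = "zprofile_set")
}

#' @export
print.zprofile_set <- function(x, ...) {
  cat(sprintf("<zprofile_set> t=%g min: %d chromosomes, mu=%.2f%%, sigma=%.2f\n",
              x$time, length(x$profiles), x$mu, x$sigma))
  invisible(x)
}

#' Check that two timed samples are comparable
#'
#' Two strains' samples taken at the same nominal time are comparable only
#' if their genome-wide mean percent replication values are well matched;
#' otherwise Z-score differences reflect S-phase progression, not locus
#' behaviour, and the pair must be excluded.
#'
#' @param profiles_a,profiles_b Named lists of [replication_profile()]s
#'   (one timepoint each).
#' @param tol Maximum allowed difference of genome means, percentage points.
#' @return A list with `matched` (logical), `mean_a`, `mean_b`, `delta`.
#' @export
check_sample_matching <- function(profiles_a, profiles_b, tol = 10) {
  gm <- function(pl) {
    x <- unlist(lapply(pl, `[[`, "values"))
    mean(x)
  }
  a <- gm(profiles_a)
  b <- gm(profiles_b)
  list(matched = abs(a - b) <= tol, mean_a = a, mean_b = b,
       delta = abs(a - b))
}

#' Call origin peaks on a smoothed replication profile
#'
#' Peaks are probes that are strict local maxima over their immediate
#' neighbours, with prominence (height above the higher of the two flanking
#' minima, walking outwards until a higher probe or the chromosome end) of
#' at least `min_prominence`. Chromosome-end probes are never peaks. Peak
#' locations in a replication profile correspond to active origins.
#'
#' @param profile A smoothed [replication_profile()].
#' @param min_prominence Minimum prominence, in profile units.
#' @return A `data.frame` with columns `chrom`, `position`, `height`,
#'   `prominence` (possibly zero rows).
#' @export
call_peaks <- function(profile, min_prominence = 0) {
  stopifnot(inherits(profile, "replication_profile"))
  if (!profile$smoothed)
    warning("calling peaks on an unsmoothed profile")
  v <- profile$values
  n <- length(v)
  empty <- data.frame(chrom = character(), position = numeric(),
                      height = numeric(), prominence = numeric())
  if (n < 3L) return(empty)
  cand <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] > v[-c(1, 2)]) + 1L
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) {
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > v[i])
    lmin <- min(left[if (length(higher_l)) (max(higher_l) + 1):(i - 1)
                     else seq_len(i - 1)])
    right <- v[(i + 1):n]
    higher_r <- which(right > v[i])
    rmin <- min(right[if (length(higher_r)) seq_len(min(higher_r) - 1)
                      else seq_along(right)])
    v[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(chrom = profile$chrom, position = profile$positions[cand[keep]],
             height = v[cand[keep]], prominence = prom[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect persistent replication-timing differences between two strains
#'
#' Compares Z-score profiles of two strains across matched S-phase samples
#' and reports maximal runs of at least `min_probes` consecutive probes
#' whose absolute Z difference is at least `delta_z` at *every* compared
#' timepoint -- i.e. differences that persist over the course of S phase.
#'
#' @param za,zb Lists of [zscore_profile()] results (`zprofile_set`), one
#'   per compared timepoint, in matching order, built on identical probe
#'   coordinates.
#' @param delta_z Z-difference threshold (default 1.5).
#' @param min_probes Minimum run length in probes (default 3).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, spanning probe positions), `n_probes`, `max_abs_delta_z`,
#'   `times_supporting` (comma-separated minutes).
#' @export
detect_timing_differences <- function(za, zb, delta_z = 1.5,
                                      min_probes = 3) {
  if (inherits(za, "zprofile_set")) za <- list(za)
  if (inherits(zb, "zprofile_set")) zb <- list(zb)
  if (length(za) != length(zb) || length(za) < 2L)
    stop("need >= 2 matched timepoints for persistence")
  times <- vapply(za, `[[`, numeric(1), "time")
  chroms <- names(za[[1]]$profiles)
  res <- list()
  for (ch in chroms) {
    pos <- za[[1]]$profiles[[ch]]$positions
    dz <- sapply(seq_along(za), function(k) {
      pa <- za[[k]]$profiles[[ch]]
      pb <- zb[[k]]$profiles[[ch]]
      if (!identical(pa$positions, pb$positions))
        stop("profiles have mismatched probe coordinates on ", ch)
      abs(pa$zvalues - pb$zvalues)
    })
    hit <- rowSums(dz >= delta_z) == length(za)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_probes)) {
      i0 <- starts[j]; i1 <- ends[j]
      spacing <- if (length(pos) > 1) stats::median(diff(pos)) else 1
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = pos[i0], end = pos[i1] + spacing,
        n_probes = i1 - i0 + 1L,
        max_abs_delta_z = max(dz[i0:i1, ]),
        times_supporting = paste(times, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      max_abs_delta_z = numeric(),
                      times_supporting = character()))
  do.call(rbind, res)
}

#' Compare two strains' array experiments end to end
#'
#' Runs the full profile chain on both probe tables: per-probe percent
#' replication (median channel normalization), window smoothing, Z-score
#' normalization, sample-matching checks (mismatched timepoints are dropped
#' with a warning), and persistent-difference detection.
#'
#' @param probes_a,probes_b Probe tables (see
#'   [probe_percent_replication()]) for the two strains, sharing timepoints
#'   and probe coordinates.
#' @param window_bp Smoothing window (bp).
#' @param delta_z,min_probes Detection thresholds.
#' @param match_tol Sample-matching tolerance, percentage points.
#' @return A list of class `strain_comparison`: `differences` (data.frame),
#'   `matched_times`, `excluded_times`, `za`, `zb`.
#' @export
compare_strain_profiles <- function(probes_a, probes_b, window_bp = 18000,
                                    delta_z = 1.5, min_probes = 3,
                                    match_tol = 10) {
  pa <- probe_percent_replication(probes_a)
  pb <- probe_percent_replication(probes_b)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) < 2L) stop("need >= 2 shared timepoints")
  smooth_all <- function(pl) lapply(pl, smooth_profile, window_bp = window_bp)
  matched <- character(0)
  excluded <- character(0)
  za <- list(); zb <- list()
  for (tt in shared) {
    chk <- check_sample_matching(pa[[tt]], pb[[tt]], tol = match_tol)
    if (!chk$matched) {
      warning(sprintf(
        "excluding sample %s: genomic percent replication not matched (%.1f vs %.1f)",
        tt, chk$mean_a, chk$mean_b))
      excluded <- c(excluded, tt)
      next
    }
    matched <- c(matched, tt)
    za[[tt]] <- zscore_profile(smooth_all(pa[[tt]]))
    zb[[tt]] <- zscore_profile(smooth_all(pb[[tt]]))
  }
  if (length(matched) < 2L) stop("fewer than 2 matched timepoints")
  diffs <- detect_timing_differences(unname(za), unname(zb),
                                     delta_z = delta_z,
                                     min_probes = min_probes)
  structure(list(differences = diffs, matched_times = matched,
                 excluded_times = excluded, za = za, zb = zb),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("<strain_comparison> %d matched timepoints (%s), %d difference region(s)\n",
              length(x$matched_times), paste(x$matched_times, collapse = ", "),
              nrow(x$differences)))
  if (nrow(x$differences) > 0)
    print(format(x$differences, digits = 3), row.names = FALSE)
  invisible(x)
}
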