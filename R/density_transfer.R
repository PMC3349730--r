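#' Construct a gradient scan
#'
#' One slot-blot quantification: the signal of a named restriction fragment
#' across the fractions of a CsCl density gradient for one timed sample.
#' Fractions are ordered dense-to-light, so unreplicated (HH) DNA peaks at a
#' higher fraction index than replicated (HL) DNA... ordering is by the
#' supplied `fraction_index`.
#'
#' @param fragment_id Fragment label.
#' @param time Sample time in minutes after release.
#' @param fraction_index Strictly increasing integer fraction indices.
#' @param signal Non-negative signal per fraction.
#' @return An object of class `gradient_scan`.
#' @export
gradient_scan <- function(fragment_id, time, fraction_index, signal) {
  if (length(fraction_index) != length(signal))
    stop("fraction_index and signal lengths differ")
  if (is.unsorted(fraction_index, strictly = TRUE))
    stop("fraction indices must be strictly increasing")
  if (any(signal < 0)) stop("signals must be >= 0")
  structure(list(fragment_id = fragment_id, time = time,
                 fraction_index = as.integer(fraction_index),
                 signal = as.numeric(signal)),
            class = "gradient_scan")
}

#' Pool gradient fractions into HH and HL densities
#'
#' Sums background-subtracted signal over the heavy-heavy (unreplicated) and
#' heavy-light (replicated) windows. Background is estimated as the median
#' signal of fractions outside both windows and subtracted per fraction,
#' floored at zero; when every fraction falls inside a window no background
#' is subtracted.
#'
#' @param scan A [gradient_scan()].
#' @param hh_window,hl_window Integer vectors of fraction indices; must be
#'   disjoint, non-empty, and within the scan's fraction range.
#' @return A list of class `pooled_densities` with elements `hh` and `hl`.
#' @export
pool_fractions <- function(scan, hh_window, hl_window) {
  stopifnot(inherits(scan, "gradient_scan"))
  if (length(hh_window) == 0L || length(hl_window) == 0L)
    stop("pooling windows must be non-empty")
  if (length(intersect(hh_window, hl_window)) > 0L)
    stop("HH and HL windows overlap")
  if (!all(c(hh_window, hl_window) %in% scan$fraction_index))
    stop("pooling windows outside the scan's fraction range")
  outside <- !(scan$fraction_index %in% c(hh_window, hl_window))
  bg <- if (any(outside)) stats::median(scan$signal[outside]) else 0
  sig <- pmax(0, scan$signal - bg)
  structure(list(hh = sum(sig[scan$fraction_index %in% hh_window]),
                 hl = sum(sig[scan$fraction_index %in% hl_window])),
            class = "pooled_densities")
}

#' Percent replication from pooled HH/HL densities
#'
#' Each replicated duplex yields two hybrid-density (HL) daughter molecules,
#' so the fraction of *molecules* replicated is `HL / (HL + 2 HH)`:
#' `100 * hl / (hl + 2 * hh)`.
#'
#' @param p A `pooled_densities` list (or anything with `hh`/`hl`).
#' @return Percent replication in `[0, 100]`.
#' @export
percent_replication <- function(p) {
  if (p$hh < 0 || p$hl < 0) stop("densities must be >= 0")
  if (p$hh + p$hl <= 0)
    stop("undefined percent replication: hh + hl must be > 0")
  100 * p$hl / (p$hl + 2 * p$hh)
}

#' Construct a replication kinetic curve
#'
#' @param fragment_id Fragment label.
#' @param times Strictly increasing sample times (minutes).
#' @param percent Percent replication per time, in `[0, 100]`.
#' @return An object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(fragment_id, times, percent) {
  if (length(times) != length(percent)) stop("times and percent differ")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(percent < -1e-9 | percent > 100 + 1e-9))
    stop("percent values must be in [0, 100]")
  structure(list(fragment_id = fragment_id, times = as.numeric(times),
                 percent = pmin(100, pmax(0, percent))),
            class = "kinetic_curve")
}

#' Estimate the genomic plateau of a kinetic curve
#'
#' Because not every G1 cell enters or completes S phase, population curves
#' plateau below 100%. The plateau is estimated as the mean of the final
#' `k` percent values of the genomic-probe curve.
#'
#' @param genomic_curve A [kinetic_curve()] for the total-genomic probe.
#' @param k Number of trailing samples to average (default 3).
#' @return Plateau percent.
#' @export
estimate_plateau <- function(genomic_curve, k = 3) {
  stopifnot(inherits(genomic_curve, "kinetic_curve"))
  if (k <= 0) stop("k must be positive")
  n <- length(genomic_curve$percent)
  if (k > n) stop("k exceeds the number of curve points")
  mean(genomic_curve$percent[(n - k + 1):n])
}

#' Time of half-maximal replication (T_rep)
#'
#' T_rep is the time at which the kinetic curve reaches half of the plateau
#' value: the first upward crossing of `plateau / 2`, linearly interpolated
#' between the bracketing samples. If the curve already exceeds half-plateau
#' at the first sample, the first time is returned.
#'
#' @param curve A [kinetic_curve()].
#' @param plateau Plateau percent (> 0), typically from [estimate_plateau()]
#'   on a genomic probe.
#' @return T_rep in minutes.
#' @export
estimate_trep <- function(curve, plateau) {
  stopifnot(inherits(curve, "kinetic_curve"))
  if (plateau <= 0) stop("plateau must be > 0")
  half <- plateau / 2
  y <- curve$percent
  t <- curve$times
  if (y[1] >= half) return(t[1])
  above <- which(y >= half)
  if (length(above) == 0L)
    stop(sprintf("locus '%s' did not reach half-maximal replication",
                 curve$fragment_id))
  i <- above[1]
  t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Early/late timing standards
#'
#' @param early_id,late_id Fragment labels of the early (ARS306 role) and
#'   late (R11 role) standards.
#' @param early_trep,late_trep Their measured T_rep values in minutes
#'   (`late_trep > early_trep`).
#' @return An object of class `timing_standards`.
#' @export
timing_standards <- function(early_id, late_id, early_trep, late_trep) {
  if (late_trep <= early_trep) stop("late_trep must exceed early_trep")
  structure(list(early_id = early_id, late_id = late_id,
                 early_trep = early_trep, late_trep = late_trep),
            class = "timing_standards")
}

#' Replication index
#'
#' Rescales T_rep so the early standard maps to 0 and the late standard to
#' 1: `(trep_x - early) / (late - early)`. Values outside `[0, 1]` are
#' possible for loci earlier than the early standard or later than the late
#' one.
#'
#' @param trep_x T_rep of the fragment of interest (minutes).
#' @param standards A [timing_standards()].
#' @return Dimensionless replication index.
#' @export
replication_index <- function(trep_x, standards) {
  stopifnot(inherits(standards, "timing_standards"))
  (trep_x - standards$early_trep) /
    (standards$late_trep - standards$early_trep)
}

#' Fit replication timing from a table of gradient scans
#'
#' The full locus-level inference chain: per fragment and timepoint, pool
#' gradient fractions into HH/HL, convert to percent replication, assemble
#' the kinetic curve, estimate T_rep against the plateau of the genomic
#' probe, and rescale to replication indices against the *measured* T_reps
#' of the early and late standards.
#'
#' @param scans Long-format `data.frame` with columns `fragment_id`,
#'   `time_min`, `fraction`, `signal` (the tab-delimited dialect written by
#'   [simulate_slotblot_experiment()] / read by [read_gradient_tsv()]).
#' @param standards_ids Named character vector `c(early = ..., late = ...)`.
#' @param genomic_id Fragment id of the total-genomic probe.
#' @param hh_window,hl_window Fraction-index windows for pooling; defaults
#'   match the default [gradient_geometry()].
#' @param plateau_k Trailing samples averaged for the genomic plateau.
#' @return An object of class `timing_fit` with components `timing` (a
#'   `data.frame` of `fragment_id`, `trep`, `replication_index`), `curves`,
#'   `plateau`, and `standards`. Methods: `print`, `summary`, `coef`
#'   (named RI vector), `plot`.
#' @export
fit_kinetics <- function(scans,
                         standards_ids = c(early = "ARS306", late = "R11"),
                         genomic_id = "genomic",
                         hh_window = 14:20, hl_window = 6:12,
                         plateau_k = 3) {
  need <- c("fragment_id", "time_min", "fraction", "signal")
  if (!all(need %in% names(scans)))
    stop("scans must have columns fragment_id, time_min, fraction, signal")
  frags <- unique(scans$fragment_id)
  if (!genomic_id %in% frags) stop("genomic probe missing from scans")
  if (!all(standards_ids %in% frags))
    stop("both standard fragments must be present")
  times <- sort(unique(scans$time_min))
  curves <- lapply(frags, function(fr) {
    sub <- scans[scans$fragment_id == fr, ]
    pct <- vapply(times, function(tt) {
      s <- sub[sub$time_min == tt, ]
      if (nrow(s) == 0L)
        stop(sprintf("fragment '%s' missing timepoint %g", fr, tt))
      s <- s[order(s$fraction), ]
      percent_replication(pool_fractions(
        gradient_scan(fr, tt, s$fraction, s$signal),
        hh_window, hl_window))
    }, numeric(1))
    kinetic_curve(fr, times, pct)
  })
  names(curves) <- frags
  plateau <- estimate_plateau(curves[[genomic_id]], k = plateau_k)
  treps <- vapply(curves, estimate_trep, numeric(1), plateau = plateau)
  std <- timing_standards(standards_ids[["early"]], standards_ids[["late"]],
                          treps[[standards_ids[["early"]]]],
                          treps[[standards_ids[["late"]]]])
  keep <- setdiff(frags, genomic_id)
  timing <- data.frame(fragment_id = keep, trep = unname(treps[keep]),
                       replication_index = vapply(
                         treps[keep], replication_index, numeric(1),
                         standards = std),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(timing = timing, curves = curves, plateau = plateau,
                 standards = std, genomic_id = genomic_id,
                 call = match.call()),
            class = "timing_fit")
}

#' @export
print.timing_fit <- function(x, digits = 3, ...) {
  cat("Replication timing fit\n")
  cat(sprintf("  genomic plateau: %.1f%%  (half-max %.1f%%)\n",
              x$plateau, x$plateau / 2))
  cat(sprintf("  standards: %s (T_rep %.1f min) -> RI 0, %s (T_rep %.1f min) -> RI 1\n",
              x$standards$early_id, x$standards$early_trep,
              x$standards$late_id, x$standards$late_trep))
  print(format(x$timing, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.timing_fit <- function(object, ...) {
  ri <- stats::setNames(object$timing$replication_index,
                        object$timing$fragment_id)
  structure(list(timing = object$timing, plateau = object$plateau,
                 standards = object$standards,
                 ri_range = range(ri), n_fragments = length(ri)),
            class = "summary.timing_fit")
}

#' @export
print.summary.timing_fit <- function(x, ...) {
  cat(sprintf("timing_fit: %d fragments, RIs in [%.2f, %.2f], plateau %.1f%%\n",
              x$n_fragments, x$ri_range[1], x$ri_range[2], x$plateau))
  print(format(x$timing, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.timing_fit <- function(object, ...) {
  stats::setNames(object$timing$replication_index, object$timing$fragment_id)
}

#' Plot replication kinetic curves from a timing fit
#'
#' @param x A `timing_fit`.
#' @param fragments Fragments to draw (default: all but the genomic probe).
#' @param ... Passed to `matplot`.
#' @export
plot.timing_fit <- function(x, fragments = NULL, ...) {
  if (is.null(fragments))
    fragments <- setdiff(names(x$curves), x$genomic_id)
  times <- x$curves[[1]]$times
  mat <- sapply(fragments, function(f) x$curves[[f]]$percent)
  graphics::matplot(times, mat, type = "l", lty = 1,
                    xlab = "minutes after release",
                    ylab = "percent replication", ...)
  graphics::abline(h = x$plateau / 2, lty = 3)
  graphics::legend("bottomright", legend = fragments, lty = 1,
                   col = seq_along(fragments), cex = 0.7, bty = "n")
  invisible(x)
}
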