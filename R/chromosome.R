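#' Construct a replication origin
#'
#' An origin is a point locus that can fire during S phase. Firing times are
#' modelled per cell as draws from a normal distribution truncated at zero;
#' `efficiency` is the per-cell probability that the origin fires at all
#' (rather than being replicated passively by an incoming fork).
#'
#' @param id Character label, e.g. `"ARS1410"`.
#' @param position Position in bp (non-negative integer; 0-based coordinates).
#' @param mean_firing_time Mean firing time in minutes from the start of S
#'   phase.
#' @param firing_sd Cell-to-cell standard deviation of the firing time
#'   (minutes, >= 0).
#' @param efficiency Probability in `[0, 1]` that the origin fires in a given
#'   cell cycle.
#' @return A one-row `data.frame` suitable for binding into the `origins`
#'   table of [chromosome_model()].
#' @export
origin <- function(id, position, mean_firing_time, firing_sd = 4,
                   efficiency = 0.85) {
  stopifnot(is.character(id), length(id) == 1L)
  if (position < 0) stop("origin position must be non-negative")
  if (firing_sd < 0) stop("firing_sd must be >= 0")
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  data.frame(id = id, position = as.numeric(position),
             mean_firing_time = as.numeric(mean_firing_time),
             firing_sd = as.numeric(firing_sd),
             efficiency = as.numeric(efficiency),
             stringsAsFactors = FALSE)
}

## Wild-type CDEIII core hexamer; the 3-bp mutant abolishes centromere
## function (used by the cen_dead scenario).
CDEIII_WT <- "TCCGAA"
CDEIII_MUTANT <- "TCTAGA"

#' Construct a centromere annotation
#'
#' A point centromere is functional iff its CDEIII core equals the wild-type
#' hexamer; non-functional centromeres exert no effect on origin timing.
#'
#' @param position Position in bp.
#' @param cdeiii_seq 6-letter CDEIII core sequence (ACGT alphabet). Defaults
#'   to the wild-type core.
#' @return A one-row `data.frame` with columns `position`, `functional`,
#'   `cdeiii_seq`.
#' @export
centromere <- function(position, cdeiii_seq = CDEIII_WT) {
  if (position < 0) stop("centromere position must be non-negative")
  cdeiii_seq <- toupper(cdeiii_seq)
  if (nchar(cdeiii_seq) != 6L || grepl("[^ACGT]", cdeiii_seq))
    stop("cdeiii_seq must be a 6-letter ACGT string")
  data.frame(position = as.numeric(position),
             functional = identical(cdeiii_seq, CDEIII_WT),
             cdeiii_seq = cdeiii_seq, stringsAsFactors = FALSE)
}

#' Construct a linear chromosome model
#'
#' @param name Chromosome label.
#' @param length Chromosome length in bp (> 0).
#' @param origins `data.frame` of origins (rows from [origin()]), positions
#'   strictly increasing and within the chromosome.
#' @param centromeres Optional `data.frame` of centromere annotations (rows
#'   from [centromere()]). More than one row is allowed so that engineered
#'   strains carrying an extra, non-functional centromere can be modelled.
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(name, length, origins, centromeres = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length <= 0) stop("chromosome length must be > 0")
  if (nrow(origins) > 0) {
    if (any(origins$position < 0) || any(origins$position > length))
      stop("origin positions must lie within [0, length]")
    if (is.unsorted(origins$position, strictly = TRUE))
      stop("origin positions must be strictly increasing")
    if (any(origins$efficiency < 0 | origins$efficiency > 1))
      stop("origin efficiencies must be in [0, 1]")
    if (any(origins$firing_sd < 0)) stop("firing_sd must be >= 0")
  }
  if (!is.null(centromeres) && nrow(centromeres) > 0) {
    if (any(centromeres$position < 0) || any(centromeres$position > length))
      stop("centromere positions must lie within [0, length]")
    rownames(centromeres) <- NULL
  }
  rownames(origins) <- NULL
  structure(list(name = name, length = as.numeric(length),
                 origins = origins, centromeres = centromeres),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  ncen <- if (is.null(x$centromeres)) 0L else nrow(x$centromeres)
  cat(sprintf("<chromosome_model> %s: %.0f bp, %d origins, %d centromere(s)\n",
              x$name, x$length, nrow(x$origins), ncen))
  if (ncen > 0) {
    fun <- ifelse(x$centromeres$functional, "functional", "non-functional")
    cat(sprintf("  CEN at %.0f bp (%s)\n", x$centromeres$position, fun))
  }
  invisible(x)
}

#' Centromere timing-advance effect
#'
#' Phenomenological model of centromere-dependent early origin activation: a
#' functional centromere advances the mean firing time of nearby origins,
#' with the advance decaying with distance and vanishing beyond `range_bp`
#' (~19 kb, the distance at which the effect is severely diminished).
#'
#' @param max_advance Maximum advance in minutes, applied at distance 0.
#' @param range_bp Decay range in bp (> 0).
#' @param decay Decay shape: `"linear"` (default), `"exponential"` (scale
#'   `range_bp`/3, hard zero beyond `range_bp`), or `"step"` (full advance
#'   within `range_bp`).
#' @return An object of class `centromere_effect`.
#' @export
centromere_effect <- function(max_advance = 45, range_bp = 19000,
                              decay = c("linear", "exponential", "step")) {
  decay <- match.arg(decay)
  if (max_advance < 0) stop("max_advance must be >= 0")
  if (range_bp <= 0) stop("range_bp must be > 0")
  structure(list(max_advance = max_advance, range_bp = range_bp,
                 decay = decay), class = "centromere_effect")
}

#' @export
print.centromere_effect <- function(x, ...) {
  cat(sprintf("<centromere_effect> %s decay, max advance %.1f min, range %.0f bp\n",
              x$decay, x$max_advance, x$range_bp))
  invisible(x)
}

decay_factor <- function(d, effect) {
  f <- switch(effect$decay,
              linear = pmax(0, 1 - d / effect$range_bp),
              exponential = exp(-3 * d / effect$range_bp),
              step = as.numeric(d <= effect$range_bp))
  ## all shapes are zero beyond the stated range
  f[d >= effect$range_bp] <- 0
  f
}

#' Apply the centromere timing-advance effect to a chromosome
#'
#' Each *functional* centromere advances every origin's mean firing time by
#' `max_advance * decay(|origin - centromere|)`, floored at 0 minutes. With
#' several functional centromeres the largest advance wins. Non-functional
#' centromeres (mutated CDEIII) leave the chromosome unchanged.
#'
#' @param chrom A [chromosome_model()].
#' @param effect A [centromere_effect()].
#' @return A modified copy of `chrom`.
#' @export
apply_centromere_effect <- function(chrom, effect) {
  stopifnot(inherits(chrom, "chromosome_model"),
            inherits(effect, "centromere_effect"))
  cen <- chrom$centromeres
  if (is.null(cen) || nrow(cen) == 0L || !any(cen$functional)) return(chrom)
  cen <- cen[cen$functional, , drop = FALSE]
  adv <- rep(0, nrow(chrom$origins))
  for (i in seq_len(nrow(cen))) {
    d <- abs(chrom$origins$position - cen$position[i])
    adv <- pmax(adv, effect$max_advance * decay_factor(d, effect))
  }
  chrom$origins$mean_firing_time <-
    pmax(0, chrom$origins$mean_firing_time - adv)
  chrom
}
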