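#' Read / write tab-delimited gradient tables
#'
#' Columns: `fragment_id`, `time_min`, `fraction`, `signal`.
#'
#' @param file Path.
#' @return `data.frame` (for the reader).
#' @export
read_gradient_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("fragment_id", "time_min", "fraction", "signal")
  if (!all(need %in% names(df)))
    stop(file, ": expected columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_gradient_tsv
#' @param scans Gradient `data.frame` to write.
#' @export
write_gradient_tsv <- function(scans, file) {
  utils::write.table(scans, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write tab-delimited probe tables
#'
#' Columns: `chrom`, `position`, `time_min`, `hh_intensity`,
#' `hl_intensity` (raw two-channel array intensities).
#'
#' @param file Path.
#' @export
read_probe_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "time_min", "hh_intensity", "hl_intensity")
  if (!all(need %in% names(df)))
    stop(file, ": expected columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_probe_tsv
#' @param probes Probe `data.frame` to write.
#' @export
write_probe_tsv <- function(probes, file) {
  utils::write.table(probes, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write Z-score tables
#'
#' Columns: `chrom`, `position`, `time_min`, `z`.
#'
#' @param file Path.
#' @return The reader returns a list of `zprofile_set`-compatible objects
#'   (one per timepoint) for use with [detect_timing_differences()].
#' @export
read_z_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "time_min", "z")
  if (!all(need %in% names(df)))
    stop(file, ": expected columns ", paste(need, collapse = ", "))
  lapply(sort(unique(df$time_min)), function(tt) {
    s <- df[df$time_min == tt, ]
    profs <- lapply(split(s, s$chrom), function(sc) {
      sc <- sc[order(sc$position), ]
      list(chrom = sc$chrom[1], positions = sc$position,
           zvalues = sc$z, time = tt)
    })
    structure(list(profiles = profs, mu = NA_real_, sigma = NA_real_,
                   time = tt), class = "zprofile_set")
  })
}

#' @rdname read_z_tsv
#' @param zsets List of `zprofile_set` objects to write.
#' @export
write_z_tsv <- function(zsets, file) {
  if (inherits(zsets, "zprofile_set")) zsets <- list(zsets)
  rows <- lapply(zsets, function(zs) {
    do.call(rbind, lapply(zs$profiles, function(p) {
      data.frame(chrom = p$chrom, position = p$positions,
                 time_min = zs$time, z = p$zvalues,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a timing table
#'
#' Tab-delimited `fragment_id`, `trep_min`, `replication_index`.
#'
#' @param fit A `timing_fit` from [fit_kinetics()].
#' @param file Path.
#' @export
write_timing_tsv <- function(fit, file) {
  stopifnot(inherits(fit, "timing_fit"))
  out <- data.frame(fragment_id = fit$timing$fragment_id,
                    trep_min = fit$timing$trep,
                    replication_index = fit$timing$replication_index)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

profiles_to_granges <- function(profiles, value_field = "values") {
  chrom <- unlist(lapply(profiles, function(p)
    rep(p$chrom, length(p$positions))))
  pos <- unlist(lapply(profiles, `[[`, "positions"))
  spacing <- unlist(lapply(profiles, function(p) {
    s <- if (length(p$positions) > 1) stats::median(diff(p$positions)) else 1
    rep(s, length(p$positions))
  }))
  score <- unlist(lapply(profiles, `[[`, value_field))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = pos + 1,
                                          end = pos + spacing),
                         score = score)
}

#' Export replication or Z profiles as bedGraph
#'
#' @param profiles Named list of [replication_profile()]s, or a
#'   `zprofile_set`.
#' @param file Output path.
#' @export
write_profile_bedgraph <- function(profiles, file) {
  gr <- if (inherits(profiles, "zprofile_set"))
    profiles_to_granges(profiles$profiles, "zvalues")
  else profiles_to_granges(profiles, "values")
  rtracklayer::export.bedGraph(gr, file)
  invisible(file)
}

#' Export peak calls or difference regions as BED
#'
#' @param x A peaks `data.frame` (from [call_peaks()]) or differences
#'   `data.frame` (from [detect_timing_differences()]).
#' @param file Output path.
#' @export
write_region_bed <- function(x, file) {
  if (nrow(x) == 0) {
    file.create(file)
    return(invisible(file))
  }
  if ("start" %in% names(x)) {
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(start = x$start + 1,
                                                  end = x$end),
                                 score = x$max_abs_delta_z)
  } else {
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(start = x$position + 1,
                                                  end = x$position + 1),
                                 score = x$prominence)
  }
  rtracklayer::export.bed(gr, file)
  invisible(file)
}

#' Write / read a scenario config
#'
#' A structured YAML description of the scenario: chromosomes with their
#' origins and centromeres, named loci, anchors, centromere-effect and
#' simulation parameters.
#'
#' @param scenario A [build_scenario()] result.
#' @param file Path.
#' @export
write_scenario_config <- function(scenario, file) {
  cfg <- list(
    name = scenario$name,
    anchors = as.list(scenario$anchors),
    standards = as.list(scenario$standards_ids),
    firing_sd = scenario$firing_sd,
    efficiency = scenario$efficiency,
    ars1531_knockout = scenario$ars1531_knockout,
    effect = unclass(scenario$effect),
    params = unclass(scenario$params),
    loci = scenario$loci,
    chromosomes = lapply(scenario$chromosomes, function(ch) {
      list(name = ch$name, length = ch$length, origins = ch$origins,
           centromeres = ch$centromeres)
    }))
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' @rdname write_scenario_config
#' @return `read_scenario_config()` returns the config as a list with
#'   `chromosomes` rebuilt as [chromosome_model()] objects and `params` /
#'   `effect` as their classed types.
#' @export
read_scenario_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg$params <- do.call(sim_params, cfg$params[setdiff(names(cfg$params),
                                                       "seed")])
  cfg$effect <- centromere_effect(cfg$effect$max_advance,
                                  cfg$effect$range_bp, cfg$effect$decay)
  if (!is.null(cfg$loci)) cfg$loci <- as.data.frame(cfg$loci)
  num <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  cfg$chromosomes <- lapply(cfg$chromosomes, function(ch) {
    ors <- num(as.data.frame(ch$origins),
               c("position", "mean_firing_time", "firing_sd", "efficiency"))
    cen <- if (!is.null(ch$centromeres))
      num(as.data.frame(ch$centromeres), "position")
    chromosome_model(ch$name, as.numeric(ch$length), ors, cen)
  })
  cfg
}

#' Write a JSON run manifest
#'
#' @param file Path.
#' @param command Subcommand or function name.
#' @param inputs Named list/vector of input paths.
#' @param outputs Character vector of written files.
#' @param seed Integer seed used (or `NA`).
#' @param config Named list of thresholds/settings.
#' @export
write_manifest <- function(file, command, inputs = list(),
                           outputs = character(), seed = NA,
                           config = list()) {
  manifest <- list(command = command, inputs = inputs, outputs = outputs,
                   seed = seed, config = config,
                   package_version =
                     as.character(utils::packageVersion("repkin")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
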