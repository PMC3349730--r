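#' Replicate recovery of replication indices from simulated slot blots
#'
#' The parameter-recovery experiment used to validate the whole inference
#' chain: simulate the slot-blot experiment `n_reps` times (independent
#' cell populations and measurement noise, seeds `seed_base + 1 ...
#' seed_base + n_reps`), fit each with [fit_kinetics()], and collect the
#' replication indices.
#'
#' @param scenario A [build_scenario()] result.
#' @param n_reps Number of replicate experiments.
#' @param seed_base Integer; replicate r uses seed `seed_base + r`.
#' @param times Sample times (minutes).
#' @param geometry,noise Simulator settings.
#' @return An object of class `ri_recovery`: list with `ri` (replicates x
#'   loci matrix), `mean_ri`, `truth` (the scenario truth table), and
#'   `scenario_name`.
#' @export
recover_replication_indices <- function(scenario, n_reps = 25,
                                        seed_base = 0,
                                        times = seq(0, 140, by = 10),
                                        geometry = gradient_geometry(),
                                        noise = noise_model()) {
  fits <- lapply(seq_len(n_reps), function(r) {
    scans <- simulate_slotblot_experiment(scenario, times = times,
                                          geometry = geometry,
                                          noise = noise,
                                          seed = seed_base + r)
    fit_kinetics(scans, standards_ids = scenario$standards_ids,
                 genomic_id = "genomic")
  })
  ri <- do.call(rbind, lapply(fits, coef))
  structure(list(ri = ri, mean_ri = colMeans(ri),
                 truth = scenario_truth_table(scenario),
                 scenario_name = scenario$name, n_reps = n_reps),
            class = "ri_recovery")
}

#' @export
print.ri_recovery <- function(x, ...) {
  cat(sprintf("<ri_recovery> scenario '%s', %d replicates\n",
              x$scenario_name, x$n_reps))
  named <- intersect(x$truth$locus, colnames(x$ri))
  tab <- data.frame(locus = named,
                    true_ri = x$truth$true_ri[match(named, x$truth$locus)],
                    mean_ri = x$mean_ri[named],
                    sd_ri = apply(x$ri[, named, drop = FALSE], 2,
                                  stats::sd))
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}
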