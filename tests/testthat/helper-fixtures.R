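## Shared builders for small, fully controlled fixtures.

## deterministic parameters: every cell cycles, enters S at exactly
## `entry` minutes, and every origin fires at its mean time
det_params <- function(entry = 0, n_cells = 50, v = 1500) {
  sim_params(fork_velocity = v, s_entry_mean = entry, s_entry_sd = 0,
             fraction_cycling = 1, n_cells = n_cells)
}

det_chromosome <- function(name = "chrT", length = 100000,
                           positions = c(20000, 80000),
                           firing = c(10, 20), sd = 0, eff = 1) {
  ors <- do.call(rbind, Map(function(i, p, m)
    origin(sprintf("ori%d", i), p, m, firing_sd = sd, efficiency = eff),
    seq_along(positions), positions, firing))
  chromosome_model(name, length, ors)
}

## independent fork-propagation oracle: distance transform on a 1-bp grid
## (forward + backward min-plus passes), entirely separate from the
## closed-form kinematics in the package
fork_oracle <- function(chrom_length, origin_pos, firing_times, v) {
  t <- rep(Inf, chrom_length + 1)
  t[origin_pos + 1] <- pmin(t[origin_pos + 1], firing_times)
  step <- 1 / v
  for (i in 2:length(t)) t[i] <- min(t[i], t[i - 1] + step)
  for (i in (length(t) - 1):1) t[i] <- min(t[i], t[i + 1] + step)
  t
}

noiseless <- function() noise_model(signal_cv = 0, background = 0)
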