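---
title: "Models and methods behind repkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repkin)
```

This vignette describes the models implemented in **repkin**, the choices
made where the underlying experimental protocol leaves room, and what the
simulation-based validation does and does not establish.

## The forward model of S phase

A chromosome is a linear sequence of origins, each with a position, a mean
firing time (minutes from S-phase entry), a cell-to-cell firing-time
standard deviation, and an efficiency (the probability of firing in a given
cell cycle). Per cell:

* each origin fires independently with its efficiency; fired origins draw a
  firing time from a normal distribution truncated at zero;
* cells in which no origin fires are resampled — a chromosome must finish
  replication. This makes the model inexact when the product of
  (1 − efficiency) over origins is non-negligible; with the default
  efficiency (0.85) and ≥ 2 origins per chromosome the resampling rate is
  ≤ 2.3%;
* forks move bidirectionally at constant velocity; a locus is replicated by
  the first arriving fork, so its replication time is
  `min_i(firing_i + |x − position_i| / v)`. Unfired origins are replicated
  passively. There is no re-firing, no fork stalling, and no
  telomere-specific delay;
* each cell enters S phase after a delay drawn from a normal distribution
  truncated at zero, and only a fraction of cells (`fraction_cycling`,
  default 0.8) enters S at all. Non-cycling cells contribute permanently
  unreplicated DNA, which is what makes population kinetic curves plateau
  below 100% and why T_rep must be measured against a genomic-probe
  plateau.

Coordinates are 0-based, positions in bp, and intervals half-open. All
stochastic steps run off explicit seeds; one seeded generator drives each
simulated experiment, and all loci of an experiment share one simulated
cell population, so spatial structure is coherent within cells.

Defaults: fork velocity 1,500 bp/min (mid-range for budding yeast; the
protocol itself does not fix one), firing SD 4 min, S-entry delay
35 ± 4 min, 80% of cells cycling, 500 cells per simulated population.
All are arguments, not constants; the gradient and noise defaults are
described below.

## The centromere effect

A functional point centromere advances the mean firing time of nearby
origins. The effect is phenomenological: advance = `max_advance ·
decay(d)`, floored so firing times stay non-negative, with `decay`
linear by default (zero at `range_bp` = 19 kb, the distance at which the
effect is severely diminished in the data this package models).
Exponential and step decays are available because the true functional form
is not identified by the available measurements; only the ordering
predictions (closer origin ⇒ larger advance; relocation inverts the
early/late order of the flanking origins) are robust to that choice, and
only those are asserted in tests. A centromere whose CDEIII core hexamer
differs from the wild-type sequence is non-functional and exerts no
effect.

## Scenario calibration

The three shipped scenarios (`wt`, `rearranged`, `cen_dead`) encode the
relative geometry of the chromosome XIV experiment (MET2 BglII site 8.5 kb
left of ARS1410; native centromere 6.8 kb left of ARS1426 and 19 kb right
of ARS1424; relocated centromere 11.5 kb from ARS1410) on an invented
784-kb coordinate system, plus standards, control, and chromosome XV-like
chromosomes and filler origins at realistic ~40–60 kb spacing so the whole
genome completes S phase by ~130 min and the genomic curve plateaus inside
the sampled window.

Each named locus has a target replication index taken from the measured
slot-blot values of the corresponding strain; targets map to minutes via
`trep = early + RI · (late − early)` with anchors 45 and 95 min, chosen
inside the observed S-phase window (entry by ~40 min, 2C by ~140 min).
Origin mean firing times are then back-calculated so that the *population
median* replication time of the locus equals its target: for an origin
with efficiency e and firing SD s the locus median sits at
`mean + s · qnorm(0.5 / e)` (the passive-replication tail lies later in
all shipped layouts), so the mean is set that much earlier. Firing times
are calibrated per scenario rather than generated from the centromere
effect because no single smooth distance-decay reproduces all measured
values simultaneously (see "Known limitations").

MET2 carries no origin; its truth follows from fork kinematics off
ARS1410 (8.5 kb ⇒ ~5.7 min at the default velocity), which lands within
0.02 RI of its measured wild-type value — a nontrivial consistency check
of the kinematic model.

## Observation models

**Slot blots.** For each locus and sample time the simulator computes the
replicated molecule fraction `f`, places mass `1 − f` at the HH gradient
peak and `2f` at the HL peak (two hybrid daughters per replicated
molecule), spreads each peak as a Gaussian over 25 fractions (HH peak at
fraction 17, HL at 9, SD 1.2 fractions — invented but representative
geometry), multiplies by mean-one lognormal noise (default CV 5%) and adds
a flat background (default 0.005 per fraction). The genomic probe is the
unweighted mean of `f` over a 5-kb grid spanning every chromosome.

**Arrays.** Probes sit on a regular grid (default 1 kb); per probe,
channel intensities are `hh ∝ 1 − f` and `hl ∝ 2f` with independent
lognormal noise and global per-channel scale factors emulating labelling
differences. Median channel equalization removes the global scales;
because it equalizes medians rather than molecule counts, per-probe
percent values are exact only when the two channel medians represent equal
molecule numbers — Z-scores, peak positions, and difference calls, which
are what the array layer feeds, are insensitive to this monotone
distortion. Probes with both channels zero are dropped and recorded.

## Inference choices

* **Pooling**: HH/HL windows default to fractions 14–20 and 6–12
  (±3 SD around the default peaks); the median signal of fractions outside
  both windows is subtracted as background, floored at zero.
* **Plateau**: mean of the final 3 genomic-curve samples. The protocol
  says only "plateau"; 3 trailing points of a 15-point curve is a
  bias/variance compromise, exposed as `plateau_k`.
* **T_rep**: first upward crossing of half-plateau, linearly interpolated
  between bracketing samples; the first-crossing rule resolves
  non-monotone noisy curves deterministically. With 10-min sampling,
  chord interpolation on a sigmoid curve biases T_rep by at most ~2 min
  (≤ 0.04 RI); the bias largely cancels in the RI because the standards
  are measured through the same chain.
* **RI**: implemented as `(T_rep(X) − early) / (late − early)`. The
  denominator orientation is fixed by the anchor conventions (early → 0,
  late → 1); the reversed orientation sometimes seen in print would
  assign the late standard −1.
* **Smoothing**: 18-kb *full-width* box mean (±9 kb), truncated at
  chromosome ends; probe-count weighting and loess alternatives were
  rejected to keep the estimator transparent.
* **Z-scores**: genome-wide mean and *population* SD per timed sample.
  With thousands of probes the sample/population distinction is
  negligible, but fixing it makes results bit-reproducible. Per-chromosome
  normalization was rejected: the reference procedure normalizes against
  the genomic average.
* **Sample matching**: strains are compared at a timepoint only if their
  genome-mean percent replication differs by ≤ 10 percentage points
  (configurable); mismatched pairs are excluded with a warning.
* **Difference calls**: runs of ≥ 3 consecutive probes with |ΔZ| ≥ 1.5 at
  *every* matched timepoint. The thresholds are calibrated so that the
  wild-type vs rearranged comparison flags exactly the two pericentric
  regions and nothing else, with same-scenario replicate pairs yielding
  zero calls; both are exposed as arguments/CLI flags. Comparisons default
  to mid-S samples (60, 65, 70 min) because persistent differences are
  only measurable while both loci are on the rising part of their curves.
* **Peaks**: strict local maxima with a walk-out prominence; chromosome
  ends are never peaks.
* **Fragments** are treated as points (a fragment is replicated when its
  midpoint is): slot-blot fragments are small relative to fork travel per
  sampling interval.

## Problem sizes used in validation

Default populations are 500 cells per chromosome; recovery experiments use
25 replicates per scenario; array simulations use 1-kb probe spacing over
a ~1.4-Mb five-chromosome genome and three timepoints; the false-positive
control uses 20 replicate pairs. These sizes put Monte-Carlo error well
below the decision thresholds (replicate SD of a mean RI ≈ 0.002) while
keeping the full validation suite fast.

## What the simulations do and do not show

The generator emulates: synchronized but imperfect S-phase entry,
sub-100% plateaus, molecule-level HH/HL bookkeeping, gradient peak
spreading, multiplicative signal noise, channel scale factors, and the
coherent spatial correlation that comes from sharing cell populations
across loci. It does **not** emulate: partially replicated fragments at
intermediate buoyant density, dye-bias curves or spatial array artifacts,
fork stalling or checkpoint control, re-replication, or sequence-driven
origin activity. Passing recovery tests therefore demonstrates that the
inference chain is a consistent estimator of the simulator's ground truth
under realistic noise — not that real arrays or gradients are free of the
systematic effects excluded above.

## Known limitations

* Under uniform-velocity bidirectional forks, a late origin closer than
  `(ΔT·v)` to a much earlier one cannot keep its late population median —
  the early fork arrives first. In the rearranged scenario this caps the
  recoverable RI of ARS1426 (25.8 kb from the early ARS1424) near 0.6,
  while the measured value for that strain is 0.79; reproducing both
  measured values simultaneously would require a locally slower fork, an
  inefficient ARS1424, or fragment-scale effects that this model
  deliberately excludes. The pipeline faithfully recovers the
  simulator's true (kinematically capped) value; the ordering inversion
  between the strains is reproduced in every replicate. The analogous
  tension exists for MET2 in the rearranged strain (measured nearly
  simultaneous with ARS1410 despite 8.5 kb of fork travel).
* The resampling rule for zero-fired-origin cells slightly enriches
  low-efficiency origins' firing rates on sparse chromosomes.
* The centromere effect is phenomenological; it makes no mechanistic
  claims about kinetochore assembly or pericentric chromatin structure.
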