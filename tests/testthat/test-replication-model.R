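test_that("domain constructors enforce their invariants", {
  expect_error(origin("a", -5, 10), "non-negative")
  expect_error(origin("a", 5, 10, efficiency = 1.2), "efficiency")
  expect_error(origin("a", 5, 10, firing_sd = -1), "firing_sd")
  expect_error(centromere(100, "TCCGAAA"), "6-letter")
  expect_true(centromere(100)$functional)
  expect_false(centromere(100, "TCTAGA")$functional)
  ors <- rbind(origin("a", 5000, 10), origin("b", 2000, 12))
  expect_error(chromosome_model("c", 10000, ors), "strictly increasing")
  expect_error(chromosome_model("c", 4000, rbind(origin("a", 5000, 10))),
               "within")
  expect_error(centromere_effect(range_bp = 0), "range_bp")
})

test_that("centromere effect advances origins by distance-decayed amounts", {
  eff <- centromere_effect(max_advance = 30, range_bp = 19000)
  ors <- rbind(origin("at_cen", 100000, 40),
               origin("mid", 109500, 40),
               origin("far", 125000, 40))
  ch <- chromosome_model("c", 200000, ors, centromere(100000))
  out <- apply_centromere_effect(ch, eff)
  # full advance at d = 0, half at d = range/2, none at d >= range
  expect_equal(out$origins$mean_firing_time, c(10, 25, 40))
  # advance floors at 0 minutes
  ch2 <- chromosome_model("c", 200000, rbind(origin("o", 100000, 12)),
                          centromere(100000))
  expect_equal(apply_centromere_effect(ch2, eff)$origins$mean_firing_time, 0)
})

test_that("non-functional or absent centromeres leave timing unchanged", {
  eff <- centromere_effect(max_advance = 30, range_bp = 19000)
  ors <- rbind(origin("o1", 95000, 40), origin("o2", 130000, 55))
  dead <- chromosome_model("c", 200000, ors, centromere(100000, "TCTAGA"))
  expect_equal(apply_centromere_effect(dead, eff)$origins, ors)
  none <- chromosome_model("c", 200000, ors)
  expect_equal(apply_centromere_effect(none, eff)$origins, ors)
})

test_that("centromere advance is non-increasing with distance, all decays", {
  d <- seq(0, 30000, by = 500)
  for (shape in c("linear", "exponential", "step")) {
    eff <- centromere_effect(30, 19000, decay = shape)
    ors <- do.call(rbind, Map(function(i, p) origin(sprintf("o%d", i), p, 60),
                              seq_along(d), 100000 + d))
    ch <- chromosome_model("c", 200000, ors, centromere(100000))
    ft <- apply_centromere_effect(ch, eff)$origins$mean_firing_time
    adv <- 60 - ft
    expect_true(all(diff(adv) <= 1e-12))
    expect_equal(adv[d >= 19000], rep(0, sum(d >= 19000)))
  }
})

test_that("sample_cell respects efficiency and firing determinism", {
  p <- det_params()
  ch <- det_chromosome(positions = 50000, firing = 12)
  set.seed(1)
  for (i in 1:10) {
    cell <- sample_cell(ch, p)
    expect_true(cell$fired)
    expect_equal(cell$firing_times, 12)
  }
  # an efficiency-0 origin never fires; its partner carries the cell
  ors <- rbind(origin("dead", 20000, 10, efficiency = 0),
               origin("live", 80000, 20, efficiency = 1))
  ch2 <- chromosome_model("c", 100000, ors)
  set.seed(2)
  fired <- replicate(200, sample_cell(ch2, p)$fired[1])
  expect_false(any(fired))
  # unsatisfiable chromosome
  ch3 <- chromosome_model("c", 100000,
                          rbind(origin("dead", 20000, 10, efficiency = 0)))
  expect_error(sample_cell(ch3, p), "efficiency 0")
})

test_that("firing fraction matches the binomial oracle at efficiency 0.6", {
  p <- det_params()
  ch <- chromosome_model("c", 100000,
                         rbind(origin("a", 30000, 10, efficiency = 0.6),
                               origin("b", 70000, 10, efficiency = 1)))
  set.seed(42)
  n <- 10000
  fired <- sum(replicate(n, sample_cell(ch, p)$fired[1]))
  ci <- qbinom(c(0.005, 0.995), n, 0.6)
  expect_gte(fired, ci[1])
  expect_lte(fired, ci[2])
})

test_that("locus replication time follows bidirectional fork kinematics", {
  p <- det_params(v = 1500)
  ch <- det_chromosome(positions = c(0, 100000), firing = c(10, 20))
  set.seed(1)
  cell <- sample_cell(ch, p)
  # at a fired origin: its own firing time
  expect_equal(locus_replication_time(cell, ch, 0, p), 10)
  # interior point: min over both origins' fork arrivals
  expect_equal(locus_replication_time(cell, ch, 50000, p),
               10 + 50000 / 1500, tolerance = 1e-12)
  # midway between same-time origins: firing + half-gap / velocity
  ch2 <- det_chromosome(positions = c(0, 100000), firing = c(15, 15))
  cell2 <- sample_cell(ch2, p)
  expect_equal(locus_replication_time(cell2, ch2, 50000, p),
               15 + 50000 / 1500, tolerance = 1e-12)
  expect_error(locus_replication_time(cell, ch, 200000, p), "outside")
})

test_that("replication time is piecewise linear with slopes +/- 1/v", {
  p <- det_params(v = 1000)
  ch <- det_chromosome(length = 60000, positions = c(10000, 50000),
                       firing = c(5, 25))
  set.seed(3)
  cell <- sample_cell(ch, p)
  x <- seq(0, 60000, by = 500)
  t <- vapply(x, function(xx) locus_replication_time(cell, ch, xx, p),
              numeric(1))
  slopes <- diff(t) / diff(x)
  expect_true(all(abs(abs(slopes) - 1 / 1000) < 1e-12 | abs(slopes) < 1e-12))
})

test_that("kinematics agree with a 1-bp fork-propagation oracle", {
  p <- det_params(v = 1500)
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(10000:50000, 1)
    k <- sample(1:4, 1)
    pos <- sort(sample(0:L, k))
    while (anyDuplicated(pos)) pos <- sort(sample(0:L, k))
    firing <- runif(k, 0, 40)
    ors <- do.call(rbind, Map(function(i, pp, m)
      origin(sprintf("o%d", i), pp, m, firing_sd = 0, efficiency = 1),
      seq_len(k), pos, firing))
    ch <- chromosome_model("c", L, ors)
    cell <- sample_cell(ch, p)
    oracle <- fork_oracle(L, pos, cell$firing_times, 1500)
    for (x in sample(0:L, 20)) {
      expect_equal(locus_replication_time(cell, ch, x, p), oracle[x + 1],
                   tolerance = 1e-9)
    }
  }
})

test_that("fraction replicated is 0 at t=0, monotone, and capped by cycling", {
  ch <- det_chromosome(positions = 50000, firing = 10, sd = 2, eff = 0.9)
  p <- sim_params(s_entry_mean = 20, s_entry_sd = 5, fraction_cycling = 0.8,
                  n_cells = 2000, seed = 5)
  ts <- seq(0, 200, by = 5)
  f <- fraction_replicated(ch, 50000, ts, p)
  expect_equal(f[1], 0)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= 0.8 + 1e-12))
  # large t approaches fraction_cycling, not 1 (binomial 99.9% band)
  band <- qbinom(c(0.0005, 0.9995), 2000, 0.8) / 2000
  expect_gte(f[length(f)], band[1])
  expect_lte(f[length(f)], band[2])
})

test_that("deterministic single origin yields a step kinetic curve", {
  ch <- det_chromosome(positions = 20000, firing = 10)
  p <- det_params(entry = 30, n_cells = 20, v = 1500)
  x <- 50000  # 30 kb from the origin: 20 min fork travel
  step_at <- 30 + 10 + 20
  expect_equal(fraction_replicated(ch, x, step_at - 0.01, p), 0)
  expect_equal(fraction_replicated(ch, x, step_at + 0.01, p), 1)
})

test_that("true profiles peak at origins and flatten after completion", {
  p <- det_params(entry = 0, n_cells = 30)
  ch <- det_chromosome(length = 100000, positions = 40000, firing = 5)
  prof <- true_profile(ch, t = 25, grid_spacing = 1000, p)
  expect_equal(prof$fraction[prof$position == 40000], max(prof$fraction))
  # non-increasing away from the origin on each side
  expect_true(all(diff(prof$fraction[prof$position <= 40000]) >= -1e-12))
  expect_true(all(diff(prof$fraction[prof$position >= 40000]) <= 1e-12))
  done <- true_profile(ch, t = 500, grid_spacing = 1000, p)
  expect_true(all(done$fraction == 1))
  # earlier left origin gives the higher left peak early in S
  ch2 <- det_chromosome(length = 100000, positions = c(25000, 75000),
                        firing = c(5, 15))
  prof2 <- true_profile(ch2, t = 10, grid_spacing = 500, p)
  expect_gt(prof2$fraction[prof2$position == 25000],
            prof2$fraction[prof2$position == 75000])
})

test_that("bedGraph export of a true profile round-trips", {
  p <- det_params(entry = 0, n_cells = 10)
  ch <- det_chromosome(length = 20000, positions = 10000, firing = 5)
  prof <- true_profile(ch, t = 8, grid_spacing = 1000, p)
  f <- tempfile(fileext = ".bedgraph")
  export_bedgraph(prof, f, chrom_length = ch$length)
  gr <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(length(gr), nrow(prof))
  expect_equal(gr$score, prof$fraction)
})

test_that("centromere relocation inverts the true timing order of the flanking origins", {
  # intrinsic (centromere-free) firing times; the relocated centromere must
  # make ARS1410 earlier than ARS1426, the native arrangement the reverse
  base <- rbind(origin("ARS1410", 450000, 45),
                origin("ARS1424", 609000, 20),
                origin("ARS1426", 634800, 46))
  eff <- centromere_effect(max_advance = 45, range_bp = 19000)
  wt <- apply_centromere_effect(
    chromosome_model("chrXIV", 784000, base, centromere(628000)), eff)
  re <- apply_centromere_effect(
    chromosome_model("chrXIV", 784000, base, centromere(438500)), eff)
  t_wt <- setNames(wt$origins$mean_firing_time, wt$origins$id)
  t_re <- setNames(re$origins$mean_firing_time, re$origins$id)
  expect_lt(t_wt[["ARS1426"]], t_wt[["ARS1410"]])
  expect_lt(t_re[["ARS1410"]], t_re[["ARS1426"]])
})
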