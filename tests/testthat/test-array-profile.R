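make_probes <- function(chrom, positions, time, f,
                        scales = c(hh = 1, hl = 1)) {
  data.frame(chrom = chrom, position = positions, time_min = time,
             hh_intensity = (1 - f) * scales[["hh"]],
             hl_intensity = 2 * f * scales[["hl"]],
             stringsAsFactors = FALSE)
}

test_that("per-probe percent replication recovers molecule fractions", {
  f <- c(0, 0.25, 0.5, 0.75, 1)
  probes <- make_probes("c1", seq(1000, 5000, 1000), 40, f)
  out <- probe_percent_replication(probes, norm = "none")
  expect_equal(out$t40$c1$values, 100 * f, tolerance = 1e-12)
  # hl = 2*hh gives 50%
  p2 <- data.frame(chrom = "c1", position = 1000, time_min = 40,
                   hh_intensity = 3, hl_intensity = 6)
  p2 <- rbind(p2, transform(p2, position = 2000))
  expect_equal(probe_percent_replication(p2, norm = "none")$t40$c1$values,
               c(50, 50))
})

test_that("median channel normalization removes global scale factors", {
  set.seed(7)
  f <- runif(40, 0.05, 0.95)
  pos <- seq(1000, 40000, 1000)
  a <- probe_percent_replication(make_probes("c1", pos, 40, f))
  b <- probe_percent_replication(
    make_probes("c1", pos, 40, f, scales = c(hh = 3, hl = 7)))
  expect_equal(a$t40$c1$values, b$t40$c1$values, tolerance = 1e-9)
})

test_that("all-zero probes are dropped and recorded", {
  probes <- make_probes("c1", seq(1000, 4000, 1000), 40,
                        c(0.2, 0.4, 0.6, 0.8))
  probes[2, c("hh_intensity", "hl_intensity")] <- 0
  out <- probe_percent_replication(probes, norm = "none")
  expect_equal(length(out$t40$c1$positions), 3)
  expect_equal(nrow(attr(out, "dropped")), 1)
  expect_equal(attr(out, "dropped")$position, 2000)
})

test_that("window smoothing averages probes within half a window", {
  p <- replication_profile("c1", c(0, 1000, 2000), c(0, 30, 0), 40)
  sm <- smooth_profile(p, window_bp = 18000)
  expect_equal(sm$values, c(10, 10, 10))
  expect_true(sm$smoothed)
  # constant profiles are fixed points; single probes unchanged
  const <- replication_profile("c1", seq(0, 9000, 1000), rep(42, 10), 40)
  expect_equal(smooth_profile(const)$values, rep(42, 10))
  single <- replication_profile("c1", 5000, 33, 40)
  expect_equal(smooth_profile(single)$values, 33)
})

test_that("smoothing stays inside the input range", {
  set.seed(3)
  for (i in 1:10) {
    v <- runif(100, 0, 100)
    p <- replication_profile("c1", seq(500, 100000, length.out = 100), v, 40)
    sm <- smooth_profile(p, window_bp = sample(c(5000, 18000, 40000), 1))
    expect_gte(min(sm$values), min(v) - 1e-9)
    expect_lte(max(sm$values), max(v) + 1e-9)
  }
})

test_that("Z-scores use the genome-wide population standard deviation", {
  p <- replication_profile("c1", c(1, 2, 3) * 1000, c(10, 20, 30), 40)
  z <- zscore_profile(list(c1 = p))
  expect_equal(z$mu, 20)
  expect_equal(z$sigma, sqrt(mean((c(10, 20, 30) - 20)^2)))
  expect_equal(z$profiles$c1$zvalues[3], 10 / 8.16496580927726,
               tolerance = 1e-9)
  expect_equal(z$profiles$c1$zvalues[2], 0)
  flat <- replication_profile("c1", c(1000, 2000), c(5, 5), 40)
  expect_error(zscore_profile(list(flat)), "degenerate")
})

test_that("Z-normalized profiles have mean 0 and sd 1 across probes", {
  set.seed(8)
  profs <- list(
    a = replication_profile("a", seq(1000, 50000, 1000), runif(50, 0, 90), 40),
    b = replication_profile("b", seq(1000, 30000, 1000), runif(30, 0, 90), 40))
  z <- zscore_profile(profs)
  zs <- unlist(lapply(z$profiles, `[[`, "zvalues"))
  expect_lt(abs(mean(zs)), 1e-9)
  expect_lt(abs(sqrt(mean(zs^2)) - 1), 1e-9)
})

test_that("sample matching compares genome-mean percent replication", {
  pa <- list(replication_profile("c1", c(1000, 2000), c(40, 40), 55))
  pb <- list(replication_profile("c1", c(1000, 2000), c(55, 55), 55))
  expect_false(check_sample_matching(pa, pb, tol = 10)$matched)
  pc <- list(replication_profile("c1", c(1000, 2000), c(45, 45), 55))
  expect_true(check_sample_matching(pa, pc, tol = 10)$matched)
  expect_true(check_sample_matching(pa, pa)$matched)
})

test_that("peak calling finds strict local maxima with prominence", {
  mono <- replication_profile("c1", seq(1000, 10000, 1000),
                              seq(10, 100, 10), 40, smoothed = TRUE)
  expect_equal(nrow(call_peaks(mono)), 0)
  flat <- replication_profile("c1", seq(1000, 10000, 1000),
                              rep(50, 10), 40, smoothed = TRUE)
  expect_equal(nrow(call_peaks(flat)), 0)
  v <- c(10, 30, 60, 30, 20, 45, 20, 10)
  p <- replication_profile("c1", seq(1000, 8000, 1000), v, 40,
                           smoothed = TRUE)
  pk <- call_peaks(p, min_prominence = 0)
  expect_equal(pk$position, c(3000, 6000))
  expect_equal(pk$prominence, c(60 - 10, 45 - 20))
  # prominence threshold filters the minor peak
  expect_equal(call_peaks(p, min_prominence = 30)$position, 3000)
  # chromosome-end probes are never peaks
  vend <- c(90, 50, 20, 10, 5)
  pend <- replication_profile("c1", seq(1000, 5000, 1000), vend, 40,
                              smoothed = TRUE)
  expect_equal(nrow(call_peaks(pend)), 0)
})

test_that("peaks on noise-free population profiles land on the true origins", {
  # closed-form population profile: origins at 30 kb and 90 kb firing at
  # N(10, 3) and N(16, 3) minutes, S entry N(20, 4), fork velocity 1500;
  # the locus replication CDF at time t gives the expected noise-free
  # percent replication (independent of the peak caller under test)
  spacing <- 2000
  pos <- seq(spacing / 2, 120000, spacing)
  v <- 1500
  cdf <- function(x, t) {
    a <- stats::pnorm(t, 10 + abs(x - 30000) / v + 20, sqrt(9 + 16))
    b <- stats::pnorm(t, 16 + abs(x - 90000) / v + 20, sqrt(9 + 16))
    1 - (1 - a) * (1 - b)
  }
  vals <- 100 * vapply(pos, cdf, numeric(1), t = 40)
  rp <- replication_profile("chrS", pos, vals, 40)
  pk <- call_peaks(smooth_profile(rp), min_prominence = 0.5)
  expect_equal(nrow(pk), 2)
  expect_lte(abs(pk$position[1] - 30000), spacing)
  expect_lte(abs(pk$position[2] - 90000), spacing)
  # grid argmax oracle: each called peak is the argmax of the raw values
  # in its neighbourhood
  for (i in 1:2) {
    near <- which(abs(pos - pk$position[i]) <= 12000)
    expect_equal(pos[near][which.max(vals[near])], pk$position[i])
  }
})

test_that("timing differences require persistence at every timepoint", {
  mk_z <- function(z, tt) {
    structure(list(profiles = list(c1 = list(chrom = "c1",
                                             positions = seq(1000, 10000, 1000),
                                             zvalues = z, time = tt)),
                   mu = 0, sigma = 1, time = tt), class = "zprofile_set")
  }
  base <- rep(0, 10)
  bump <- base; bump[4:7] <- 2
  za <- list(mk_z(bump, 60), mk_z(bump, 70), mk_z(bump, 80))
  zb <- list(mk_z(base, 60), mk_z(base, 70), mk_z(base, 80))
  d <- detect_timing_differences(za, zb, delta_z = 1.5, min_probes = 3)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 4000)
  expect_equal(d$end, 8000)
  expect_equal(d$max_abs_delta_z, 2)
  expect_equal(d$times_supporting, "60,70,80")
  # identical profiles: nothing
  expect_equal(nrow(detect_timing_differences(zb, zb)), 0)
  # difference at one of three timepoints only: nothing
  za1 <- list(mk_z(bump, 60), mk_z(base, 70), mk_z(base, 80))
  expect_equal(nrow(detect_timing_differences(za1, zb)), 0)
  # runs shorter than min_probes are discarded
  short <- base; short[5:6] <- 2
  za2 <- list(mk_z(short, 60), mk_z(short, 70), mk_z(short, 80))
  expect_equal(nrow(detect_timing_differences(za2, zb, min_probes = 3)), 0)
  expect_error(detect_timing_differences(za[1], zb[1]), "2 matched")
})

test_that("array simulator round-trips through the profile layer", {
  # deterministic scenario-free check: noiseless channels, no scaling
  ch <- det_chromosome(name = "chrS", length = 60000, positions = 30000,
                      firing = 10)
  p <- det_params(entry = 0, n_cells = 25)
  prof <- true_profile(ch, t = 18, grid_spacing = 1000, p)
  probes <- make_probes("chrS", prof$position + 1, 18, prof$fraction)
  got <- probe_percent_replication(probes, norm = "none")$t18$chrS$values
  expect_equal(got, 100 * prof$fraction, tolerance = 1e-9)
})
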