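test_that("reference regions keep the inclusive >= min_mean boundary", {
  peaks <- read_peaks_bed(write_lines_tmp("chr1\t3000\t4000", ".bed"))
  at3 <- make_track(chr1 = rep(3, 100))
  rr <- reference_regions(peaks, at3, half_width = 2000, min_mean = 3)
  expect_equal(rr$n_ref, 1L)                   # mean exactly 3.0 is kept
  expect_equal(rr$regions$center, 3500)
  expect_equal(rr$regions$start, 1500)
  expect_equal(rr$regions$end, 5500)
  below <- make_track(chr1 = rep(2.99, 100))
  expect_equal(reference_regions(peaks, below, 2000, 3)$n_ref, 0L)
})

test_that("peak centers use the floor midpoint and regions are never merged", {
  # two overlapping peaks stay two regions (counted separately)
  peaks <- read_peaks_bed(write_lines_tmp(c("chr1\t3000\t4001", "chr1\t3500\t4500"),
                                          ".bed"))
  tr <- make_track(chr1 = rep(5, 100))
  rr <- reference_regions(peaks, tr, 2000, 3)
  expect_equal(rr$regions$center, c(floor((3000 + 4001) / 2), 4000))
  expect_equal(rr$n_ref, 2L)
  # a merge-based variant would count 1: document the difference
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rr$regions$start + 1, rr$regions$end)))
  expect_equal(length(merged), 1L)

  empty <- read_peaks_bed(write_lines_tmp(character(), ".bed"))
  expect_warning(rr0 <- reference_regions(empty, tr), "empty peak set")
  expect_equal(rr0$n_ref, 0L)
})

test_that("reference region means are length-weighted over the raw K27 track", {
  peaks <- read_peaks_bed(write_lines_tmp("chr1\t900\t1100", ".bed"))
  v <- rep(0, 60); v[1:10] <- 8    # high signal on [0, 1000) only
  tr <- make_track(chr1 = v)
  rr <- reference_regions(peaks, tr, half_width = 500, min_mean = 3)
  # region [500, 1500): 500 bp at 8, 500 bp at 0
  expect_equal(rr$regions$mean_k27, 4)
  expect_equal(rr$n_ref, 1L)
})

test_that("threshold calibration matches hand-worked step functions", {
  b <- c(10, 8, 6.4, 2, 1)
  th <- calibrate_threshold(b, b, target = 3)
  expect_equal(th$theta, 6.4)
  expect_equal(th$achieved, 3L)

  # exact count 2 unattainable (counts jump 1 -> 3): tie rule prefers the
  # larger count, hence the smaller threshold
  b2 <- c(5, 5, 5, 1)
  th2 <- calibrate_threshold(b2, b2, target = 2)
  expect_equal(th2$theta, 5)
  expect_equal(th2$achieved, 3L)

  # full-set target: theta is the smallest limiting signal
  b3 <- c(4, 2, 9, 7)
  th3 <- calibrate_threshold(b3, b3, target = 4)
  expect_equal(th3$theta, 2)
  expect_equal(th3$achieved, 4L)

  th0 <- calibrate_threshold(b3, b3, target = 0)
  expect_equal(th0$achieved, 0L)
  expect_gt(th0$theta, max(b3))
  expect_equal(sum(b3 >= th0$theta), 0L)

  expect_error(calibrate_threshold(b3, b3, target = 5), "exceeds")
  expect_error(calibrate_threshold(c(a = 1, b = 2), c(b = 2, a = 1), 1),
               "same genes")
})

test_that("calibration equals the exhaustive sweep oracle, and counts are monotone", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(5:400, 1)
    b <- if (runif(1) < 0.5) round(runif(n, 0, 20), 1)   # force ties
         else runif(n, 0, 20)
    target <- sample(0:n, 1)
    got <- calibrate_threshold(b, b, target)
    if (target == 0) {
      expect_equal(got$achieved, 0L)
    } else {
      want <- oracle_calibrate(b, target)
      expect_equal(got$theta, want$theta)
      expect_equal(got$achieved, as.integer(want$achieved))
    }
    # count(theta) non-increasing in theta
    thetas <- sort(unique(b))
    counts <- vapply(thetas, function(t) sum(b >= t), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("bivalency is the inclusive conjunction of both marks", {
  theta <- 6.365
  k27 <- c(g1 = theta, g2 = theta + 1, g3 = 100, g4 = theta - 1e-9)
  k4 <- c(g1 = theta, g2 = theta - 1e-9, g3 = 100, g4 = 100)
  calls <- call_bivalent(k27, k4, theta, "E4.5_ICM")
  expect_equal(bivalent_genes(calls), c("g1", "g3"))   # both exactly theta: in
  expect_equal(calls$genes$b, pmin(unname(k27), unname(k4)))
  # conjunction is symmetric in the two marks
  swapped <- call_bivalent(k4, k27, theta, "E4.5_ICM")
  expect_equal(bivalent_genes(swapped), bivalent_genes(calls))
})

test_that("calls on separated zero-noise data recover the planted sets exactly", {
  cfg <- simulation_config(
    n_genes = 200, stages = "S1",
    class_fractions = c(bivalent = 0.25, k4_only = 0.25, k27_only = 0.25,
                        silent = 0.25),
    signal_sds = 0, background_max = 0, multi_tss_fraction = 0,
    genes_per_chrom = 100, seed = 3)
  ds <- generate_dataset(cfg)
  res <- analyze_bivalency(ds$annotation,
                           list(S1 = ds$tracks$S1$H3K27me3),
                           list(S1 = ds$tracks$S1$H3K4me3),
                           k4_peaks = ds$peaks, calibration_stage = "S1",
                           top_n = 40)
  planted <- planted_bivalent(ds, "S1")
  # reference regions = peaks at bivalent promoters only
  expect_equal(res$n_ref, length(planted))
  expect_setequal(bivalent_genes(res$calls$S1), planted)
  expect_equal(res$threshold$achieved, res$threshold$target)
})
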