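test_that("promoter means handle zero, constant and multi-TSS cases", {
  ann <- make_ann(c("g1", "g1", "g2"), "chr1", c(2000L, 6000L, 9000L))
  w <- promoter_window(1000, 1000)

  zero <- make_track(chr1 = numeric(120))
  expect_equal(unname(promoter_mean_signal(zero, ann, w)), c(0, 0))

  const <- make_track(chr1 = rep(4, 120))
  expect_equal(unname(promoter_mean_signal(const, ann, w)), c(4, 4))
  # window length does not matter for a constant track
  expect_equal(unname(promoter_mean_signal(const, ann, promoter_window(300, 200))),
               c(4, 4))

  # max-over-TSS: g1's two promoters read 2.0 and 5.0
  v <- numeric(120); v[11:30] <- 2; v[51:70] <- 5; v[81:100] <- 3
  tr <- make_track(chr1 = v)
  got <- promoter_mean_signal(tr, ann, w)
  expect_equal(unname(got), c(5, 3))
})

test_that("partial bin overlap is length-weighted", {
  # bins [1.0, 3.0]; window = last 50 bp of bin 1 plus all of bin 2
  tr <- make_track(chr1 = c(1, 3))
  ann <- make_ann("g1", "chr1", 150L)
  got <- promoter_mean_signal(tr, ann, promoter_window(100, 50))
  expect_equal(unname(got), (1 * 50 + 3 * 100) / 150, tolerance = 1e-12)
})

test_that("windows truncate at chromosome edges and renormalize", {
  tr <- make_track(chr1 = c(2, 4, 4, 4))
  # TSS at 50: window [-950, 1050) truncates to [0, 400); weights 100 each
  ann <- make_ann("g1", "chr1", 50L)
  got <- promoter_mean_signal(tr, ann, promoter_window(1000, 1000))
  expect_equal(unname(got), mean(c(2, 4, 4, 4)))
  # fully outside the covered extent is an error naming the gene
  far <- make_ann("gFar", "chr1", 5000L)
  expect_error(promoter_mean_signal(tr, far, promoter_window(100, 100)), "gFar")
})

test_that("asymmetric windows are strand-oriented; strand_aware=FALSE is naive", {
  v <- numeric(100); v[1:50] <- 1; v[51:100] <- 9    # low left, high right of 5000
  tr <- make_track(chr1 = v)
  plus <- make_ann("g1", "chr1", 5000L, "+")
  minus <- make_ann("g1", "chr1", 5000L, "-")
  w <- promoter_window(1000, 500, strand_aware = TRUE)
  # plus: [4000, 5500) = 1000 bp low + 500 bp high
  expect_equal(unname(promoter_mean_signal(tr, plus, w)),
               (1 * 1000 + 9 * 500) / 1500, tolerance = 1e-12)
  # minus mirrors: ~500 bp low + ~1000 bp high around the TSS base
  got_minus <- unname(promoter_mean_signal(tr, minus, w))
  expect_equal(got_minus,
               oracle_promoter_signal(tr, minus, w)[["g1"]], tolerance = 1e-12)
  expect_gt(got_minus, unname(promoter_mean_signal(tr, plus, w)))
  w0 <- promoter_window(1000, 500, strand_aware = FALSE)
  expect_equal(promoter_mean_signal(tr, minus, w0),
               promoter_mean_signal(tr, plus, w0))
})

test_that("promoter quantification is linear and monotone in added TSSs", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- make_track(chr1 = runif(80, 0, 10), chr2 = rexp(60))
    ann <- make_ann(sprintf("g%d", c(1, 1, 2, 3)), c("chr1", "chr1", "chr2", "chr2"),
                    as.integer(c(sample.int(7000, 2), sample.int(5000, 2))),
                    sample(c("+", "-"), 4, replace = TRUE))
    w <- promoter_window(800, 400)
    base <- promoter_mean_signal(tr, ann, w)
    c_ <- runif(1, 0.1, 10)
    expect_equal(unname(promoter_mean_signal(scale_track(tr, c_), ann, w)),
                 unname(base) * c_, tolerance = 1e-9)
    # dropping g1's second TSS can never increase its value
    ann1 <- make_ann(ann$gene_id[-2], ann$chrom[-2], ann$tss[-2], ann$strand[-2])
    expect_lte(promoter_mean_signal(tr, ann1, w)[["g1"]], base[["g1"]])
  }
})

test_that("promoter means match the per-basepair oracle on random tracks", {
  set.seed(17)
  for (rep in 1:25) {
    tr <- make_track(chr1 = runif(sample(20:60, 1), 0, 20),
                     bin_size = sample(c(50, 100, 250), 1))
    n_tss <- sample(2:5, 1)
    chrom_len <- length(tr$values$chr1) * tr$bin_size
    ann <- make_ann(sprintf("g%d", sample(1:3, n_tss, replace = TRUE)),
                    "chr1",
                    as.integer(sample(seq(500, chrom_len - 500), n_tss)),
                    sample(c("+", "-"), n_tss, replace = TRUE))
    w <- promoter_window(sample(c(0, 300, 1000), 1), sample(c(150, 500), 1),
                         strand_aware = sample(c(TRUE, FALSE), 1))
    expect_equal(promoter_mean_signal(tr, ann, w),
                 oracle_promoter_signal(tr, ann, w), tolerance = 1e-9)
  }
})

test_that("build_matrix assembles stage columns in order and validates inputs", {
  ann <- make_ann(c("g1", "g2", "g3"), "chr1", c(1000L, 3000L, 5000L))
  t1 <- make_track(chr1 = rep(1, 60), stage = "A")
  t2 <- make_track(chr1 = rep(2, 60), stage = "B")
  m <- build_matrix(list(B = t2, A = t1), ann, promoter_window(500, 500))
  expect_equal(dim(m$values), c(3L, 2L))
  expect_equal(colnames(m$values), c("B", "A"))
  expect_equal(unname(m$values[, "B"]), rep(2, 3))
  expect_false(m$normalized)
  expect_error(build_matrix(list(A = t1, A = t2), ann, promoter_window(500, 500)),
               "duplicate")
  t3 <- make_track(chr1 = rep(1, 60), mark = "H3K4me3")
  expect_error(build_matrix(list(A = t1, B = t3), ann, promoter_window(500, 500)),
               "same mark")
})

test_that("zero-noise synthetic promoter matrix equals planted class means times depth", {
  cfg <- simulation_config(
    n_genes = 40, stages = c("S1", "S2"),
    class_fractions = c(bivalent = 0.5, k4_only = 0.25, k27_only = 0.25, silent = 0),
    signal_sds = 0, background_max = 0, multi_tss_fraction = 0,
    depth = list(H3K4me3 = c(S1 = 1, S2 = 3), H3K27me3 = c(S1 = 2, S2 = 0.5)),
    genes_per_chrom = 20, seed = 9)
  ds <- generate_dataset(cfg)
  m <- build_matrix(lapply(ds$tracks, `[[`, "H3K27me3"), ds$annotation,
                    promoter_window(1000, 1000))
  expected <- exp(cfg$signal_means[ds$truth$S2, "H3K27me3"]) * 0.5
  expect_equal(unname(m$values[, "S2"]), unname(expected), tolerance = 1e-12)
  expected1 <- exp(cfg$signal_means[ds$truth$S1, "H3K27me3"]) * 2
  expect_equal(unname(m$values[, "S1"]), unname(expected1), tolerance = 1e-12)
})
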