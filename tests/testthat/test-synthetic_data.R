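test_that("degenerate config paints exact class-mean plateaus on both marks", {
  cfg <- simulation_config(
    n_genes = 12, stages = "S1",
    class_fractions = c(bivalent = 1, k4_only = 0, k27_only = 0, silent = 0),
    signal_sds = 0, background_max = 0, multi_tss_fraction = 0,
    genes_per_chrom = 6, seed = 1)
  ds <- generate_dataset(cfg)
  w <- promoter_window(1000, 1000)
  k27 <- promoter_mean_signal(ds$tracks$S1$H3K27me3, ds$annotation, w)
  k4 <- promoter_mean_signal(ds$tracks$S1$H3K4me3, ds$annotation, w)
  expect_equal(unname(k27), rep(exp(cfg$signal_means["bivalent", "H3K27me3"]), 12))
  expect_equal(unname(k4), rep(exp(cfg$signal_means["bivalent", "H3K4me3"]), 12))
})

test_that("generation is byte-for-byte reproducible from the seed", {
  cfg <- simulation_config(n_genes = 60, stages = c("S1", "S2"),
                           genes_per_chrom = 30, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the data
  cfg2 <- simulation_config(n_genes = 60, stages = c("S1", "S2"),
                            genes_per_chrom = 30, seed = 100)
  d3 <- tempfile()
  write_dataset(generate_dataset(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "S1_H3K4me3.bedGraph"))),
                         unname(tools::md5sum(file.path(d3, "S1_H3K4me3.bedGraph")))))
})

test_that("depth multipliers rescale raw tracks exactly without touching draws", {
  base <- simulation_config(n_genes = 50, stages = c("S1", "S2"),
                            genes_per_chrom = 25, seed = 12)
  tenx <- simulation_config(n_genes = 50, stages = c("S1", "S2"),
                            genes_per_chrom = 25, seed = 12,
                            depth = c(S1 = 10, S2 = 1))
  ds_base <- generate_dataset(base)
  ds_tenx <- generate_dataset(tenx)
  for (chrom in names(ds_base$tracks$S1$H3K27me3$values)) {
    expect_equal(ds_tenx$tracks$S1$H3K27me3$values[[chrom]],
                 10 * ds_base$tracks$S1$H3K27me3$values[[chrom]])
    expect_equal(ds_tenx$tracks$S1$H3K4me3$values[[chrom]],
                 10 * ds_base$tracks$S1$H3K4me3$values[[chrom]])
    expect_equal(ds_tenx$tracks$S2$H3K4me3$values[[chrom]],
                 ds_base$tracks$S2$H3K4me3$values[[chrom]])
  }
  expect_identical(ds_tenx$truth, ds_base$truth)
  expect_identical(ds_tenx$peaks, ds_base$peaks)   # peak truth is depth-free
})

test_that("empirical class fractions match the configuration (binomial 99% CI)", {
  fr <- c(bivalent = 0.2, k4_only = 0.3, k27_only = 0.1, silent = 0.4)
  cfg <- simulation_config(n_genes = 5000, stages = c("S1", "S2"),
                           class_fractions = fr, seed = 2024)
  ds <- generate_dataset(cfg)
  for (s in cfg$stages) {
    emp <- table(factor(ds$truth[[s]], levels = names(fr))) / 5000
    hw <- qnorm(0.995) * sqrt(fr * (1 - fr) / 5000)
    expect_true(all(abs(emp - fr) <= hw),
                info = paste("stage", s))
  }
})

test_that("empirical class log-means track the configured means", {
  cfg <- simulation_config(n_genes = 4000, stages = "S1",
                           class_fractions = c(bivalent = 1, k4_only = 0,
                                               k27_only = 0, silent = 0),
                           background_max = 0, multi_tss_fraction = 0,
                           seed = 8)
  ds <- generate_dataset(cfg)
  vals <- promoter_mean_signal(ds$tracks$S1$H3K4me3, ds$annotation,
                               promoter_window(1000, 1000))
  mu <- cfg$signal_means["bivalent", "H3K4me3"]
  sd <- cfg$signal_sds["bivalent", "H3K4me3"]
  expect_lt(abs(mean(log(vals)) - mu), 3 * sd / sqrt(4000))
})

test_that("written datasets satisfy the format readers' invariants", {
  sc <- scenario_small()
  dir <- tempfile()
  paths <- write_dataset(sc$ds, dir)
  ann <- read_tss_annotation(paths$annotation)
  expect_s3_class(ann, "tss_annotation")
  # multi-TSS genes carry two records
  n_multi <- round(sc$cfg$multi_tss_fraction * sc$cfg$n_genes)
  expect_equal(nrow(ann), sc$cfg$n_genes + n_multi)
  tr <- read_bedgraph(paths$stages$k27_track[3], sc$cfg$bin_size)
  mem <- sc$ds$tracks$S3$H3K27me3
  for (chrom in names(mem$values)) {
    # written track may drop trailing zero bins; values agree where covered
    n <- length(tr$values[[chrom]])
    expect_equal(tr$values[[chrom]], mem$values[[chrom]][seq_len(n)],
                 tolerance = 1e-12)
    expect_true(all(mem$values[[chrom]][-seq_len(n)] == 0))
  }
  pk <- read_peaks_bed(paths$stages$k4_peaks[3])
  expect_true(all(pk$start < pk$end))
  expect_true(all(pk$end - pk$start == sc$cfg$peak_width))
  expr <- read_expression_table(paths$expression)
  expect_equal(dim(expr), c(sc$cfg$n_genes, 4L))
})

test_that("the two-wave scenario plants exact counts and pure K4-gain transitions", {
  sc <- scenario_small()
  ds <- sc$ds; n <- sc$cfg$n_genes
  tr <- sc$cfg$trajectories
  for (s in sc$cfg$stages) {
    planted_frac <- sum(tr$fraction[tr[[s]] == "bivalent"])
    expect_equal(length(planted_bivalent(ds, s)), round(planted_frac * n))
  }
  # every gene newly bivalent at S4 was k27_only at S3 (gained K4 on
  # pre-existing K27); every gene newly bivalent at S3 gained both marks
  new_s4 <- setdiff(planted_bivalent(ds, "S4"), planted_bivalent(ds, "S3"))
  prior <- ds$truth$S3[match(new_s4, ds$truth$gene_id)]
  expect_true(all(prior == "k27_only"))
  new_s3 <- setdiff(planted_bivalent(ds, "S3"), planted_bivalent(ds, "S2"))
  expect_true(all(ds$truth$S2[match(new_s3, ds$truth$gene_id)] == "silent"))
})

test_that("impossible configurations are rejected", {
  expect_error(simulation_config(class_fractions = c(bivalent = 0.5, k4_only = 0.2,
                                                     k27_only = 0.2, silent = 0.2)),
               "impossible")
  expect_error(simulation_config(depth = c(S1 = 0, S2 = 1)), "depth")
  expect_error(simulation_config(signal_sds = -1))
})
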