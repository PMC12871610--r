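# Shared fixtures and independent oracles. Expensive fixtures are built once
# per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# track from a plain list of per-chromosome bin values
make_track <- function(..., bin_size = 100, mark = "H3K27me3", stage = "S1") {
  binned_track(list(...), bin_size = bin_size, mark = mark, stage = stage)
}

# annotation from parallel vectors
make_ann <- function(gene_id, chrom, tss, strand = "+") {
  df <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                   strand = rep_len(strand, length(gene_id)),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand",
               sprintf("%s\t%s\t%d\t%s", df$gene_id, df$chrom,
                       as.integer(df$tss), df$strand)), f)
  on.exit(unlink(f))
  read_tss_annotation(f)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# independent per-basepair oracle for window means / promoter signal
oracle_window_mean <- function(v, bin_size, ws, we) {
  chrom_len <- length(v) * bin_size
  lo <- max(ws, 0); hi <- min(we, chrom_len)
  if (hi <= lo) return(NA_real_)
  bp <- seq.int(lo, hi - 1)
  mean(v[floor(bp / bin_size) + 1])
}

oracle_promoter_signal <- function(track, ann, window) {
  per_tss <- vapply(seq_len(nrow(ann)), function(i) {
    minus <- window$strand_aware && ann$strand[i] == "-"
    t <- ann$tss[i]
    ws <- if (minus) t + 1 - window$downstream else t - window$upstream
    we <- if (minus) t + 1 + window$upstream else t + window$downstream
    v <- track$values[[ann$chrom[i]]]
    if (is.null(v)) return(0)
    oracle_window_mean(v, track$bin_size, ws, we)
  }, 0)
  genes <- unique(ann$gene_id)
  vapply(genes, function(g) max(per_tss[ann$gene_id == g]), 0)
}

# exhaustive sweep over all candidate thresholds (distinct b values),
# tracking the best |count - target| with ties to the larger count
oracle_calibrate <- function(b, target) {
  if (target == 0) return(list(theta = NA_real_, achieved = 0L))
  best <- list(theta = NA_real_, achieved = NA_integer_, gap = Inf)
  for (th in unique(b)) {
    cnt <- sum(b >= th)
    gap <- abs(cnt - target)
    if (gap < best$gap || (gap == best$gap && cnt > best$achieved))
      best <- list(theta = th, achieved = cnt, gap = gap)
  }
  best
}

scenario_small <- function() get_fixture("scenario_small", function() {
  cfg <- scenario_two_waves(n_genes = 1000, seed = 42, genes_per_chrom = 250)
  ds <- generate_dataset(cfg)
  list(cfg = cfg, ds = ds,
       k27 = lapply(ds$tracks, `[[`, "H3K27me3"),
       k4 = lapply(ds$tracks, `[[`, "H3K4me3"))
})

# larger on-disk scenario exercising the file-based pipeline end to end
scenario_big <- function() get_fixture("scenario_big", function() {
  cfg <- scenario_two_waves(n_genes = 5000, seed = 11)
  ds <- generate_dataset(cfg)
  dir <- file.path(tempdir(), "bivalink_scenario_big")
  paths <- write_dataset(ds, dir)
  list(cfg = cfg, ds = ds, dir = dir, paths = paths)
})

# planted transition partition from the truth table
truth_partition <- function(ds, stage_A, stage_B) {
  A <- planted_bivalent(ds, stage_A)
  B <- planted_bivalent(ds, stage_B)
  list(A_specific = sort(setdiff(A, B)), shared = sort(intersect(A, B)),
       B_specific = sort(setdiff(B, A)))
}
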