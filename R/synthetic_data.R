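PROMOTER_CLASSES <- c("bivalent", "k4_only", "k27_only", "silent")
MARKS <- c("H3K4me3", "H3K27me3")

default_signal_means <- function() {
  m <- rbind(bivalent = c(log(30), log(20)),
             k4_only  = c(log(40), log(0.15)),
             k27_only = c(log(0.15), log(20)),
             silent   = c(log(0.1), log(0.1)))
  colnames(m) <- MARKS
  m
}

#' Simulation configuration
#'
#' Describes a multi-stage synthetic dataset with planted bivalency truth.
#' Each gene belongs, at each stage, to one of four promoter classes —
#' `bivalent`, `k4_only`, `k27_only`, `silent` — and each class draws its
#' promoter-level FPKM per mark from a log-normal (parameters are mean and
#' sd of log-FPKM). The drawn value is painted as a plateau of
#' `promoter_span` bp centered on the TSS over a low uniform background,
#' and the whole track is multiplied by the stage's depth multiplier, so
#' cross-stage depth differences are planted explicitly for the
#' normalization step to remove.
#'
#' Class labels come either from `class_fractions` (independent draw per
#' gene per stage) or, when `trajectories` is supplied, from a trajectory
#' table: a `data.frame` with a `fraction` column and one class-label
#' column per stage. Trajectory counts are made exact by largest-remainder
#' apportionment, so planted per-stage class sizes are exact by
#' construction; genes are assigned to trajectories in a seeded random
#' permutation.
#'
#' H3K4me3 peaks are emitted per TSS whose pre-depth K4 draw reaches
#' `peak_floor` (peak truth should not depend on the depth nuisance).
#' A `multi_tss_fraction` of genes carries a secondary TSS offset by
#' `multi_tss_offset` bp whose signal is an independent draw scaled by
#' `secondary_tss_factor` (< 1: secondary promoters are weaker).
#' Expression FPKM is drawn log-normally per class
#' (`expression_meanlog`); bivalent and silent genes are low-expressed.
#'
#' @param n_genes Number of genes.
#' @param stages Character vector of stage names (order = developmental order).
#' @param class_fractions Named numeric vector over the four classes summing
#'   to 1 (recycled to all stages), or a list with one such vector per stage.
#'   Ignored when `trajectories` is given.
#' @param trajectories Optional trajectory table (see Details).
#' @param signal_means 4 x 2 matrix (class x mark) of mean log-FPKM.
#' @param signal_sds Scalar or matrix like `signal_means`; sd of log-FPKM.
#' @param depth Per-stage depth multipliers: scalar, named vector (per
#'   stage), or list of per-mark vectors `c(H3K4me3 =, H3K27me3 =)`.
#' @param multi_tss_fraction Fraction of genes with a secondary TSS.
#' @param multi_tss_offset Offset of the secondary TSS in bp.
#' @param secondary_tss_factor Multiplier on the secondary TSS's draw.
#' @param bin_size Track bin size in bp.
#' @param promoter_span Width of the painted promoter plateau in bp.
#' @param gene_spacing Distance between consecutive TSSs in bp.
#' @param genes_per_chrom Genes per simulated chromosome.
#' @param chrom_margin Bp of background before the first / after the last TSS.
#' @param background_max Background values are Uniform(0, background_max).
#' @param background_block Background is piecewise constant over this many
#'   consecutive bins (keeps files compact without being flat).
#' @param peak_floor Minimum pre-depth K4 promoter FPKM to emit a peak.
#' @param peak_width Emitted peak width in bp, centered on the TSS.
#' @param expression_meanlog Named per-class mean log-FPKM of expression.
#' @param expression_sdlog Sd of log expression.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000,
                              stages = c("S1", "S2"),
                              class_fractions = c(bivalent = 0.15, k4_only = 0.25,
                                                  k27_only = 0.15, silent = 0.45),
                              trajectories = NULL,
                              signal_means = default_signal_means(),
                              signal_sds = 0.25,
                              depth = 1,
                              multi_tss_fraction = 0.2,
                              multi_tss_offset = 3000,
                              secondary_tss_factor = 0.1,
                              bin_size = 100,
                              promoter_span = 2400,
                              gene_spacing = 8000,
                              genes_per_chrom = 500,
                              chrom_margin = 5000,
                              background_max = 0.2,
                              background_block = 10,
                              peak_floor = 8,
                              peak_width = 1000,
                              expression_meanlog = c(bivalent = log(0.8),
                                                     k4_only = log(30),
                                                     k27_only = log(0.3),
                                                     silent = log(0.3)),
                              expression_sdlog = 0.5,
                              seed = 1) {
  stopifnot(n_genes >= 1, length(stages) >= 1, !anyDuplicated(stages),
            bin_size > 0, promoter_span > 0, gene_spacing > 0,
            genes_per_chrom >= 1, background_max >= 0, background_block >= 1,
            peak_width > 0, multi_tss_fraction >= 0, multi_tss_fraction <= 1,
            expression_sdlog >= 0)

  if (is.null(trajectories)) {
    if (!is.list(class_fractions))
      class_fractions <- rep(list(class_fractions), length(stages))
    if (length(class_fractions) != length(stages))
      stop("class_fractions must have one entry per stage")
    names(class_fractions) <- stages
    for (s in stages) {
      fr <- class_fractions[[s]]
      if (!all(PROMOTER_CLASSES %in% names(fr)))
        stop("class_fractions must be named over: ",
             paste(PROMOTER_CLASSES, collapse = ", "))
      if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
        stop("impossible class fractions at stage ", s,
             ": must be non-negative and sum to 1")
      class_fractions[[s]] <- fr[PROMOTER_CLASSES]
    }
  } else {
    stopifnot(is.data.frame(trajectories), "fraction" %in% colnames(trajectories),
              all(stages %in% colnames(trajectories)))
    if (any(trajectories$fraction < 0) ||
        abs(sum(trajectories$fraction) - 1) > 1e-9)
      stop("impossible trajectory fractions: must be non-negative and sum to 1")
    for (s in stages)
      if (!all(trajectories[[s]] %in% PROMOTER_CLASSES))
        stop("unknown promoter class in trajectory table, stage ", s)
    class_fractions <- NULL
  }

  if (!is.matrix(signal_sds))
    signal_sds <- matrix(signal_sds, nrow = nrow(signal_means),
                         ncol = ncol(signal_means),
                         dimnames = dimnames(signal_means))
  stopifnot(all(signal_sds >= 0),
            identical(rownames(signal_means), PROMOTER_CLASSES),
            identical(colnames(signal_means), MARKS))

  if (!is.list(depth)) {
    d <- if (length(depth) == 1L) stats::setNames(rep(depth, length(stages)), stages)
         else depth[stages]
    depth <- list(H3K4me3 = d, H3K27me3 = d)
  }
  for (mark in MARKS) {
    if (length(depth[[mark]]) == 1L)
      depth[[mark]] <- stats::setNames(rep(depth[[mark]], length(stages)), stages)
    if (any(is.na(depth[[mark]][stages])) || any(depth[[mark]][stages] <= 0))
      stop("depth multipliers must be > 0 for every stage and mark")
  }
  stopifnot(all(PROMOTER_CLASSES %in% names(expression_meanlog)))

  structure(list(n_genes = as.integer(n_genes), stages = stages,
                 class_fractions = class_fractions, trajectories = trajectories,
                 signal_means = signal_means, signal_sds = signal_sds,
                 depth = depth, multi_tss_fraction = multi_tss_fraction,
                 multi_tss_offset = multi_tss_offset,
                 secondary_tss_factor = secondary_tss_factor,
                 bin_size = bin_size, promoter_span = promoter_span,
                 gene_spacing = gene_spacing, genes_per_chrom = genes_per_chrom,
                 chrom_margin = chrom_margin, background_max = background_max,
                 background_block = background_block, peak_floor = peak_floor,
                 peak_width = peak_width,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog, seed = as.integer(seed)),
            class = "simulation_config")
}

# largest-remainder apportionment of n among fractions (exact, deterministic)
apportion <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic multi-stage dataset with planted truth
#'
#' Draws class labels, promoter signal, tracks, H3K4me3 peaks and
#' expression per the configuration (see [simulation_config]); fully
#' reproducible from `config$seed`. The random stream order is fixed:
#' class labels, strands, multi-TSS subset, then per stage (in order) per
#' mark (H3K4me3 first) the primary and secondary promoter draws, then
#' per-stage/mark backgrounds, then expression. Depth multipliers are
#' applied after all draws, so changing only `depth` rescales tracks
#' exactly without perturbing anything else.
#'
#' @param config A [simulation_config].
#' @return An object of class `bivalink_dataset`: list with `annotation`
#'   (`tss_annotation`), `tracks` (stage -> mark -> [binned_track]),
#'   `peaks` (stage -> `peak_set` of H3K4me3 peaks), `expression`
#'   (data.frame, rownames = gene ids, one column per stage), `truth`
#'   (data.frame: gene_id, planted class per stage, trajectory if used)
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  stages <- config$stages
  gene_id <- sprintf("g%05d", seq_len(n))

  # 1. planted class labels
  classes <- matrix(NA_character_, n, length(stages),
                    dimnames = list(gene_id, stages))
  trajectory <- NULL
  if (!is.null(config$trajectories)) {
    tr <- config$trajectories
    counts <- apportion(tr$fraction, n)
    traj_idx <- sample(rep.int(seq_len(nrow(tr)), counts))
    trajectory <- if (!is.null(tr$trajectory)) tr$trajectory[traj_idx]
                  else as.character(traj_idx)
    for (s in stages) classes[, s] <- tr[[s]][traj_idx]
  } else {
    for (s in stages)
      classes[, s] <- sample(PROMOTER_CLASSES, n, replace = TRUE,
                             prob = config$class_fractions[[s]])
  }

  # 2-3. placement, strand, multi-TSS subset
  chrom <- paste0("chr", (seq_len(n) - 1) %/% config$genes_per_chrom + 1)
  tss <- config$chrom_margin +
    ((seq_len(n) - 1) %% config$genes_per_chrom) * config$gene_spacing
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_multi <- round(config$multi_tss_fraction * n)
  multi <- sort(sample.int(n, n_multi))
  is_multi <- seq_len(n) %in% multi

  ann <- data.frame(
    gene_id = c(gene_id, gene_id[is_multi]),
    chrom = c(chrom, chrom[is_multi]),
    tss = c(tss, tss[is_multi] + config$multi_tss_offset),
    strand = c(strand, strand[is_multi]), stringsAsFactors = FALSE)
  ord <- order(ann$gene_id, ann$tss, method = "radix")
  annotation <- tss_annotation(ann[ord, , drop = FALSE])
  rownames(annotation) <- NULL

  # 4. promoter-level draws (pre-depth), per stage then mark
  draws <- list()       # draws[[stage]][[mark]] = list(primary, secondary)
  for (s in stages) {
    draws[[s]] <- list()
    for (mark in MARKS) {
      mu <- config$signal_means[classes[, s], mark]
      sd <- config$signal_sds[classes[, s], mark]
      primary <- stats::rlnorm(n, mu, sd)
      secondary <- config$secondary_tss_factor *
        stats::rlnorm(n, mu, sd)   # drawn for all genes; used for multi-TSS
      draws[[s]][[mark]] <- list(primary = primary, secondary = secondary)
    }
  }

  # chromosome layouts
  chrom_names <- unique(chrom)
  n_on <- table(factor(chrom, levels = chrom_names))
  chrom_len <- 2 * config$chrom_margin +
    (as.integer(n_on) - 1) * config$gene_spacing
  n_bins <- stats::setNames(ceiling(chrom_len / config$bin_size), chrom_names)

  paint <- function(values, pos, level) {
    bs <- config$bin_size
    half <- config$promoter_span / 2
    for (k in seq_along(pos)) {
      b0 <- max(floor((pos[k] - half) / bs), 0)
      b1 <- min(ceiling((pos[k] + half) / bs) - 1, length(values) - 1)
      if (b1 >= b0) values[(b0:b1) + 1] <- level[k]
    }
    values
  }

  # 5. tracks: background + plateaus, then depth
  tracks <- list()
  for (s in stages) {
    tracks[[s]] <- list()
    for (mark in MARKS) {
      vals <- list()
      for (cn in chrom_names) {
        nb <- n_bins[[cn]]
        nblock <- ceiling(nb / config$background_block)
        bg <- rep(stats::runif(nblock, 0, config$background_max),
                  each = config$background_block)[seq_len(nb)]
        i <- which(chrom == cn)
        v <- paint(bg, tss[i], draws[[s]][[mark]]$primary[i])
        im <- i[is_multi[i]]
        if (length(im))
          v <- paint(v, tss[im] + config$multi_tss_offset,
                     draws[[s]][[mark]]$secondary[match(im, seq_len(n))])
        vals[[cn]] <- v * config$depth[[mark]][[s]]
      }
      tracks[[s]][[mark]] <- binned_track(vals, config$bin_size, mark, s)
    }
  }

  # 6. H3K4me3 peaks: per TSS whose pre-depth K4 draw reaches the floor
  peaks <- list()
  for (s in stages) {
    k4p <- draws[[s]]$H3K4me3$primary
    k4s <- draws[[s]]$H3K4me3$secondary
    pos <- c(tss[k4p >= config$peak_floor],
             tss[is_multi & k4s >= config$peak_floor] + config$multi_tss_offset)
    ids <- c(gene_id[k4p >= config$peak_floor],
             gene_id[is_multi & k4s >= config$peak_floor])
    chr <- c(chrom[k4p >= config$peak_floor],
             chrom[is_multi & k4s >= config$peak_floor])
    o <- order(chr, pos, ids, method = "radix")
    peaks[[s]] <- peak_set(data.frame(
      chrom = chr[o], start = pos[o] - config$peak_width / 2,
      end = pos[o] + config$peak_width / 2, name = ids[o],
      stringsAsFactors = FALSE))
  }

  # 7. expression
  expression <- as.data.frame(lapply(stages, function(s) {
    stats::rlnorm(n, config$expression_meanlog[classes[, s]],
                  config$expression_sdlog)
  }), col.names = stages)
  rownames(expression) <- gene_id

  truth <- data.frame(gene_id = gene_id, classes, stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (!is.null(trajectory)) truth$trajectory <- trajectory
  rownames(truth) <- NULL

  structure(list(annotation = annotation, tracks = tracks, peaks = peaks,
                 expression = expression, truth = truth, config = config),
            class = "bivalink_dataset")
}

#' Planted bivalent genes of a dataset at one stage
#'
#' @param dataset A `bivalink_dataset`.
#' @param stage Stage name.
#' @return Character vector of gene ids planted as `bivalent`.
#' @export
planted_bivalent <- function(dataset, stage) {
  dataset$truth$gene_id[dataset$truth[[stage]] == "bivalent"]
}

#' Write a synthetic dataset to disk
#'
#' Writes `annotation.tsv`, one bedGraph per stage and mark
#' (`<stage>_<mark>.bedGraph`), one BED of H3K4me3 peaks per stage
#' (`<stage>_H3K4me3_peaks.bed`), `expression.tsv` and a `truth.tsv`
#' sidecar, in the same dialects the readers in this package consume.
#' Output is deterministic: the same dataset writes byte-identical files.
#'
#' @param dataset A `bivalink_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `annotation`, `expression`, `truth` paths
#'   and a `stages` data.frame (name, k27_track, k4_track, k4_peaks) ready
#'   to drop into a pipeline run configuration.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "bivalink_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  write_tss_annotation(dataset$annotation, p("annotation.tsv"))
  stage_rows <- lapply(dataset$config$stages, function(s) {
    for (mark in MARKS)
      write_bedgraph(dataset$tracks[[s]][[mark]], p(s, "_", mark, ".bedGraph"))
    write_peaks_bed(dataset$peaks[[s]], p(s, "_H3K4me3_peaks.bed"))
    data.frame(name = s, k27_track = p(s, "_H3K27me3.bedGraph"),
               k4_track = p(s, "_H3K4me3.bedGraph"),
               k4_peaks = p(s, "_H3K4me3_peaks.bed"), stringsAsFactors = FALSE)
  })
  expr <- dataset$expression
  num <- function(x) formatC(x, format = "g", digits = 10)
  writeLines(c(paste(c("gene_id", colnames(expr)), collapse = "\t"),
               do.call(function(...) paste(..., sep = "\t"),
                       c(list(rownames(expr)), lapply(expr, num)))),
             p("expression.tsv"))
  tr <- dataset$truth
  writeLines(c(paste(colnames(tr), collapse = "\t"),
               do.call(function(...) paste(..., sep = "\t"), tr)),
             p("truth.tsv"))
  invisible(list(annotation = p("annotation.tsv"),
                 expression = p("expression.tsv"), truth = p("truth.tsv"),
                 stages = do.call(rbind, stage_rows)))
}

#' Two-wave bivalency scenario
#'
#' A four-stage configuration encoding the two waves of bivalency gain seen
#' across early development: in wave 1 (stage S2 to S3) a block of genes
#' gains both marks at once; in wave 2 (S3 to S4) genes that carried
#' H3K27me3 all along gain H3K4me3, so every gene newly bivalent at S4 is a
#' "K4-gain" type. The trajectory table also plants constitutively bivalent
#' (shared), early-only bivalent (lost after S2), constitutively active,
#' K27-only and silent genes, and per-stage depth multipliers differ so the
#' normalization step is exercised. Planted per-stage class counts are
#' exact by construction.
#'
#' @param n_genes Number of genes (default 5000).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulation_config].
#' @return A [simulation_config] with stages `S1`-`S4` and a planted
#'   trajectory table.
#' @export
scenario_two_waves <- function(n_genes = 5000, seed = 1, ...) {
  tr <- data.frame(
    trajectory = c("silent", "active", "shared_bivalent", "both_gain",
                   "k4_gain", "k27_only", "early_bivalent"),
    fraction = c(0.25, 0.20, 0.10, 0.15, 0.15, 0.10, 0.05),
    S1 = c("silent", "k4_only", "bivalent", "silent", "k27_only", "k27_only", "bivalent"),
    S2 = c("silent", "k4_only", "bivalent", "silent", "k27_only", "k27_only", "bivalent"),
    S3 = c("silent", "k4_only", "bivalent", "bivalent", "k27_only", "k27_only", "k27_only"),
    S4 = c("silent", "k4_only", "bivalent", "bivalent", "bivalent", "k27_only", "k27_only"),
    stringsAsFactors = FALSE)
  simulation_config(
    n_genes = n_genes, stages = c("S1", "S2", "S3", "S4"), trajectories = tr,
    depth = list(H3K4me3 = c(S1 = 1, S2 = 2, S3 = 1, S4 = 0.5),
                 H3K27me3 = c(S1 = 1.2, S2 = 0.6, S3 = 1, S4 = 2)),
    seed = seed, ...)
}
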