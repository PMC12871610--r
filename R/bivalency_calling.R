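#' Peak-derived reference bivalent regions
#'
#' Places a window of `±half_width` bp around the center of every H3K4me3
#' peak (`center = floor((start + end) / 2)`, 0-based) and computes the
#' length-weighted mean of the *raw* (un-normalized) H3K27me3 track over it.
#' Regions with mean `>= min_mean` (inclusive) count as strong H3K27me3
#' domains overlapping an H3K4me3 peak; their number `n_ref` is the target
#' the bivalency threshold is calibrated against. Regions are counted one
#' per peak — overlapping peaks are neither merged nor deduplicated.
#'
#' @param k4_peaks A `peak_set` of H3K4me3 peaks.
#' @param k27_track Raw H3K27me3 [binned_track] for the same stage.
#' @param half_width Half-width of the region around each peak center (bp).
#' @param min_mean Minimum mean raw FPKM to keep a region (inclusive).
#' @return An object of class `reference_regions`: list with `regions`
#'   (data.frame chrom/start/end/center/mean_k27/kept), `half_width`,
#'   `min_mean` and `n_ref` (number of kept regions).
#' @export
reference_regions <- function(k4_peaks, k27_track, half_width = 2000, min_mean = 3.0) {
  stopifnot(inherits(k4_peaks, "peak_set"), inherits(k27_track, "binned_track"),
            half_width > 0)
  if (nrow(k4_peaks) == 0L) {
    warning("empty peak set: 0 reference regions; threshold calibration ",
            "against this count will select no genes")
    regions <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                          center = numeric(), mean_k27 = numeric(), kept = logical())
    return(structure(list(regions = regions, half_width = half_width,
                          min_mean = min_mean, n_ref = 0L),
                     class = "reference_regions"))
  }
  center <- floor((k4_peaks$start + k4_peaks$end) / 2)
  start <- center - half_width
  end <- center + half_width
  mean_k27 <- numeric(nrow(k4_peaks))
  for (chrom in unique(k4_peaks$chrom)) {
    i <- which(k4_peaks$chrom == chrom)
    v <- k27_track$values[[chrom]]
    if (is.null(v)) { mean_k27[i] <- 0; next }
    m <- window_means(v, k27_track$bin_size, start[i], end[i])
    mean_k27[i] <- ifelse(is.na(m), 0, m)   # region fully outside coverage
  }
  kept <- mean_k27 >= min_mean
  regions <- data.frame(chrom = k4_peaks$chrom, start = start, end = end,
                        center = center, mean_k27 = mean_k27, kept = kept,
                        stringsAsFactors = FALSE)
  structure(list(regions = regions, half_width = half_width,
                 min_mean = min_mean, n_ref = sum(kept)),
            class = "reference_regions")
}

#' @export
print.reference_regions <- function(x, ...) {
  cat(sprintf("<reference_regions> %d peaks, %d kept (mean raw K27 >= %g over +/-%g bp)\n",
              nrow(x$regions), x$n_ref, x$min_mean, x$half_width))
  invisible(x)
}

#' Calibrate the unified bivalency threshold against a target count
#'
#' For every gene let `b_g = min(normK27_g, normK4_g)` — the limiting
#' signal. The number of genes with both marks above a cutoff `theta`,
#' `count(theta) = |{g : b_g >= theta}|`, is a non-increasing step function
#' whose attainable values occur exactly at the distinct `b_g`. The
#' calibrated threshold is the `target`-th largest `b_g` when a count of
#' exactly `target` is attainable; otherwise the candidate minimizing
#' `|count - target|`, ties broken toward the larger (more inclusive) count,
#' i.e. the smaller threshold. `target = 0` yields a threshold just above
#' `max(b_g)`.
#'
#' @param norm_k27,norm_k4 Named per-gene normalized promoter FPKM vectors
#'   over the same gene universe (the calibration stage's columns).
#' @param target Target gene count, typically `n_ref` from
#'   [reference_regions].
#' @param stage Optional calibration stage label, recorded on the result.
#' @param source Optional description of where `target` came from.
#' @return An object of class `bivalency_threshold`: list with `theta`,
#'   `target`, `achieved`, `stage`, `source`.
#' @export
calibrate_threshold <- function(norm_k27, norm_k4, target, stage = NA_character_,
                                source = "reference region count") {
  stopifnot(length(norm_k27) == length(norm_k4), target >= 0)
  if (!is.null(names(norm_k27)) && !is.null(names(norm_k4)) &&
      !identical(names(norm_k27), names(norm_k4)))
    stop("norm_k27 and norm_k4 must cover the same genes in the same order")
  n <- length(norm_k27)
  if (target > n)
    stop("calibration target (", target, ") exceeds the gene universe (", n, ")")
  b <- pmin(norm_k27, norm_k4)
  if (target == 0) {
    max_b <- if (n) max(b) else 0
    theta <- max_b + 2 * .Machine$double.eps * max(max_b, 1)
    achieved <- 0L
  } else {
    cand <- sort(unique(b), decreasing = TRUE)       # candidate thresholds
    counts <- cumsum(tabulate(match(b, cand), nbins = length(cand)))
    gap <- abs(counts - target)
    # ties in |count - target| go to the larger count == later candidate
    best <- max(which(gap == min(gap)))
    theta <- cand[best]
    achieved <- counts[best]
  }
  structure(list(theta = theta, target = as.integer(target),
                 achieved = as.integer(achieved), stage = stage, source = source),
            class = "bivalency_threshold")
}

#' @export
print.bivalency_threshold <- function(x, ...) {
  cat(sprintf("<bivalency_threshold> theta=%.6g (stage %s): target %d, achieved %d\n",
              x$theta, x$stage, x$target, x$achieved))
  invisible(x)
}

#' Call bivalent genes at one stage
#'
#' A gene is bivalent iff its normalized promoter FPKM is at or above the
#' unified threshold for *both* marks (inclusive), equivalently iff its
#' limiting signal `b_g = min(normK27, normK4)` is `>= theta`.
#'
#' @param norm_k27,norm_k4 Named per-gene normalized promoter FPKM vectors
#'   over the same gene universe.
#' @param theta The unified threshold (see [calibrate_threshold]).
#' @param stage Stage label recorded on the result.
#' @return An object of class `stage_calls`: list with `stage`, `theta` and
#'   `genes` (data.frame gene_id/norm_k27/norm_k4/b/bivalent).
#' @export
call_bivalent <- function(norm_k27, norm_k4, theta, stage = NA_character_) {
  stopifnot(length(norm_k27) == length(norm_k4), is.finite(theta))
  if (!is.null(names(norm_k27)) && !is.null(names(norm_k4)) &&
      !identical(names(norm_k27), names(norm_k4)))
    stop("norm_k27 and norm_k4 must cover the same genes in the same order")
  ids <- names(norm_k27)
  if (is.null(ids)) ids <- as.character(seq_along(norm_k27))
  b <- pmin(norm_k27, norm_k4)
  genes <- data.frame(gene_id = ids, norm_k27 = unname(norm_k27),
                      norm_k4 = unname(norm_k4), b = unname(b),
                      bivalent = unname(b >= theta), stringsAsFactors = FALSE)
  structure(list(stage = stage, theta = theta, genes = genes),
            class = "stage_calls")
}

#' @export
print.stage_calls <- function(x, ...) {
  cat(sprintf("<stage_calls> stage=%s: %d / %d genes bivalent (theta=%.6g)\n",
              x$stage, sum(x$genes$bivalent), nrow(x$genes), x$theta))
  invisible(x)
}

#' Bivalent gene ids of a call set
#'
#' @param calls A `stage_calls`.
#' @return Character vector of bivalent gene ids.
#' @export
bivalent_genes <- function(calls) {
  stopifnot(inherits(calls, "stage_calls"))
  calls$genes$gene_id[calls$genes$bivalent]
}
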