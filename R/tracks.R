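#' Binned signal track
#'
#' A fixed-bin coverage track for one histone mark at one developmental
#' stage. Values are FPKM per bin; bin `i` (0-based) covers the half-open
#' genomic interval `[i * bin_size, (i + 1) * bin_size)`. Bins never written
#' by the source data are 0; positions beyond the last covered bin of a
#' chromosome are treated as outside the chromosome.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome, in bin order starting at position 0.
#' @param bin_size Bin width in bp (> 0).
#' @param mark Mark label (e.g. `"H3K27me3"`); informational.
#' @param stage Stage label; informational.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, mark = NA_character_, stage = NA_character_) {
  stopifnot(is.list(values), length(bin_size) == 1L, bin_size > 0)
  if (length(values) && is.null(names(values)))
    stop("`values` must be a named (by chromosome) list")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("track values for ", chrom, " are not numeric")
    if (anyNA(v) || any(!is.finite(v))) stop("non-finite track value on ", chrom)
    if (any(v < 0)) stop("negative track value on ", chrom)
  }
  structure(
    list(values = values, bin_size = as.numeric(bin_size),
         mark = mark, stage = stage),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- sum(vapply(x$values, length, 1L))
  cat(sprintf("<binned_track> mark=%s stage=%s bin_size=%g bp, %d chromosomes, %d bins\n",
              x$mark, x$stage, x$bin_size, length(x$values), nb))
  invisible(x)
}

#' Multiply every value of a track by a positive constant
#'
#' Convenience for depth-perturbation experiments.
#'
#' @param track A `binned_track`.
#' @param c Positive scalar.
#' @return A scaled `binned_track`.
#' @export
scale_track <- function(track, c) {
  stopifnot(inherits(track, "binned_track"), is.numeric(c), length(c) == 1L, c > 0)
  track$values <- lapply(track$values, `*`, c)
  track
}

# Rasterize 0-based half-open intervals onto a fixed bin grid.
# Interval boundaries not aligned to the grid contribute length-weighted;
# conserves total mass (sum value * length) exactly up to float rounding.
rasterize_intervals <- function(start, end, value, bin_size) {
  if (length(start) == 0L) return(numeric(0))
  n_bins <- max(ceiling(end / bin_size))
  first <- floor(start / bin_size)
  nb <- ceiling(end / bin_size) - first
  iv <- rep.int(seq_along(start), nb)
  idx <- rep.int(first, nb) + sequence(nb) - 1   # 0-based bin ids
  ov <- pmin(end[iv], (idx + 1) * bin_size) - pmax(start[iv], idx * bin_size)
  acc <- numeric(n_bins)
  sums <- rowsum(value[iv] * ov, idx)
  acc[as.integer(rownames(sums)) + 1L] <- sums[, 1L]
  acc / bin_size
}

# Length-weighted mean of track values over half-open windows on one
# chromosome. Windows are truncated at the chromosome edges ([0, n_bins *
# bin_size)) and renormalized by covered length. Returns NA for windows with
# zero usable length (fully outside the chromosome). Vectorized over windows.
window_means <- function(v, bin_size, win_start, win_end) {
  out <- rep(NA_real_, length(win_start))
  if (length(v) == 0L) return(out)
  chrom_len <- length(v) * bin_size
  ws <- pmax(win_start, 0)
  we <- pmin(win_end, chrom_len)
  len <- we - ws
  ok <- which(len > 0)
  if (!length(ok)) return(out)
  first <- floor(ws[ok] / bin_size)
  nbmax <- max(ceiling(we[ok] / bin_size) - first)
  idx <- outer(first, seq_len(nbmax) - 1, "+")        # 0-based bin ids
  w <- pmax(pmin(we[ok], (idx + 1) * bin_size) - pmax(ws[ok], idx * bin_size), 0)
  vals <- matrix(v[pmin(idx, length(v) - 1) + 1], nrow = nrow(idx))
  out[ok] <- rowSums(vals * w) / len[ok]
  out
}
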