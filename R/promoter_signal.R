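#' Promoter window definition
#'
#' A promoter window around a TSS, in bp. For a plus-strand TSS at 0-based
#' position `t` the window is `[t - upstream, t + downstream)`; for a
#' minus-strand TSS (when `strand_aware`) the exact mirror around the TSS
#' base, `[t + 1 - downstream, t + 1 + upstream)`. With
#' `strand_aware = FALSE` the plus-strand formula is used for every gene.
#'
#' Two windows matter in practice: the normalization window (default
#' 1,000 bp upstream to 500 bp downstream) used to compute saturation scale
#' factors, and the symmetric calling window (±1,000 bp) used for the
#' matrix that bivalency calls are made on.
#'
#' @param upstream,downstream Extents in bp; their sum must be positive.
#' @param strand_aware Orient the window by transcription direction?
#' @return An object of class `promoter_window`.
#' @export
promoter_window <- function(upstream = 1000, downstream = 1000, strand_aware = TRUE) {
  stopifnot(is.numeric(upstream), is.numeric(downstream),
            upstream + downstream > 0, is.logical(strand_aware))
  structure(list(upstream = upstream, downstream = downstream,
                 strand_aware = strand_aware),
            class = "promoter_window")
}

# window bounds for each TSS record; returns list(start, end)
window_bounds <- function(tss, strand, window) {
  minus <- window$strand_aware & strand == "-"
  start <- ifelse(minus, tss + 1 - window$downstream, tss - window$upstream)
  end <- ifelse(minus, tss + 1 + window$upstream, tss + window$downstream)
  list(start = start, end = end)
}

#' Mean promoter signal per gene, with the max-over-TSS rule
#'
#' For every TSS, computes the length-weighted mean of the track over the
#' promoter window (truncated at chromosome edges and renormalized by the
#' covered length). A gene with several TSSs gets the highest value among
#' them. A TSS on a chromosome absent from the track scores 0; a TSS whose
#' window lies entirely outside the covered chromosome extent is an error.
#'
#' @param track A [binned_track].
#' @param ann A `tss_annotation`.
#' @param window A [promoter_window].
#' @return Named numeric vector, one value per gene, in order of first
#'   appearance in the annotation.
#' @export
promoter_mean_signal <- function(track, ann, window) {
  stopifnot(inherits(track, "binned_track"), inherits(ann, "tss_annotation"),
            inherits(window, "promoter_window"))
  genes <- unique(ann$gene_id)
  if (!nrow(ann)) return(stats::setNames(numeric(0), genes))
  wb <- window_bounds(ann$tss, ann$strand, window)
  per_tss <- numeric(nrow(ann))
  for (chrom in unique(ann$chrom)) {
    i <- which(ann$chrom == chrom)
    v <- track$values[[chrom]]
    if (is.null(v)) {
      per_tss[i] <- 0      # chromosome not in track: no signal
      next
    }
    m <- window_means(v, track$bin_size, wb$start[i], wb$end[i])
    if (anyNA(m))
      stop("zero usable promoter window for gene ",
           ann$gene_id[i[which(is.na(m))[1L]]], " on ", chrom)
    per_tss[i] <- m
  }
  out <- vapply(split(per_tss, factor(ann$gene_id, levels = genes)), max, 0)
  stats::setNames(out, genes)
}

#' Build a gene-by-stage promoter signal matrix
#'
#' Applies [promoter_mean_signal] to one track per stage (all for the same
#' mark) and assembles the per-gene vectors as matrix columns in the given
#' stage order.
#'
#' @param tracks Named list (stage name -> [binned_track]) of tracks for one
#'   mark.
#' @param ann A `tss_annotation`.
#' @param window A [promoter_window].
#' @return An object of class `promoter_matrix`: list with `mark`, `window`,
#'   `normalized` (FALSE here) and `values` (gene x stage numeric matrix).
#' @export
build_matrix <- function(tracks, ann, window) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  stages <- names(tracks)
  if (is.null(stages) || any(!nzchar(stages)))
    stop("tracks must be a named list (stage name -> track)")
  if (anyDuplicated(stages))
    stop("duplicate stage names: ", stages[duplicated(stages)][1L])
  marks <- unique(vapply(tracks, function(t) t$mark, ""))
  if (length(marks) > 1L)
    stop("all tracks in a matrix must carry the same mark, got: ",
         paste(marks, collapse = ", "))
  cols <- lapply(tracks, promoter_mean_signal, ann = ann, window = window)
  values <- do.call(cbind, cols)
  colnames(values) <- stages
  structure(list(mark = marks, window = window, normalized = FALSE,
                 values = values),
            class = "promoter_matrix")
}

#' @export
print.promoter_matrix <- function(x, ...) {
  cat(sprintf("<promoter_matrix> mark=%s %s, %d genes x %d stages (window -%g/+%g bp)\n",
              x$mark, if (x$normalized) "normalized" else "raw",
              nrow(x$values), ncol(x$values),
              x$window$upstream, x$window$downstream))
  invisible(x)
}
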