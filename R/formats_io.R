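check_readable <- function(path) {
  if (length(path) != 1L || !is.character(path) || !file.exists(path))
    stop("cannot read '", path, "': no such file")
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Reads a tab-separated table of transcription start sites with columns
#' `gene_id`, `chrom`, `tss`, `strand` (header optional; detected
#' automatically). Coordinates are 0-based. A gene may appear on several
#' rows — one per alternative TSS; promoter quantification later takes the
#' maximum over a gene's TSSs.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `tss_annotation` with columns
#'   `gene_id` (character), `chrom` (character), `tss` (integer-valued
#'   numeric, 0-based) and `strand` (`"+"` or `"-"`).
#' @export
read_tss_annotation <- function(path) {
  check_readable(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty TSS annotation file: ", path)
    return(tss_annotation(data.frame(gene_id = character(), chrom = character(),
                                     tss = numeric(), strand = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cols <- c("gene_id", "chrom", "tss", "strand")
  header <- fields[[1L]]
  has_header <- length(header) >= 4L && is.na(suppressWarnings(as.numeric(header[3L])))
  if (has_header) {
    if (!all(cols %in% header))
      stop("TSS annotation header must contain columns: ", paste(cols, collapse = ", "))
    pos <- match(cols, header)
    fields <- fields[-1L]
  } else {
    pos <- 1:4
  }
  row_offset <- if (has_header) 1L else 0L
  bad_len <- which(vapply(fields, length, 1L) < max(pos))
  if (length(bad_len))
    stop("TSS annotation row ", bad_len[1L] + row_offset, ": expected ",
         length(cols), " tab-separated columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  ann <- data.frame(gene_id = get(pos[1L]), chrom = get(pos[2L]),
                    tss = suppressWarnings(as.numeric(get(pos[3L]))),
                    strand = get(pos[4L]), stringsAsFactors = FALSE)
  check <- function(bad, what) {
    if (any(bad))
      stop("TSS annotation row ", which(bad)[1L] + row_offset, ": ", what)
  }
  check(!nzchar(ann$gene_id), "empty gene_id")
  check(is.na(ann$tss), "non-numeric tss coordinate")
  check(ann$tss < 0, "negative tss coordinate")
  check(!(ann$strand %in% c("+", "-")), "strand must be '+' or '-'")
  tss_annotation(ann)
}

tss_annotation <- function(df) {
  key <- paste(df$gene_id, df$chrom, df$tss)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, chrom, tss) record: ", key[which(duplicated(key))[1L]])
  class(df) <- c("tss_annotation", "data.frame")
  df
}

#' Write a TSS annotation table
#'
#' @param ann A `tss_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_annotation <- function(ann, path) {
  lines <- c("gene_id\tchrom\ttss\tstrand",
             sprintf("%s\t%s\t%d\t%s", ann$gene_id, ann$chrom,
                     as.integer(ann$tss), ann$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Parses a UCSC bedGraph (track lines ignored) and rasterizes the values
#' onto a fixed grid of `bin_size` bp bins. Intervals whose boundaries are
#' not grid-aligned are averaged into bins weighted by overlap length, so
#' total signal mass (sum of value times length) is conserved. Bins not
#' covered by any interval are 0. Intervals must not overlap within a
#' chromosome.
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @param bin_size Target bin width in bp.
#' @param mark,stage Optional labels stored on the returned track.
#' @return A [binned_track].
#' @export
read_bedgraph <- function(path, bin_size, mark = NA_character_, stage = NA_character_) {
  check_readable(path)
  if (file.size(path) == 0L)
    return(binned_track(structure(list(), names = character()), bin_size, mark, stage))
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- S4Vectors::mcols(gr)$score
  if (anyNA(score) || any(!is.finite(score)))
    stop("bedGraph ", path, ": non-finite signal value")
  if (any(score < 0))
    stop("bedGraph ", path, ": negative signal value")
  if (!GenomicRanges::isDisjoint(gr)) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    stop("bedGraph ", path, ": overlapping intervals (e.g. records ",
         S4Vectors::queryHits(ov)[1L], " and ", S4Vectors::subjectHits(ov)[1L], ")")
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  values <- lapply(split(seq_along(gr), chrom), function(i) {
    rasterize_intervals(start0[i], end0[i], score[i], bin_size)
  })
  binned_track(values[unique(chrom)], bin_size, mark, stage)
}

#' Write a binned track as bedGraph
#'
#' Adjacent bins with identical values are merged into one interval, so a
#' write/read round trip through [read_bedgraph] with the same bin size
#' reproduces the track exactly. Output is deterministic (byte-identical for
#' identical tracks). Values are printed with full double precision.
#'
#' @param track A [binned_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       as.integer(start_bin[keep] * track$bin_size),
                       as.integer(end_bin[keep] * track$bin_size),
                       formatC(r$values[keep], format = "g", digits = 17)), con)
  }
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED3+ input; 0-based half-open intervals are preserved verbatim (no
#' merging, no sorting). Strand and score, when present, are retained as
#' metadata but ignored by all downstream peak operations.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` of class `peak_set` with columns `chrom`, `start`,
#'   `end` and, when present in the input, `name`, `score`, `strand`.
#' @export
read_peaks_bed <- function(path) {
  check_readable(path)
  if (file.size(path) == 0L)
    return(peak_set(data.frame(chrom = character(), start = numeric(), end = numeric())))
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) df$strand <- strand
  peak_set(df)
}

peak_set <- function(df) {
  if (any(df$start >= df$end))
    stop("peak interval with start >= end at record ",
         which(df$start >= df$end)[1L])
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Write peaks as BED
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  name <- if (is.null(peaks$name)) "." else peaks$name
  lines <- sprintf("%s\t%d\t%d\t%s", peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-stage expression table
#'
#' Tab-separated, header required: first column `gene_id`, remaining columns
#' one per stage, values FPKM.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with rownames = gene ids and one numeric column per
#'   stage.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop("expression table must have 'gene_id' as its first column")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in expression table")
  rownames(df) <- df$gene_id
  df$gene_id <- NULL
  m <- as.matrix(df)
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop("expression values must be finite and non-negative")
  as.data.frame(df)
}

#' Read a plain-text gene list
#'
#' One gene id per line; blank lines ignored.
#'
#' @param path Path to the file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write per-stage bivalency calls as a TSV table
#'
#' Emits one row per (stage, gene): `gene_id`, `stage`, `normK27`, `normK4`,
#' `b_g` (the limiting signal, min of the two marks) and `is_bivalent`.
#' Rows are ordered by stage then gene id, so output is deterministic.
#'
#' @param calls A single `stage_calls` object or a list of them (see
#'   [call_bivalent]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  if (inherits(calls, "stage_calls")) calls <- list(calls)
  stopifnot(length(calls) >= 1L)
  rows <- lapply(calls, function(cs) {
    stopifnot(inherits(cs, "stage_calls"))
    df <- cs$genes
    data.frame(gene_id = df$gene_id, stage = cs$stage,
               normK27 = df$norm_k27, normK4 = df$norm_k4,
               b_g = df$b, is_bivalent = df$bivalent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stage, out$gene_id, method = "radix"), , drop = FALSE]
  num <- function(x) formatC(x, format = "g", digits = 10)
  lines <- c("gene_id\tstage\tnormK27\tnormK4\tb_g\tis_bivalent",
             sprintf("%s\t%s\t%s\t%s\t%s\t%s", out$gene_id, out$stage,
                     num(out$normK27), num(out$normK4), num(out$b_g),
                     ifelse(out$is_bivalent, "TRUE", "FALSE")))
  writeLines(lines, path)
  invisible(path)
}
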