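#' Classify bivalency transitions between two stages
#'
#' Partitions the union of the two bivalent sets into three disjoint groups:
#' genes bivalent only at the earlier stage (`A_specific`), genes bivalent
#' at both (`shared` — bivalency inherited/maintained), and genes bivalent
#' only at the later stage (`B_specific` — newly gained). Fractions are
#' reported against both stages' bivalent counts; `shared_frac_B`
#' (shared over the later stage's count) is the convention used for
#' statements like "194 out of 1457 inherited".
#'
#' @param calls_A,calls_B `stage_calls` for the earlier and later stage,
#'   over the same gene universe.
#' @return An object of class `transition_partition`: list with `stage_A`,
#'   `stage_B`, the three gene-id sets, their counts, and fractions
#'   relative to each stage's bivalent count.
#' @export
classify_transition <- function(calls_A, calls_B) {
  stopifnot(inherits(calls_A, "stage_calls"), inherits(calls_B, "stage_calls"))
  uA <- calls_A$genes$gene_id
  uB <- calls_B$genes$gene_id
  if (!setequal(uA, uB)) {
    off <- c(setdiff(uA, uB), setdiff(uB, uA))
    stop("gene universes differ between stages; offending genes: ",
         paste(utils::head(off, 5L), collapse = ", "),
         if (length(off) > 5L) sprintf(" (and %d more)", length(off) - 5L) else "")
  }
  A <- bivalent_genes(calls_A)
  B <- bivalent_genes(calls_B)
  shared <- intersect(A, B)
  a_spec <- setdiff(A, B)
  b_spec <- setdiff(B, A)
  frac <- function(k, n) if (n > 0) k / n else NA_real_
  structure(list(
    stage_A = calls_A$stage, stage_B = calls_B$stage,
    A_specific = a_spec, shared = shared, B_specific = b_spec,
    n_A = length(A), n_B = length(B),
    n_A_specific = length(a_spec), n_shared = length(shared),
    n_B_specific = length(b_spec),
    shared_frac_A = frac(length(shared), length(A)),
    shared_frac_B = frac(length(shared), length(B))
  ), class = "transition_partition")
}

#' @export
print.transition_partition <- function(x, ...) {
  cat(sprintf("<transition_partition> %s -> %s: %d %s-specific | %d shared | %d %s-specific\n",
              x$stage_A, x$stage_B, x$n_A_specific, x$stage_A, x$n_shared,
              x$n_B_specific, x$stage_B))
  if (!is.na(x$shared_frac_B))
    cat(sprintf("  shared / bivalent(%s) = %d/%d = %.1f%%\n",
                x$stage_B, x$n_shared, x$n_B, 100 * x$shared_frac_B))
  invisible(x)
}

#' Bivalent-count timeline with consecutive fold changes
#'
#' @param calls Either a list of `stage_calls` (in stage order) or a named
#'   integer vector of per-stage bivalent counts.
#' @return A `data.frame` with columns `stage`, `n_bivalent` and
#'   `fold_change` (count over the previous stage's count; `NA` for the
#'   first stage and whenever the previous count is 0 — undefined, not
#'   infinite).
#' @export
count_timeline <- function(calls) {
  if (is.numeric(calls)) {
    counts <- as.integer(calls)
    stages <- names(calls)
    if (is.null(stages)) stages <- as.character(seq_along(calls))
  } else {
    stopifnot(is.list(calls), length(calls) >= 1L)
    counts <- vapply(calls, function(cs) length(bivalent_genes(cs)), 1L)
    stages <- vapply(calls, function(cs) cs$stage, "")
  }
  prev <- c(NA_integer_, counts[-length(counts)])
  fc <- ifelse(!is.na(prev) & prev > 0, counts / prev, NA_real_)
  data.frame(stage = stages, n_bivalent = counts, fold_change = fc,
             stringsAsFactors = FALSE)
}

#' Summarize expression of gene groups
#'
#' For each group of genes, reports n and the quartiles (q1, median, q3) of
#' either a single stage's FPKM or, for a two-stage contrast, the per-gene
#' `log2((FPKM_B + c) / (FPKM_A + c))` with pseudocount `c`. Genes missing
#' from the expression table are dropped (with a message); if fewer than
#' `min_coverage` of a group is covered, that is an error.
#'
#' @param groups Named list of gene-id character vectors (e.g. the three
#'   sets of a [classify_transition] partition, or bivalent/non-bivalent).
#' @param expr Expression table as from [read_expression_table] (rownames =
#'   gene ids, one column per stage).
#' @param stages A single stage name (FPKM summary) or a length-2 vector
#'   `c(A, B)` (log2 fold-change summary of B over A).
#' @param pseudocount Added to both FPKM values in a contrast (default 1).
#' @param min_coverage Minimum fraction of each group that must be present
#'   in `expr` (default 0.9).
#' @return A `data.frame` with one row per group: `group`, `n`, `q1`,
#'   `median`, `q3`. Empty groups get `n = 0` and `NA` quartiles.
#' @export
summarize_group_expression <- function(groups, expr, stages, pseudocount = 1,
                                       min_coverage = 0.9) {
  stopifnot(is.list(groups), length(stages) %in% 1:2,
            all(stages %in% colnames(expr)))
  if (is.null(names(groups))) stop("`groups` must be a named list")
  per_gene <- if (length(stages) == 1L) {
    stats::setNames(expr[[stages]], rownames(expr))
  } else {
    stats::setNames(log2((expr[[stages[2L]]] + pseudocount) /
                         (expr[[stages[1L]]] + pseudocount)), rownames(expr))
  }
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 0L)
      return(data.frame(group = g, n = 0L, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_))
    present <- ids %in% names(per_gene)
    if (mean(present) < min_coverage)
      stop("expression table covers only ", round(100 * mean(present)),
           "% of group '", g, "' (need >= ", 100 * min_coverage, "%)")
    if (any(!present))
      message(sum(!present), " gene(s) of group '", g,
              "' missing from expression table; dropped")
    q <- stats::quantile(per_gene[ids[present]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = sum(present), q1 = q[1L], median = q[2L], q3 = q[3L])
  })
  do.call(rbind, rows)
}

#' Intersect a bivalent call set with an external gene list
#'
#' Raw overlap counts (no statistics) between the bivalent genes of a stage
#' and an externally supplied gene list, e.g. an up-regulated gene set.
#'
#' @param calls A `stage_calls`.
#' @param gene_list Character vector of gene ids (duplicates ignored).
#' @return List with `n_both`, `n_bivalent_only`, `n_list_only` and the
#'   corresponding gene-id vectors `both`, `bivalent_only`, `list_only`.
#' @export
intersect_with_list <- function(calls, gene_list) {
  stopifnot(inherits(calls, "stage_calls"), is.character(gene_list))
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0L)
    warning("empty external gene list: all overlap counts are 0")
  biv <- bivalent_genes(calls)
  both <- intersect(biv, gene_list)
  list(n_both = length(both),
       n_bivalent_only = length(setdiff(biv, gene_list)),
       n_list_only = length(setdiff(gene_list, biv)),
       both = both,
       bivalent_only = setdiff(biv, gene_list),
       list_only = setdiff(gene_list, biv))
}
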