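#' Saturated signal value of one stage
#'
#' Ranks a stage's per-gene promoter values in descending order and returns
#' the median of the top `top_n` (all values when fewer than `top_n` genes).
#' This "saturated" value anchors cross-stage normalization: marks like
#' H3K27me3/H3K4me3 saturate at their strongest promoters, so the top of the
#' distribution tracks global depth rather than biology.
#'
#' @param column Numeric vector of per-gene promoter FPKM.
#' @param top_n How many top promoters to take the median over (default
#'   3000; lower it for small gene universes).
#' @return The saturated FPKM value (scalar > 0).
#' @export
saturated_value <- function(column, top_n = 3000) {
  stopifnot(length(column) >= 1L, top_n >= 1L)
  top <- sort(column, decreasing = TRUE)[seq_len(min(top_n, length(column)))]
  s <- stats::median(top)
  if (s <= 0)
    stop("degenerate normalization: saturated value is 0 (all-zero top promoters)")
  s
}

#' Compute per-stage saturation scale factors
#'
#' Under the default `"equalize"` convention the factor for stage s is
#' `f_s = S_ref / S_s`, so that after multiplication every stage's saturated
#' value equals the reference stage's — this removes per-stage depth
#' differences. The `"literal"` convention (`f_s = S_s / S_ref`) is the
#' other reading of dividing each stage's saturated value by the reference's
#' and is kept behind this switch; it amplifies rather than removes depth
#' differences and is not recommended.
#'
#' @param matrix A raw `promoter_matrix` (see [build_matrix]).
#' @param reference_stage Stage whose saturated value anchors the factors;
#'   its factor is exactly 1.
#' @param top_n Passed to [saturated_value].
#' @param convention `"equalize"` (default) or `"literal"`.
#' @return An object of class `saturation_factors`: list with `stages`, `S`
#'   (per-stage saturated values), `f` (per-stage factors), `reference`,
#'   `top_n`, `convention`.
#' @export
compute_scale_factors <- function(matrix, reference_stage, top_n = 3000,
                                  convention = c("equalize", "literal")) {
  stopifnot(inherits(matrix, "promoter_matrix"))
  convention <- match.arg(convention)
  stages <- colnames(matrix$values)
  if (!reference_stage %in% stages)
    stop("reference stage '", reference_stage, "' not in matrix stages")
  S <- vapply(stages, function(s) saturated_value(matrix$values[, s], top_n), 0)
  f <- if (convention == "equalize") S[[reference_stage]] / S else S / S[[reference_stage]]
  f[[reference_stage]] <- 1   # exact, not up to rounding
  structure(list(stages = stages, S = S, f = f, reference = reference_stage,
                 top_n = top_n, convention = convention),
            class = "saturation_factors")
}

#' @export
print.saturation_factors <- function(x, ...) {
  cat(sprintf("<saturation_factors> convention=%s reference=%s top_n=%d\n",
              x$convention, x$reference, x$top_n))
  print(data.frame(stage = x$stages, S = unname(x$S), f = unname(x$f)))
  invisible(x)
}

#' Apply saturation scale factors to a promoter matrix
#'
#' Multiplies each stage column by its factor. Within-stage gene ranking is
#' unchanged (factors are positive scalars); under the `"equalize"`
#' convention the saturated value of every stage afterwards equals the
#' reference stage's.
#'
#' @param matrix A `promoter_matrix`.
#' @param factors A `saturation_factors` covering every stage of the matrix
#'   (typically computed from a matrix under the normalization window and
#'   applied to the calling-window matrix).
#' @return The normalized `promoter_matrix` (`normalized = TRUE`).
#' @export
normalize_matrix <- function(matrix, factors) {
  stopifnot(inherits(matrix, "promoter_matrix"),
            inherits(factors, "saturation_factors"))
  stages <- colnames(matrix$values)
  missing <- setdiff(stages, factors$stages)
  if (length(missing))
    stop("no scale factor for stage(s): ", paste(missing, collapse = ", "))
  matrix$values <- sweep(matrix$values, 2L, factors$f[stages], "*")
  matrix$normalized <- TRUE
  matrix
}

#' Write a scale-factor audit table
#'
#' TSV with one row per stage: stage, saturated value S, factor f.
#'
#' @param factors A `saturation_factors`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factors_tsv <- function(factors, path) {
  lines <- c("stage\tsaturated_value\tscale_factor",
             sprintf("%s\t%s\t%s", factors$stages,
                     formatC(unname(factors$S), format = "g", digits = 10),
                     formatC(unname(factors$f), format = "g", digits = 10)))
  writeLines(lines, path)
  invisible(path)
}
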