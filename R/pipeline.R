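#' Read a pipeline run configuration from YAML
#'
#' The file maps directly onto the arguments of [run_pipeline]: a `stages`
#' list (each with `name`, `k27_track`, `k4_track`, optional `k4_peaks`),
#' `annotation`, and optional keys `bin_size`, `norm_window`
#' (`upstream`/`downstream`), `call_window`, `strand_aware`, `top_n`,
#' `convention`, `reference_stage`, `calibration_stage`, `target_count`,
#' `half_width`, `min_mean`, `expression`, `output_dir`. All method
#' constants default to the published values (100 bp bins; -1000/+500
#' normalization window; +/-1000 calling window; top 3000 promoters;
#' +/-2000 bp reference regions; minimum mean 3).
#'
#' @param path Path to a YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

resolve_path <- function(path, base) {
  if (is.null(path) || file.exists(path)) return(path)
  cand <- file.path(base, path)
  if (!is.null(base) && file.exists(cand)) cand else path
}

#' Run the full bivalency pipeline
#'
#' End-to-end orchestration: read annotation and per-stage tracks, quantify
#' promoter signal under the normalization and calling windows, compute
#' per-mark saturation scale factors anchored at the reference stage,
#' normalize the calling-window matrices, derive the reference region count
#' from the calibration stage's H3K4me3 peaks and raw H3K27me3 track
#' (unless `target_count` overrides it), calibrate the unified threshold,
#' call bivalent genes per stage, and classify transitions between
#' consecutive stages. When `output_dir` is set, writes the call table,
#' per-mark factor tables, a transitions TSV and a JSON run report; on any
#' failure partial outputs are removed.
#'
#' @param config A `run_config` (see [read_run_config]), a path to a YAML
#'   file, or an equivalent named list.
#' @return Invisibly, a list with `report` (parameters, saturated values
#'   and factors, theta, n_ref, per-stage counts, transition summaries,
#'   input checksums), `calls` (per-stage `stage_calls`), `threshold`,
#'   `factors`, `partitions` and `timeline`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stages_tab <- config$stages
  if (is.data.frame(stages_tab))
    stages_tab <- lapply(seq_len(nrow(stages_tab)), function(i) as.list(stages_tab[i, ]))
  stage_names <- vapply(stages_tab, `[[`, "", "name")
  if (anyDuplicated(stage_names)) stop("duplicate stage names in config")

  grab <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  base <- config$base_dir
  bin_size <- grab("bin_size", 100)
  nw <- grab("norm_window", list(upstream = 1000, downstream = 500))
  cw <- grab("call_window", list(upstream = 1000, downstream = 1000))
  strand_aware <- grab("strand_aware", TRUE)
  top_n <- grab("top_n", 3000)
  convention <- grab("convention", "equalize")
  calibration_stage <- config$calibration_stage
  if (is.null(calibration_stage))
    stop("config must name a calibration_stage")
  if (!calibration_stage %in% stage_names)
    stop("calibration stage '", calibration_stage, "' not among stages")
  reference_stage <- grab("reference_stage", calibration_stage)
  half_width <- grab("half_width", 2000)
  min_mean <- grab("min_mean", 3)
  norm_window <- promoter_window(nw$upstream, nw$downstream, strand_aware)
  call_window <- promoter_window(cw$upstream, cw$downstream, strand_aware)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  input_paths <- character()
  ann_path <- resolve_path(config$annotation, base)
  input_paths <- c(input_paths, annotation = ann_path)
  ann <- step("read_annotation", read_tss_annotation(ann_path))

  k27_tracks <- list(); k4_tracks <- list(); peak_paths <- list()
  for (st in stages_tab) {
    k27p <- resolve_path(st$k27_track, base)
    k4p <- resolve_path(st$k4_track, base)
    input_paths[paste0(st$name, "_k27")] <- k27p
    input_paths[paste0(st$name, "_k4")] <- k4p
    k27_tracks[[st$name]] <- step(paste0("read_tracks[", st$name, "]"),
                                  read_bedgraph(k27p, bin_size, "H3K27me3", st$name))
    k4_tracks[[st$name]] <- step(paste0("read_tracks[", st$name, "]"),
                                 read_bedgraph(k4p, bin_size, "H3K4me3", st$name))
    if (!is.null(st$k4_peaks) && !is.na(st$k4_peaks))
      peak_paths[[st$name]] <- resolve_path(st$k4_peaks, base)
  }

  res <- step("analysis", analyze_bivalency(
    annotation = ann, k27_tracks = k27_tracks, k4_tracks = k4_tracks,
    k4_peaks = lapply(peak_paths, read_peaks_bed),
    calibration_stage = calibration_stage, reference_stage = reference_stage,
    target_count = config$target_count, top_n = top_n,
    convention = convention, norm_window = norm_window,
    call_window = call_window, half_width = half_width, min_mean = min_mean))

  expr_summary <- NULL
  if (!is.null(config$expression)) {
    expr_path <- resolve_path(config$expression, base)
    input_paths["expression"] <- expr_path
    expr <- step("read_expression", read_expression_table(expr_path))
    expr_summary <- step("expression_summary", lapply(res$calls, function(cs) {
      groups <- list(bivalent = bivalent_genes(cs),
                     non_bivalent = setdiff(cs$genes$gene_id, bivalent_genes(cs)))
      summarize_group_expression(groups, expr, cs$stage)
    }))
  }

  report <- list(
    parameters = list(
      stages = stage_names, bin_size = bin_size,
      norm_window = list(upstream = norm_window$upstream,
                         downstream = norm_window$downstream),
      call_window = list(upstream = call_window$upstream,
                         downstream = call_window$downstream),
      strand_aware = strand_aware, top_n = top_n, convention = convention,
      reference_stage = reference_stage, calibration_stage = calibration_stage,
      target_count = config$target_count, half_width = half_width,
      min_mean = min_mean),
    n_genes = nrow(res$calls[[1L]]$genes),
    inputs = lapply(stats::setNames(seq_along(input_paths), names(input_paths)),
                    function(i) list(path = unname(input_paths[i]),
                                     md5 = unname(tools::md5sum(input_paths[i])))),
    saturated_values = list(H3K27me3 = as.list(res$factors$H3K27me3$S),
                            H3K4me3 = as.list(res$factors$H3K4me3$S)),
    scale_factors = list(H3K27me3 = as.list(res$factors$H3K27me3$f),
                         H3K4me3 = as.list(res$factors$H3K4me3$f)),
    n_ref = res$n_ref, theta = res$threshold$theta,
    threshold_target = res$threshold$target,
    threshold_achieved = res$threshold$achieved,
    bivalent_counts = as.list(stats::setNames(res$timeline$n_bivalent,
                                              res$timeline$stage)),
    transitions = lapply(res$partitions, function(p) list(
      stage_A = p$stage_A, stage_B = p$stage_B,
      n_A_specific = p$n_A_specific, n_shared = p$n_shared,
      n_B_specific = p$n_B_specific,
      shared_frac_A = p$shared_frac_A, shared_frac_B = p$shared_frac_B)))
  if (!is.null(expr_summary)) report$expression_summary <- expr_summary

  out <- list(report = report, calls = res$calls, threshold = res$threshold,
              factors = res$factors, partitions = res$partitions,
              timeline = res$timeline)

  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    tryCatch({
      f <- file.path(dir, "calls.tsv"); written <- c(written, f)
      write_call_table(res$calls, f)
      for (mark in names(res$factors)) {
        f <- file.path(dir, paste0("scale_factors_", mark, ".tsv"))
        written <- c(written, f)
        write_factors_tsv(res$factors[[mark]], f)
      }
      f <- file.path(dir, "transitions.tsv"); written <- c(written, f)
      tp <- do.call(rbind, lapply(res$partitions, function(p)
        data.frame(stage_A = p$stage_A, stage_B = p$stage_B,
                   n_A_specific = p$n_A_specific, n_shared = p$n_shared,
                   n_B_specific = p$n_B_specific)))
      if (is.null(tp)) tp <- data.frame(stage_A = character(), stage_B = character(),
                                        n_A_specific = integer(), n_shared = integer(),
                                        n_B_specific = integer())
      utils::write.table(tp, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f <- file.path(dir, "report.json"); written <- c(written, f)
      jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      out$report$manifest <- written
    }, error = function(e) {
      unlink(written)
      stop("pipeline stage 'write_outputs' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  invisible(out)
}

#' Core bivalency analysis on in-memory objects
#'
#' The computational heart of [run_pipeline], usable directly on a
#' generated [generate_dataset] result (no files needed): quantify,
#' normalize, derive the reference count, calibrate, call and classify.
#'
#' @param annotation A `tss_annotation`.
#' @param k27_tracks,k4_tracks Named lists (stage -> [binned_track]).
#' @param k4_peaks Named list (stage -> `peak_set`); only the calibration
#'   stage's entry is used, and only when `target_count` is NULL.
#' @param calibration_stage Stage whose normalized signals are calibrated
#'   against the reference count.
#' @param reference_stage Anchor of the scale factors (default: the
#'   calibration stage).
#' @param target_count Optional override of the reference region count.
#' @param top_n,convention Passed to [compute_scale_factors].
#' @param norm_window Window the scale factors are computed on
#'   (default -1000/+500 bp).
#' @param call_window Window of the matrix that calls are made on
#'   (default +/-1000 bp).
#' @param half_width,min_mean Passed to [reference_regions].
#' @return List with `matrices` (per-mark normalized `promoter_matrix`),
#'   `factors`, `ref_regions` (NULL under an override), `n_ref`,
#'   `threshold`, `calls`, `partitions`, `timeline`.
#' @export
analyze_bivalency <- function(annotation, k27_tracks, k4_tracks,
                              k4_peaks = list(), calibration_stage,
                              reference_stage = calibration_stage,
                              target_count = NULL, top_n = 3000,
                              convention = "equalize",
                              norm_window = promoter_window(1000, 500),
                              call_window = promoter_window(1000, 1000),
                              half_width = 2000, min_mean = 3) {
  stopifnot(identical(names(k27_tracks), names(k4_tracks)))
  stage_names <- names(k27_tracks)
  stopifnot(calibration_stage %in% stage_names)

  norm_mats <- list(H3K27me3 = build_matrix(k27_tracks, annotation, norm_window),
                    H3K4me3 = build_matrix(k4_tracks, annotation, norm_window))
  call_mats <- list(H3K27me3 = build_matrix(k27_tracks, annotation, call_window),
                    H3K4me3 = build_matrix(k4_tracks, annotation, call_window))
  factors <- lapply(norm_mats, compute_scale_factors,
                    reference_stage = reference_stage, top_n = top_n,
                    convention = convention)
  normalized <- list(
    H3K27me3 = normalize_matrix(call_mats$H3K27me3, factors$H3K27me3),
    H3K4me3 = normalize_matrix(call_mats$H3K4me3, factors$H3K4me3))

  ref <- NULL
  if (is.null(target_count)) {
    if (is.null(k4_peaks[[calibration_stage]]))
      stop("no H3K4me3 peaks for calibration stage '", calibration_stage,
           "' and no target_count override")
    ref <- reference_regions(k4_peaks[[calibration_stage]],
                             k27_tracks[[calibration_stage]],
                             half_width = half_width, min_mean = min_mean)
    target_count <- ref$n_ref
    source <- sprintf("%d reference regions (raw K27 mean >= %g over +/-%g bp around K4 peak centers)",
                      ref$n_ref, min_mean, half_width)
  } else {
    source <- "target count override"
  }

  threshold <- calibrate_threshold(
    normalized$H3K27me3$values[, calibration_stage],
    normalized$H3K4me3$values[, calibration_stage],
    target = target_count, stage = calibration_stage, source = source)
  if (threshold$target == 0L) {
    # degenerate run: silence every stage, not just the calibration one
    gmax <- max(pmin(normalized$H3K27me3$values, normalized$H3K4me3$values))
    threshold$theta <- max(threshold$theta,
                           gmax + 2 * .Machine$double.eps * max(gmax, 1))
  }

  calls <- lapply(stage_names, function(s)
    call_bivalent(normalized$H3K27me3$values[, s],
                  normalized$H3K4me3$values[, s], threshold$theta, stage = s))
  names(calls) <- stage_names

  partitions <- list()
  if (length(stage_names) > 1L)
    for (i in seq_len(length(stage_names) - 1L)) {
      key <- paste0(stage_names[i], "->", stage_names[i + 1L])
      partitions[[key]] <- classify_transition(calls[[i]], calls[[i + 1L]])
    }

  list(matrices = normalized, factors = factors, ref_regions = ref,
       n_ref = target_count, threshold = threshold, calls = calls,
       partitions = partitions, timeline = count_timeline(calls))
}
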