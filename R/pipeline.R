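#' Pipeline configuration
#'
#' @param thresholds classification thresholds
#'   (\code{\link{class_thresholds}}).
#' @param shift read shift in bp for fragment counting.
#' @param window_half_width,bin_width coverage-profile window geometry.
#' @param ma_pseudocount,ma_alpha MA-analysis settings.
#' @param linkage clustering linkage.
#' @param strict abort on missing optional inputs instead of skipping the
#'   stage.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(thresholds = class_thresholds(), shift = 150L,
                            window_half_width = 2000L, bin_width = 10L,
                            ma_pseudocount = 0.5, ma_alpha = 0.01,
                            linkage = "complete", strict = FALSE) {
  stopifnot(inherits(thresholds, "class_thresholds"), shift >= 0,
            window_half_width > 0, bin_width > 0,
            ma_pseudocount > 0, ma_alpha > 0, ma_alpha < 1,
            linkage %in% c("complete", "average", "single"))
  structure(list(thresholds = thresholds, shift = as.integer(shift),
                 window_half_width = as.integer(window_half_width),
                 bin_width = as.integer(bin_width),
                 ma_pseudocount = ma_pseudocount, ma_alpha = ma_alpha,
                 linkage = linkage, strict = strict),
            class = "pipeline_config")
}

#' Run the full replicate-concordance analysis from a manifest
#'
#' Per condition: overlap summary, concordance label, peak partition,
#' coverage profiles and depth diagnostics (when fragment files are
#' listed), TSS summaries (when an annotation is given), MA differential
#' fractions (two-replicate conditions with fragments) and a merge
#' recommendation. Dataset level: class counts and occupancy clustering
#' over all experiments. Missing optional inputs skip their stage with a
#' flag unless \code{strict}.
#'
#' @param manifest manifest TSV path or data.frame
#'   (\code{\link{read_manifest}}).
#' @param config a \code{\link{pipeline_config}}.
#' @param base_dir directory for relative manifest paths (default: the
#'   manifest's own directory).
#' @param annotation optional GTF path or transcript data.frame for TSS
#'   annotation.
#' @return object of class \code{pipeline_report}.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         base_dir = NULL, annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest) && is.null(base_dir))
    base_dir <- dirname(manifest)
  if (is.null(base_dir)) base_dir <- "."
  conds <- load_dataset(manifest, base_dir)
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  idx <- if (!is.null(annotation)) build_tss_index(annotation) else NULL

  per_condition <- lapply(conds, function(cond) {
    s <- overlap_summary(cond)
    label <- classify_condition(s, config$thresholds)
    parts <- partition_condition(cond)
    names(parts) <- vapply(parts, `[[`, character(1), "experiment_id")
    fsets <- list()
    for (e in cond$experiments) {
      if (!is.na(e$fragment_source) && file.exists(e$fragment_source))
        fsets[[e$id]] <- read_fragments_bed(e$fragment_source, e$id,
                                            shift = config$shift)
      else if (!is.na(e$fragment_source) && config$strict)
        stop("missing fragment file for ", e$id, ": ", e$fragment_source)
    }
    have_frags <- length(fsets) == length(cond$experiments)
    profiles <- if (have_frags)
      lapply(names(parts), function(id)
        coverage_profile(parts[[id]], fsets[[id]],
                         config$window_half_width, config$bin_width))
    depth <- if (have_frags) depth_vs_peaks(cond, fsets)
    ma <- if (have_frags && length(cond$experiments) == 2L)
      run_ma_analysis(cond, fsets, pseudocount = config$ma_pseudocount,
                      alpha = config$ma_alpha)
    tss <- if (!is.null(idx))
      lapply(parts, tss_summary, idx = idx)
    if (!is.null(profiles)) names(profiles) <- names(parts)
    list(condition_id = cond$id, summary = s, label = label,
         partitions = parts, profiles = profiles, depth = depth,
         ma = ma, tss = tss,
         skipped = c(coverage = !have_frags, ma = !(have_frags &&
                       length(cond$experiments) == 2L),
                     tss = is.null(idx)),
         recommendation = recommend_peak_list(cond, label))
  })

  classification <- summarize_dataset(conds, config$thresholds)
  all_exps <- unlist(lapply(conds, `[[`, "experiments"),
                     recursive = FALSE, use.names = FALSE)
  clustering <- NULL
  if (length(all_exps) >= 3L) {
    occ <- build_occupancy(all_exps)
    corr <- correlation_matrix(occ)
    clustering <- list(occupancy = occ, correlation = corr,
                       dendrogram = hier_cluster(corr,
                                                 method = config$linkage))
  }
  structure(list(per_condition = per_condition,
                 classification = classification,
                 clustering = clustering, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  counts <- attr(x$classification, "counts")
  cat("Replicate-concordance report:", nrow(x$classification),
      "conditions (", counts["similar"], "similar,", counts["sensitive"],
      "sensitive,", counts["dissimilar"], "dissimilar )\n")
  invisible(x)
}

#' Write a pipeline report to files
#'
#' Emits \code{classification.tsv}, \code{summary.json},
#' \code{dendrogram.nwk} (when clustering ran) and per-condition coverage
#' profile matrices \code{profile_<condition>.tsv}.
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(dir, "classification.tsv")
  utils::write.table(as.data.frame(report$classification), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  counts <- attr(report$classification, "counts")
  summary <- list(
    n_conditions = nrow(report$classification),
    counts = as.list(counts),
    conditions = lapply(report$per_condition, function(pc) {
      list(condition_id = pc$condition_id, label = pc$label,
           fractions = pc$summary$per_experiment$fraction,
           n_peaks = pc$summary$per_experiment$n_peaks,
           strategy = pc$recommendation$strategy,
           fraction_significant =
             if (!is.null(pc$ma)) pc$ma$fraction_significant else NULL,
           skipped = as.list(pc$skipped))
    }))
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)

  if (!is.null(report$clustering)) {
    p <- file.path(dir, "dendrogram.nwk")
    write_newick(report$clustering$dendrogram, p)
    paths <- c(paths, p)
  }
  for (pc in report$per_condition) {
    if (is.null(pc$profiles)) next
    mat <- do.call(cbind, lapply(names(pc$profiles), function(id) {
      cv <- pc$profiles[[id]]$curves
      out <- do.call(cbind, cv)
      colnames(out) <- paste(id, names(cv), sep = ".")
      out
    }))
    df <- data.frame(offset = pc$profiles[[1L]]$offsets, mat,
                     check.names = FALSE)
    p <- file.path(dir, paste0("profile_", pc$condition_id, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
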