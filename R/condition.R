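#' A single ChIP-seq experiment (one peak list)
#'
#' @param id experiment identifier, unique within a dataset.
#' @param condition_id identifier of the condition this replicate belongs to.
#' @param lab,antibody free-text metadata.
#' @param peaks peak data.frame (see \code{\link{read_narrowpeak}}); sorted
#'   on construction.
#' @param fragment_source optional path to a fragment BED file.
#' @return object of class \code{chip_experiment}.
#' @export
chip_experiment <- function(id, condition_id, peaks, lab = "", antibody = "",
                            fragment_source = NA_character_) {
  stopifnot(is.character(id), nzchar(id), is.data.frame(peaks))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(peaks)))
    stop("peaks must have chrom/start/end columns")
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(id = id, condition_id = condition_id, lab = lab,
                 antibody = antibody, peaks = peaks,
                 fragment_source = fragment_source),
            class = "chip_experiment")
}

#' A condition: replicate experiments sharing factor, cell line, treatment
#'
#' Replicated ENCODE-style conditions have between 2 and 5 experiments; a
#' single-experiment condition is allowed at construction but rejected by
#' replicate-comparison operations.
#'
#' @param id condition identifier.
#' @param factor,cell_line,treatment condition metadata.
#' @param experiments list of \code{chip_experiment} objects.
#' @return object of class \code{chip_condition}.
#' @export
chip_condition <- function(id, experiments, factor = "", cell_line = "",
                           treatment = "") {
  stopifnot(is.list(experiments),
            all(vapply(experiments, inherits, logical(1), "chip_experiment")))
  ids <- vapply(experiments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate experiment ids in condition ", id)
  if (length(experiments) > 5L)
    warning("condition ", id, " has ", length(experiments),
            " experiments; replicated conditions normally have 2-5")
  names(experiments) <- ids
  structure(list(id = id, factor = factor, cell_line = cell_line,
                 treatment = treatment, experiments = experiments),
            class = "chip_condition")
}

#' @export
print.chip_experiment <- function(x, ...) {
  cat("ChIP-seq experiment", x$id, "(", nrow(x$peaks), "peaks )\n")
  invisible(x)
}

#' @export
print.chip_condition <- function(x, ...) {
  cat("Condition", x$id, "-", length(x$experiments), "replicates\n")
  for (e in x$experiments)
    cat("  ", e$id, ":", nrow(e$peaks), "peaks\n")
  invisible(x)
}
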