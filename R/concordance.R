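#' Classification thresholds for replicate concordance
#'
#' A condition is \emph{similar} when at least
#' \code{similar_min_fraction} (default 50\%) of the peaks of every
#' replicate overlap the common peak list. Among the rest, it is
#' \emph{sensitive} when one peak list is at least
#' \code{sensitive_size_ratio} times (default 2) bigger than another and
#' strictly more than \code{sensitive_min_small_fraction} (default 70\%) of
#' the smaller list overlaps the common list. Everything else is
#' \emph{dissimilar}.
#'
#' @param similar_min_fraction minimum common-peak fraction for every
#'   replicate of a similar condition (inclusive, \code{>=}).
#' @param sensitive_size_ratio minimum largest/smallest peak-count ratio
#'   (inclusive, \code{>=}).
#' @param sensitive_min_small_fraction common fraction the smallest list
#'   must exceed (strict, \code{>}).
#' @return object of class \code{class_thresholds}.
#' @export
class_thresholds <- function(similar_min_fraction = 0.5,
                             sensitive_size_ratio = 2,
                             sensitive_min_small_fraction = 0.7) {
  stopifnot(similar_min_fraction > 0, similar_min_fraction <= 1,
            sensitive_size_ratio > 0,
            sensitive_min_small_fraction > 0,
            sensitive_min_small_fraction <= 1)
  structure(list(similar_min_fraction = similar_min_fraction,
                 sensitive_size_ratio = sensitive_size_ratio,
                 sensitive_min_small_fraction = sensitive_min_small_fraction),
            class = "class_thresholds")
}

#' Per-replicate overlap with the common peak list
#'
#' Computes the common regions (genomic segments covered by every
#' replicate) and, for each experiment, the number and fraction of its
#' peaks overlapping at least one base of a common region. The fraction of
#' common peaks in each experiment is the measure of replicate consistency
#' that drives classification.
#'
#' @param cond a \code{chip_condition} with at least two experiments, each
#'   with at least one peak.
#' @return object of class \code{overlap_summary}: \code{condition_id},
#'   \code{per_experiment} data.frame (\code{experiment_id}, \code{n_peaks},
#'   \code{n_common}, \code{fraction}), \code{n_common_regions}.
#' @export
overlap_summary <- function(cond) {
  stopifnot(inherits(cond, "chip_condition"))
  exps <- cond$experiments
  if (length(exps) < 2L)
    stop("overlap_summary() needs >= 2 experiments in condition ", cond$id)
  empty <- vapply(exps, function(e) nrow(e$peaks) == 0L, logical(1))
  if (any(empty))
    stop("experiment ", exps[[which(empty)[1L]]]$id,
         " has an empty peak list")
  common <- common_regions(lapply(exps, `[[`, "peaks"))
  per <- do.call(rbind, lapply(exps, function(e) {
    n <- nrow(e$peaks)
    k <- sum(.count_hits(e$peaks, common) > 0L)
    data.frame(experiment_id = e$id, n_peaks = n, n_common = k,
               fraction = k / n, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(condition_id = cond$id, per_experiment = per,
                 n_common_regions = nrow(common), common_regions = common),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Overlap summary for condition", x$condition_id, "(",
      x$n_common_regions, "common regions )\n")
  print(x$per_experiment, row.names = FALSE)
  invisible(x)
}

#' Classify a condition as similar, sensitive or dissimilar
#'
#' @param s an \code{\link{overlap_summary}}.
#' @param thresholds a \code{\link{class_thresholds}} object.
#' @return character scalar: "similar", "sensitive" or "dissimilar".
#' @export
classify_condition <- function(s, thresholds = class_thresholds()) {
  stopifnot(inherits(s, "overlap_summary"),
            inherits(thresholds, "class_thresholds"))
  per <- s$per_experiment
  if (all(per$fraction >= thresholds$similar_min_fraction))
    return("similar")
  big <- max(per$n_peaks)
  small_i <- which.min(per$n_peaks)
  if (big >= thresholds$sensitive_size_ratio * per$n_peaks[small_i] &&
      per$fraction[small_i] > thresholds$sensitive_min_small_fraction)
    return("sensitive")
  "dissimilar"
}

#' Classify every condition in a dataset
#'
#' @param conds list of \code{chip_condition} objects.
#' @param thresholds a \code{\link{class_thresholds}} object.
#' @return object of class \code{concordance_summary}: a data.frame
#'   (\code{condition_id}, \code{label}, \code{n_experiments},
#'   \code{n_peaks}, \code{fractions}) with an aggregate count per label in
#'   \code{attr(, "counts")}.
#' @export
summarize_dataset <- function(conds, thresholds = class_thresholds()) {
  stopifnot(length(conds) >= 1L)
  ids <- vapply(conds, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate condition ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(conds, function(cond) {
    s <- overlap_summary(cond)
    data.frame(
      condition_id = cond$id,
      label = classify_condition(s, thresholds),
      n_experiments = nrow(s$per_experiment),
      n_peaks = paste(s$per_experiment$n_peaks, collapse = ","),
      fractions = paste(sprintf("%.3f", s$per_experiment$fraction),
                        collapse = ","),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$condition_id), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- vapply(c("similar", "sensitive", "dissimilar"),
                   function(l) sum(tab$label == l), integer(1))
  structure(tab, counts = counts,
            class = c("concordance_summary", "data.frame"))
}

#' @export
print.concordance_summary <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(nrow(x), "conditions:", counts["similar"], "similar,",
      counts["sensitive"], "sensitive,", counts["dissimilar"],
      "dissimilar\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Recommended merged peak list for a classified condition
#'
#' Similar and sensitive conditions get the union of the replicate peak
#' lists. For dissimilar conditions, external evidence (clustering, TSS
#' profile, motifs) can name a preferred replicate via \code{override};
#' otherwise the conservative intersection (common regions) is returned
#' with a warning flag.
#'
#' @param cond a \code{chip_condition}.
#' @param label the condition's concordance label.
#' @param override optional experiment id of the preferred replicate
#'   (dissimilar conditions only).
#' @return list with \code{regions} (interval or peak data.frame),
#'   \code{strategy} ("union", "intersection" or "replicate:<id>") and
#'   \code{flagged} (TRUE when intersection was used for lack of evidence).
#' @export
recommend_peak_list <- function(cond, label, override = NULL) {
  stopifnot(inherits(cond, "chip_condition"),
            label %in% c("similar", "sensitive", "dissimilar"))
  lists <- lapply(cond$experiments, `[[`, "peaks")
  if (label %in% c("similar", "sensitive"))
    return(list(regions = merge_regions(lists), strategy = "union",
                flagged = FALSE))
  if (!is.null(override)) {
    if (!override %in% names(cond$experiments))
      stop("override names unknown experiment: ", override)
    return(list(regions = cond$experiments[[override]]$peaks,
                strategy = paste0("replicate:", override), flagged = FALSE))
  }
  list(regions = common_regions(lists), strategy = "intersection",
       flagged = TRUE)
}
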