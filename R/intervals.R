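#' @importFrom GenomicRanges GRanges reduce countOverlaps seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## All coordinates in this package are 0-based half-open [start, end),
## the BED/narrowPeak convention. GRanges (1-based closed) is used only
## internally; the +1/-0 shims below are the single place the two dialects
## meet.

NP_COLS <- c("chrom", "start", "end", "name", "score", "strand",
             "signal", "pvalue", "qvalue", "summit")

#' Construct a genomic-interval data frame
#'
#' Intervals are 0-based half-open \code{[start, end)}. This is the
#' coordinate dialect used everywhere in the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy \code{end > start}.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   sorted by (chrom, start).
#' @export
genomic_intervals <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(start < 0L)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start (half-open intervals)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# interval df (0-based half-open) -> GRanges (1-based closed)
.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

# GRanges -> interval df
.from_gr <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Do two intervals overlap by at least one base?
#'
#' Half-open semantics: \code{[100,200)} and \code{[200,300)} do not
#' overlap; \code{[100,200)} and \code{[199,300)} share one base.
#'
#' @param a,b single intervals: lists or one-row data.frames with
#'   \code{chrom}, \code{start}, \code{end}.
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

# per-row count of peaks in `query` overlapping >=1 bp of `subject`
# (both interval data.frames)
.count_hits <- function(query, subject) {
  if (nrow(query) == 0L) return(integer(0))
  if (nrow(subject) == 0L) return(integer(nrow(query)))
  GenomicRanges::countOverlaps(.as_gr(query), .as_gr(subject),
                               minoverlap = 1L, ignore.strand = TRUE)
}

#' Genomic segments covered by every input peak list
#'
#' Iterated pairwise genomic intersection: the maximal segments covered by
#' at least one peak in each of the input lists. This is the "common peak
#' list" used to score replicate consistency.
#'
#' @param lists list of two or more peak / interval data.frames.
#' @return interval data.frame, sorted and non-overlapping.
#' @export
common_regions <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("common_regions() needs at least 2 peak lists")
  grs <- lapply(lists, function(df)
    GenomicRanges::reduce(.as_gr(df), min.gapwidth = 0L))
  res <- Reduce(function(x, y)
    suppressWarnings(GenomicRanges::intersect(x, y, ignore.strand = TRUE)),
    grs)
  # intersect boundaries from different lists can abut; covered-by-all
  # runs are maximal segments, so adjacent pieces merge here
  .from_gr(GenomicRanges::reduce(res))
}

#' Minimal disjoint cover of one or more peak lists
#'
#' Merges intervals that overlap by at least one base; half-open abutting
#' intervals (\code{[100,200)}, \code{[200,300)}) are kept separate.
#'
#' @param lists list of one or more peak / interval data.frames.
#' @return interval data.frame, sorted and non-overlapping.
#' @export
merge_regions <- function(lists) {
  if (!is.list(lists) || is.data.frame(lists)) lists <- list(lists)
  all <- do.call(rbind, lapply(lists, function(df)
    df[, c("chrom", "start", "end"), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  .from_gr(GenomicRanges::reduce(.as_gr(all), min.gapwidth = 0L))
}

#' Partition each replicate's peaks into common / sample-specific /
#' undetected
#'
#' For each experiment in a condition: \emph{common} peaks overlap at least
#' one peak of every other replicate; \emph{sample-specific} peaks overlap
#' no peak of any other replicate; \emph{undetected} regions are the merged
#' peaks of the other replicates with no overlap in this experiment. With
#' three or more replicates, peaks overlapping some but not all other
#' replicates fall in neither common nor sample-specific.
#'
#' @param cond a \code{chip_condition} (see \code{\link{chip_condition}}).
#' @return list of \code{peak_partition} objects, one per experiment, each
#'   with elements \code{experiment_id}, \code{common},
#'   \code{sample_specific} (peak data.frames) and \code{undetected}
#'   (interval data.frame).
#' @export
partition_condition <- function(cond) {
  stopifnot(inherits(cond, "chip_condition"))
  exps <- cond$experiments
  if (length(exps) < 2L)
    stop("partition_condition() needs a condition with >= 2 experiments")
  lapply(seq_along(exps), function(i) {
    e <- exps[[i]]
    others <- exps[-i]
    hits <- vapply(others, function(o) .count_hits(e$peaks, o$peaks) > 0L,
                   logical(nrow(e$peaks)))
    if (nrow(e$peaks) == 1L) hits <- matrix(hits, nrow = 1L)
    in_all <- apply(hits, 1L, all)
    in_none <- apply(hits, 1L, function(x) !any(x))
    others_merged <- merge_regions(lapply(others, `[[`, "peaks"))
    undet <- others_merged[.count_hits(others_merged, e$peaks) == 0L, ,
                           drop = FALSE]
    structure(list(experiment_id = e$id,
                   common = e$peaks[in_all, , drop = FALSE],
                   sample_specific = e$peaks[in_none, , drop = FALSE],
                   undetected = undet),
              class = "peak_partition")
  })
}

#' @export
print.peak_partition <- function(x, ...) {
  cat("Peak partition for experiment", x$experiment_id, "\n")
  cat("  common:         ", nrow(x$common), "peaks\n")
  cat("  sample-specific:", nrow(x$sample_specific), "peaks\n")
  cat("  undetected:     ", nrow(x$undetected), "regions\n")
  invisible(x)
}
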