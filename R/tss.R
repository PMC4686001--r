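#' Build a TSS index from transcript annotation
#'
#' The TSS of a transcript on the + strand is its start; on the - strand
#' its last base (\code{end - 1} in 0-based coordinates). Transcripts
#' sharing a (chromosome, position, strand) are collapsed into one index
#' entry carrying all transcript ids.
#'
#' @param annotation either a GTF file path (transcript lines are used;
#'   GTF's 1-based closed coordinates are converted on read) or a
#'   data.frame with columns \code{chrom, start, end, strand,
#'   transcript_id} in 0-based half-open coordinates.
#' @return object of class \code{tss_index}: per-chromosome data.frames of
#'   sorted \code{pos}, \code{strand}, \code{ids}.
#' @export
build_tss_index <- function(annotation) {
  if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation, format = "gtf")
    gr <- gr[gr$type == "transcript"]
    annotation <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id
                      else paste0("tx", seq_along(gr)),
      stringsAsFactors = FALSE)
  }
  ok <- annotation$strand %in% c("+", "-")
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " transcript(s) with unknown strand skipped")
  annotation <- annotation[ok, , drop = FALSE]
  pos <- ifelse(annotation$strand == "+", annotation$start,
                annotation$end - 1L)
  key <- paste(annotation$chrom, pos, annotation$strand)
  ids <- vapply(split(annotation$transcript_id, key), paste,
                character(1), collapse = ";")
  u <- !duplicated(key)
  tab <- data.frame(chrom = annotation$chrom[u], pos = pos[u],
                    strand = annotation$strand[u],
                    ids = as.character(ids[key[u]]),
                    stringsAsFactors = FALSE)
  by_chrom <- lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$pos), c("pos", "strand", "ids"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  structure(list(by_chrom = by_chrom, n_skipped = n_skipped),
            class = "tss_index")
}

#' @export
print.tss_index <- function(x, ...) {
  cat("TSS index:", sum(vapply(x$by_chrom, nrow, integer(1))),
      "sites on", length(x$by_chrom), "chromosomes\n")
  invisible(x)
}

# signed distance of point m from TSS at pos/strand: positive when m is
# downstream in gene orientation
.signed_dist <- function(m, pos, strand) {
  ifelse(strand == "+", m - pos, pos - m)
}

#' Signed distance from a peak to its nearest TSS
#'
#' The nearest TSS minimizes the absolute distance from the peak
#' \emph{midpoint}. The sign is strand-aware: positive when the midpoint
#' lies downstream of that TSS in gene orientation, negative upstream.
#' Ties on absolute distance are broken toward the downstream (positive)
#' TSS.
#'
#' @param peak a single interval, or a data.frame of peaks (vectorized).
#' @param idx a \code{\link{build_tss_index}}.
#' @return signed distance(s) in bp; \code{NA} when the peak's chromosome
#'   has no TSS.
#' @export
nearest_tss_distance <- function(peak, idx) {
  stopifnot(inherits(idx, "tss_index"))
  if (is.data.frame(peak) && nrow(peak) != 1L) {
    return(vapply(seq_len(nrow(peak)), function(i)
      nearest_tss_distance(peak[i, ], idx), numeric(1)))
  }
  tab <- idx$by_chrom[[peak$chrom]]
  if (is.null(tab) || nrow(tab) == 0L) return(NA_real_)
  m <- (peak$start + peak$end) %/% 2L
  j <- findInterval(m, tab$pos)
  cand <- unique(pmin(pmax(c(j, j + 1L), 1L), nrow(tab)))
  d <- .signed_dist(m, tab$pos[cand], tab$strand[cand])
  best <- which(abs(d) == min(abs(d)))
  if (length(best) > 1L) {
    pos_best <- best[d[best] > 0]
    best <- if (length(pos_best)) pos_best[1L] else best[1L]
  }
  d[best]
}

#' Distribution summary of TSS distances for peak sets
#'
#' @param peaks a peak data.frame or a \code{peak_partition} (one summary
#'   per set).
#' @param idx a \code{\link{build_tss_index}}.
#' @param breaks positive breakpoints of the log-spaced |distance|
#'   histogram.
#' @return for a data.frame: list of class \code{tss_summary} with
#'   \code{n}, \code{n_unannotated}, \code{median_abs}, \code{frac_overlap}
#'   (TSS inside the peak), \code{frac_downstream} (signed distance > 0)
#'   and \code{hist} (counts per bin). For a partition: named list of such
#'   records.
#' @export
tss_summary <- function(peaks, idx,
                        breaks = c(0, 10^(0:6), Inf)) {
  if (inherits(peaks, "peak_partition")) {
    return(lapply(list(common = peaks$common,
                       sample_specific = peaks$sample_specific,
                       undetected = peaks$undetected),
                  tss_summary, idx = idx, breaks = breaks))
  }
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L)
    return(structure(list(n = 0L, n_unannotated = 0L,
                          median_abs = NA_real_, frac_overlap = NA_real_,
                          frac_downstream = NA_real_, hist = NULL),
                     class = "tss_summary"))
  d <- nearest_tss_distance(peaks, idx)
  ok <- !is.na(d)
  overlap <- vapply(seq_len(nrow(peaks)), function(i) {
    tab <- idx$by_chrom[[peaks$chrom[i]]]
    if (is.null(tab)) return(FALSE)
    any(tab$pos >= peaks$start[i] & tab$pos < peaks$end[i])
  }, logical(1))
  h <- table(cut(abs(d[ok]), breaks = breaks, right = FALSE,
                 include.lowest = TRUE))
  structure(list(n = nrow(peaks), n_unannotated = sum(!ok),
                 median_abs = stats::median(abs(d[ok])),
                 frac_overlap = mean(overlap[ok]),
                 frac_downstream = mean(d[ok] > 0),
                 hist = h, distances = d),
            class = "tss_summary")
}

#' @export
print.tss_summary <- function(x, ...) {
  cat("TSS distances over", x$n, "peaks:",
      "median |d| =", x$median_abs, "bp,",
      sprintf("%.1f%%", 100 * x$frac_overlap), "overlap a TSS,",
      sprintf("%.1f%%", 100 * x$frac_downstream), "downstream\n")
  invisible(x)
}
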