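#' Fragment positions for one experiment
#'
#' A fragment is represented by a single shifted 5' point: \code{pos +
#' shift} on the + strand, \code{pos - shift} on the - strand (shift
#' default 150 bp, moving the 5' end toward the fragment midpoint). The
#' library size is the number of fragments provided, assumed uniquely
#' aligned and deduplicated.
#'
#' @param experiment_id experiment the fragments belong to.
#' @param chrom,pos,strand parallel vectors: chromosome, 0-based 5'
#'   position, strand ("+"/"-").
#' @param shift read shift in bp, >= 0.
#' @return object of class \code{fragment_set} with sorted per-chromosome
#'   shifted positions.
#' @export
fragment_set <- function(experiment_id, chrom, pos, strand, shift = 150L) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand),
            shift >= 0)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("fragment strand must be '+' or '-'")
  shifted <- ifelse(strand == "-", pos - shift, pos + shift)
  by_chrom <- split(as.numeric(shifted), as.character(chrom))
  by_chrom <- lapply(by_chrom, sort)
  structure(list(experiment_id = experiment_id, shifted = by_chrom,
                 library_size = length(pos), shift = shift),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("Fragment set", x$experiment_id, ":", x$library_size,
      "fragments on", length(x$shifted), "chromosomes ( shift", x$shift,
      "bp )\n")
  invisible(x)
}

# fragments with shifted position in [start, end) on one chromosome;
# counts via binary search on the sorted position vector
.count_in <- function(f, chrom, start, end) {
  v <- f$shifted[[chrom]]
  if (is.null(v)) return(rep(0L, length(start)))
  findInterval(end - 0.5, v) - findInterval(start - 0.5, v)
}

#' Count fragments in a region
#'
#' @param region a single interval (list or one-row data.frame with
#'   \code{chrom}, \code{start}, \code{end}).
#' @param f a \code{\link{fragment_set}}.
#' @return integer count of fragments whose shifted position lies in
#'   \code{[start, end)}.
#' @export
count_fragments <- function(region, f) {
  stopifnot(inherits(f, "fragment_set"))
  as.integer(.count_in(f, region$chrom, region$start, region$end))
}

#' Peak FPKM (fragments per kilobase per million)
#'
#' \code{FPKM = count / ((length/1000) * (library_size/1e6))}.
#'
#' @param peak a single interval; or a data.frame of intervals (vectorized).
#' @param f a \code{\link{fragment_set}} with positive library size.
#' @return numeric FPKM value(s).
#' @export
peak_fpkm <- function(peak, f) {
  stopifnot(inherits(f, "fragment_set"), f$library_size > 0)
  len <- peak$end - peak$start
  if (any(len <= 0)) stop("zero-length peak")
  if (is.data.frame(peak) && nrow(peak) > 1L) {
    counts <- vapply(seq_len(nrow(peak)), function(i)
      count_fragments(peak[i, ], f), integer(1))
  } else counts <- count_fragments(peak, f)
  counts / ((len / 1000) * (f$library_size / 1e6))
}

#' Fraction of reads in peaks (FRiP)
#'
#' Peaks are merged first so overlapping peaks never double-count a
#' fragment.
#'
#' @param peaks peak data.frame.
#' @param f a \code{\link{fragment_set}} with positive library size.
#' @return fraction in [0, 1].
#' @export
frip <- function(peaks, f) {
  stopifnot(inherits(f, "fragment_set"), f$library_size > 0)
  merged <- merge_regions(list(peaks))
  inside <- sum(vapply(split(merged, merged$chrom), function(m)
    sum(.count_in(f, m$chrom[1L], m$start, m$end)), numeric(1)))
  inside / f$library_size
}

#' Mean FPKM coverage profiles at common / sample-specific / undetected
#' peaks
#'
#' Windows of \code{± window_half_width} bp are centered on peak midpoints
#' (undetected regions have no summit, so midpoints are used throughout);
#' shifted fragments are counted per \code{bin_width} bp bin, converted to
#' FPKM with the bin as the length term, then averaged over the peaks of
#' each set. Empty peak sets give curves of \code{NA}, not zeros.
#'
#' @param partition a \code{peak_partition} (see
#'   \code{\link{partition_condition}}).
#' @param f a \code{\link{fragment_set}}.
#' @param window_half_width half window in bp (default 2000).
#' @param bin_width bin size in bp (default 10); must divide the window
#'   evenly.
#' @return object of class \code{coverage_profile}: \code{curves} (named
#'   list of mean-FPKM vectors for common, sample_specific, undetected),
#'   bin midpoint offsets in \code{offsets}, per-set peak counts in
#'   \code{n_peaks}, and \code{n_clipped} windows extending past position 0.
#' @export
coverage_profile <- function(partition, f, window_half_width = 2000L,
                             bin_width = 10L) {
  stopifnot(inherits(partition, "peak_partition"),
            inherits(f, "fragment_set"))
  if ((2L * window_half_width) %% bin_width != 0L)
    stop("bin_width must divide the window evenly")
  nbins <- (2L * window_half_width) %/% bin_width
  sets <- list(common = partition$common,
               sample_specific = partition$sample_specific,
               undetected = partition$undetected)
  n_clipped <- 0L
  curves <- lapply(sets, function(df) {
    if (is.null(df) || nrow(df) == 0L) return(rep(NA_real_, nbins))
    mids <- (df$start + df$end) %/% 2L
    counts <- matrix(0, nrow(df), nbins)
    for (i in seq_len(nrow(df))) {
      edges <- mids[i] - window_half_width + bin_width * (0:nbins)
      if (edges[1L] < 0L) n_clipped <<- n_clipped + 1L
      v <- f$shifted[[df$chrom[i]]]
      counts[i, ] <- if (is.null(v)) 0 else diff(findInterval(edges - 0.5, v))
    }
    fpkm <- counts / ((bin_width / 1000) * (f$library_size / 1e6))
    colMeans(fpkm)
  })
  structure(list(window_half_width = window_half_width,
                 bin_width = bin_width, curves = curves,
                 offsets = -window_half_width + bin_width *
                   (seq_len(nbins) - 0.5),
                 n_peaks = vapply(sets, function(d)
                   if (is.null(d)) 0L else nrow(d), integer(1)),
                 n_clipped = n_clipped),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile: +/-", x$window_half_width, "bp,", x$bin_width,
      "bp bins\n")
  for (nm in names(x$curves)) {
    mu <- mean(x$curves[[nm]])
    cat(sprintf("  %-16s %5d peaks, mean FPKM %s\n", nm, x$n_peaks[[nm]],
                if (is.na(mu)) "NA" else sprintf("%.3f", mu)))
  }
  invisible(x)
}

#' Sequencing depth and enrichment versus peak-list size
#'
#' For each replicate, reports peak count, library size and median FPKM at
#' its common peaks. For two replicates the record carries
#' \code{depth_concordant} (the experiment with more reads also has more
#' peaks) and \code{enrichment_concordant} (the experiment with the higher
#' median common-peak FPKM has more peaks); with three or more replicates
#' it reports the sign of the Pearson correlation for both pairings.
#'
#' @param cond a \code{chip_condition}.
#' @param fsets named list of \code{\link{fragment_set}} objects keyed by
#'   experiment id (entries may be missing).
#' @return list of class \code{depth_diagnostic}.
#' @export
depth_vs_peaks <- function(cond, fsets) {
  stopifnot(inherits(cond, "chip_condition"))
  parts <- partition_condition(cond)
  names(parts) <- vapply(parts, `[[`, character(1), "experiment_id")
  per <- do.call(rbind, lapply(cond$experiments, function(e) {
    fs <- fsets[[e$id]]
    has <- !is.null(fs)
    med <- NA_real_
    if (has && nrow(parts[[e$id]]$common) > 0L)
      med <- stats::median(peak_fpkm(parts[[e$id]]$common, fs))
    data.frame(experiment_id = e$id, n_peaks = nrow(e$peaks),
               library_size = if (has) fs$library_size else NA_integer_,
               median_common_fpkm = med, has_fragments = has,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  complete <- all(per$has_fragments)
  res <- list(condition_id = cond$id, per_experiment = per,
              complete = complete)
  if (complete && nrow(per) == 2L) {
    res$depth_concordant <-
      which.max(per$library_size) == which.max(per$n_peaks)
    res$enrichment_concordant <-
      which.max(per$median_common_fpkm) == which.max(per$n_peaks)
  } else if (complete) {
    res$depth_cor_sign <- sign(stats::cor(per$library_size, per$n_peaks))
    res$enrichment_cor_sign <-
      sign(stats::cor(per$median_common_fpkm, per$n_peaks))
  }
  structure(res, class = "depth_diagnostic")
}

#' @export
print.depth_diagnostic <- function(x, ...) {
  cat("Depth/enrichment diagnostic for condition", x$condition_id, "\n")
  print(x$per_experiment, row.names = FALSE)
  if (!is.null(x$depth_concordant))
    cat("  depth concordant:", x$depth_concordant,
        "| enrichment concordant:", x$enrichment_concordant, "\n")
  invisible(x)
}
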