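# Brute-force oracles and tiny builders shared across tests.
# All oracles work in 0-based half-open coordinates on small coordinate
# ranges so per-base enumeration stays cheap.

ORACLE_CHROMS <- c(chrA = 5000L, chrB = 4000L)

rand_intervals <- function(n, chroms = ORACLE_CHROMS, max_w = 300L) {
  chrom <- sample(names(chroms), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chroms[[chrom[i]]] - w[i], 1L) - 1L, integer(1))
  genomic_intervals(chrom, start, start + w)
}

# per-base coverage: named list of logical vectors, index = 0-based pos + 1
base_cover <- function(df, chroms = ORACLE_CHROMS) {
  cov <- lapply(chroms, function(L) logical(L))
  for (i in seq_len(nrow(df)))
    cov[[df$chrom[i]]][(df$start[i] + 1L):df$end[i]] <- TRUE
  cov
}

cover_to_intervals <- function(cov) {
  out <- lapply(names(cov), function(ch) {
    r <- rle(cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    return(genomic_intervals(character(0), integer(0), integer(0)))
  df[order(df$chrom, df$start), , drop = FALSE]
}

oracle_common <- function(lists, chroms = ORACLE_CHROMS) {
  covs <- lapply(lists, base_cover, chroms = chroms)
  all_cov <- covs[[1L]]
  for (cv in covs[-1L])
    for (ch in names(all_cov)) all_cov[[ch]] <- all_cov[[ch]] & cv[[ch]]
  cover_to_intervals(all_cov)
}

oracle_merge <- function(lists, chroms = ORACLE_CHROMS) {
  covs <- lapply(lists, base_cover, chroms = chroms)
  any_cov <- covs[[1L]]
  for (cv in covs[-1L])
    for (ch in names(any_cov)) any_cov[[ch]] <- any_cov[[ch]] | cv[[ch]]
  cover_to_intervals(any_cov)
}

oracle_overlaps <- function(a, b) {
  a$chrom == b$chrom &&
    length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L))) > 0
}

# condition from a list of interval data.frames
mk_condition <- function(lists, id = "cond") {
  exps <- lapply(seq_along(lists), function(i)
    chip_experiment(id = paste0("rep", i), condition_id = id,
                    peaks = lists[[i]]))
  chip_condition(id = id, experiments = exps)
}

# one row interval
iv <- function(chrom, start, end) {
  list(chrom = chrom, start = start, end = end)
}

# hand-made overlap_summary for classifier tests
mk_summary <- function(n_peaks, fractions) {
  structure(list(
    condition_id = "x",
    per_experiment = data.frame(
      experiment_id = paste0("rep", seq_along(n_peaks)),
      n_peaks = n_peaks, n_common = round(n_peaks * fractions),
      fraction = fractions, stringsAsFactors = FALSE),
    n_common_regions = 1L), class = "overlap_summary")
}

# fragment set from bare positions on one chromosome
mk_fragments <- function(pos, strand = "+", chrom = "chrA", shift = 0L,
                         id = "f") {
  fragment_set(id, chrom = rep(chrom, length(pos)), pos = pos,
               strand = rep_len(strand, length(pos)), shift = shift)
}

SMALL_GENOME <- genome_spec(data.frame(name = c("chr1", "chr2"),
                                       length = c(2.5e6, 2.5e6)))
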