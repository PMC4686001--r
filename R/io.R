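#' Read a narrowPeak / BED peak file
#'
#' Accepts 6- to 10-column tab-separated BED-derived files with no header
#' (ENCODE uniform narrowPeak is BED6+4). Gzipped files are read
#' transparently. Missing optional columns are filled with sentinels:
#' \code{NA} for signal/p/q, \code{-1} for the summit offset.
#'
#' @param path file path (.narrowPeak, .bed, optionally .gz).
#' @return peak data.frame with columns \code{chrom, start, end, name,
#'   score, strand, signal, pvalue, qvalue, summit}, sorted by
#'   (chrom, start). \code{summit} is the offset from \code{start}, or -1.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L | nf > 10L))
    stop("malformed peak line ", which(nf < 6L | nf > 10L)[1L], " in ",
         path, ": expected 6-10 tab-separated columns")
  ncol_file <- nf[1L]
  if (any(nf != ncol_file))
    stop("malformed peak line ", which(nf != ncol_file)[1L], " in ", path,
         ": inconsistent column count")
  m <- matrix(unlist(fields), ncol = ncol_file, byrow = TRUE)
  get <- function(j, default) if (ncol_file >= j) m[, j] else default
  df <- data.frame(
    chrom = m[, 1L],
    start = suppressWarnings(as.integer(m[, 2L])),
    end = suppressWarnings(as.integer(m[, 3L])),
    name = as.character(get(4L, ".")),
    score = suppressWarnings(as.integer(get(5L, "0"))),
    strand = as.character(get(6L, ".")),
    signal = suppressWarnings(as.numeric(get(7L, NA_character_))),
    pvalue = suppressWarnings(as.numeric(get(8L, NA_character_))),
    qvalue = suppressWarnings(as.numeric(get(9L, NA_character_))),
    summit = suppressWarnings(as.integer(get(10L, "-1"))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("malformed peak line ", bad[1L], " in ", path,
         ": non-numeric coordinates")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("invalid peak line ", bad[1L], " in ", path, ": end <= start")
  bad <- which(df$summit >= 0L & df$summit >= (df$end - df$start))
  if (length(bad))
    stop("invalid peak line ", bad[1L], " in ", path,
         ": summit offset outside peak")
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

.empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = integer(0), strand = character(0),
             signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
             summit = integer(0), stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak (BED6+4)
#'
#' Missing signal/p/q are written as -1 (the narrowPeak sentinel), so a
#' read/write/read cycle reproduces identical records.
#'
#' @param peaks peak data.frame as returned by \code{\link{read_narrowpeak}}.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  num <- function(x) ifelse(is.na(x), "-1",
                            format(x, trim = TRUE, scientific = FALSE,
                                   digits = 15))
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
                 peaks$score, peaks$strand, num(peaks$signal),
                 num(peaks$pvalue), num(peaks$qvalue), peaks$summit,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read fragment positions from a BED6 file of read intervals
#'
#' The 5' end is inferred from strand (start for +, end - 1 for -);
#' downstream counting shifts it by \code{shift} toward the fragment
#' midpoint.
#'
#' @param path BED file of read/fragment intervals (>= 6 columns, or 3
#'   columns in which case strand is taken as +).
#' @param experiment_id id to attach to the fragment set.
#' @param shift read shift in bp (default 150).
#' @return a \code{\link{fragment_set}}.
#' @export
read_fragments_bed <- function(path, experiment_id = basename(path),
                               shift = 150L) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = list(V1 = "character"))
  strand <- if (ncol(df) >= 6L) df[[6L]] else rep("+", nrow(df))
  pos <- ifelse(strand == "-", as.integer(df[[3L]]) - 1L,
                as.integer(df[[2L]]))
  fragment_set(experiment_id, chrom = df[[1L]], pos = pos, strand = strand,
               shift = shift)
}

#' Read a condition manifest
#'
#' Tab-separated with header; required columns \code{experiment_id,
#' condition_id, factor, cell_line, treatment, lab, antibody, peak_path};
#' optional \code{fragment_path} (empty for peak-only experiments).
#'
#' @param path manifest TSV path.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  req <- c("experiment_id", "condition_id", "factor", "cell_line",
           "treatment", "lab", "antibody", "peak_path")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$experiment_id))
    stop("duplicate experiment_id in manifest")
  if (!"fragment_path" %in% names(m)) m$fragment_path <- ""
  m
}

#' Load a dataset of conditions from a manifest
#'
#' @param manifest path to a manifest TSV or a data.frame from
#'   \code{\link{read_manifest}}.
#' @param base_dir directory against which relative paths are resolved.
#' @return named list of \code{chip_condition} objects.
#' @export
load_dataset <- function(manifest, base_dir = ".") {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  resolve <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                                file.path(base_dir, p), p)
  conds <- lapply(split(m, m$condition_id), function(rows) {
    rows <- rows[order(rows$experiment_id), , drop = FALSE]
    exps <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      chip_experiment(id = r$experiment_id, condition_id = r$condition_id,
                      lab = r$lab, antibody = r$antibody,
                      peaks = read_narrowpeak(resolve(r$peak_path)),
                      fragment_source = if (nzchar(r$fragment_path))
                        resolve(r$fragment_path) else NA_character_)
    })
    chip_condition(id = rows$condition_id[1L], factor = rows$factor[1L],
                   cell_line = rows$cell_line[1L],
                   treatment = rows$treatment[1L], experiments = exps)
  })
  conds[order(names(conds))]
}
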