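#' Genome specification for the synthetic generator
#'
#' @param chromosomes data.frame with columns \code{name} and \code{length}
#'   (bp). Default: two 10 Mb chromosomes, enough room for ~1000
#'   narrowPeak-sized sites at realistic density.
#' @return object of class \code{genome_spec}.
#' @export
genome_spec <- function(chromosomes = data.frame(
                          name = c("chr1", "chr2"),
                          length = c(10e6, 10e6))) {
  stopifnot(all(chromosomes$length > 0),
            !anyDuplicated(chromosomes$name))
  chromosomes$name <- as.character(chromosomes$name)
  structure(list(chromosomes = chromosomes,
                 total = sum(chromosomes$length)),
            class = "genome_spec")
}

#' Specification of one synthetic replicated condition
#'
#' Encodes the mechanisms behind the three concordance classes: replicates
#' share a set of true binding sites; each replicate detects a site with a
#' probability that grows with the site's ChIP strength (scaled so the
#' mean detection rate equals \code{sensitivity}), add false peaks as a
#' Poisson process, and sample fragments as uniform background plus
#' strength-proportional enrichment at \emph{true} sites -- so sites a
#' replicate failed to detect still carry signal. Dissimilar conditions
#' additionally restrict each replicate to a partially disjoint detectable
#' subset of sites (\code{site_overlap} = fraction shared).
#'
#' @param id condition id.
#' @param intended_class "similar", "sensitive" or "dissimilar"; fills
#'   class-typical defaults for \code{sensitivity} and \code{site_overlap}
#'   when those are NULL.
#' @param n_replicates number of replicate experiments (2-5).
#' @param n_true_sites number of true binding sites.
#' @param site_width length-2 range of site widths (bp).
#' @param sensitivity per-replicate mean detection probability, recycled.
#' @param site_overlap fraction of true sites detectable by all replicates
#'   (1 = fully shared; < 1 splits the rest evenly into
#'   replicate-exclusive subsets).
#' @param false_peak_rate false peaks per Mb per replicate.
#' @param boundary_jitter peak boundary jitter, uniform on
#'   \code{[-jitter, jitter]} bp per edge.
#' @param enrichment_fold mean fold enrichment of fragment density at true
#'   sites over background (> 1); recycled per replicate, so replicates
#'   can differ in ChIP efficiency.
#' @param library_size target fragments per replicate, recycled (used to
#'   derive the background rate unless \code{background_rate} is given).
#' @param background_rate background fragments per bp; overrides
#'   \code{library_size} when set.
#' @param differential_fraction fraction of true sites whose enrichment
#'   differs between replicates 1 and 2 (alternating direction), for
#'   differential-binding simulations.
#' @param differential_ratio fold change at differential sites.
#' @param shift read shift the fragment coordinates are built for.
#' @param seed RNG seed for this condition.
#' @return object of class \code{condition_spec}.
#' @export
condition_spec <- function(id, intended_class = c("similar", "sensitive",
                                                  "dissimilar"),
                           n_replicates = 2L, n_true_sites = 1000L,
                           site_width = c(150L, 400L), sensitivity = NULL,
                           site_overlap = NULL, false_peak_rate = 2,
                           boundary_jitter = 20L, enrichment_fold = 5,
                           library_size = 1e6, background_rate = NULL,
                           differential_fraction = 0,
                           differential_ratio = 1, shift = 150L,
                           seed = 1L) {
  intended_class <- match.arg(intended_class)
  if (is.null(sensitivity))
    sensitivity <- switch(intended_class,
                          similar = 0.92,
                          sensitive = c(0.95, 0.30),
                          dissimilar = 0.90)
  if (is.null(site_overlap))
    site_overlap <- if (intended_class == "dissimilar") 0.2 else 1
  sensitivity <- rep_len(sensitivity, n_replicates)
  enrichment_fold <- rep_len(enrichment_fold, n_replicates)
  library_size <- rep_len(library_size, n_replicates)
  stopifnot(n_replicates >= 2L, n_replicates <= 5L,
            all(sensitivity > 0), all(sensitivity <= 1),
            site_overlap > 0, site_overlap <= 1,
            all(enrichment_fold > 1), false_peak_rate >= 0,
            differential_fraction >= 0, differential_fraction <= 1,
            differential_ratio >= 1)
  structure(list(id = id, intended_class = intended_class,
                 n_replicates = as.integer(n_replicates),
                 n_true_sites = as.integer(n_true_sites),
                 site_width = as.integer(site_width),
                 sensitivity = sensitivity, site_overlap = site_overlap,
                 false_peak_rate = false_peak_rate,
                 boundary_jitter = as.integer(boundary_jitter),
                 enrichment_fold = enrichment_fold,
                 library_size = library_size,
                 background_rate = background_rate,
                 differential_fraction = differential_fraction,
                 differential_ratio = differential_ratio,
                 shift = as.integer(shift), seed = as.integer(seed)),
            class = "condition_spec")
}

# uniform non-overlapping placement: assign sites to chromosomes, then use
# the gap construction (uniform points in the free space, offset by the
# cumulated widths) which cannot produce overlaps
.place_sites <- function(g, n, width_range) {
  widths <- sample(seq(width_range[1L], width_range[2L]), n, replace = TRUE)
  chrom <- sample(g$chromosomes$name, n, replace = TRUE,
                  prob = g$chromosomes$length)
  out <- vector("list", length(g$chromosomes$name))
  for (ci in seq_along(g$chromosomes$name)) {
    nm <- g$chromosomes$name[ci]
    len <- g$chromosomes$length[ci]
    i <- which(chrom == nm)
    if (!length(i)) next
    w <- widths[i]
    free <- len - sum(w)
    if (free <= 0)
      stop("cannot place ", length(i), " sites on ", nm,
           " without overlap; use a larger genome")
    pts <- sort(floor(stats::runif(length(w), 0, free)))
    starts <- pts + c(0, cumsum(w[-length(w)]))
    out[[ci]] <- data.frame(chrom = nm, start = as.integer(starts),
                            end = as.integer(starts + w),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# logistic detection curve in log strength, intercept calibrated so the
# mean detection probability over the given strengths equals `target`
.detect_probs <- function(strength, target) {
  if (target >= 1) return(rep(1, length(strength)))
  f <- function(a) mean(stats::plogis(a + 2 * log(strength))) - target
  a <- stats::uniroot(f, c(-60, 60))$root
  stats::plogis(a + 2 * log(strength))
}

.sample_chrom_pos <- function(g, n) {
  chrom <- sample(g$chromosomes$name, n, replace = TRUE,
                  prob = g$chromosomes$length)
  len <- g$chromosomes$length[match(chrom, g$chromosomes$name)]
  data.frame(chrom = chrom, pos = floor(stats::runif(n, 0, len)),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic replicated condition with ground truth
#'
#' See \code{\link{condition_spec}} for the generative model. Identical
#' seeds give identical output.
#'
#' @param g a \code{\link{genome_spec}}.
#' @param s a \code{\link{condition_spec}}.
#' @param fragments also simulate fragment sets (slower; peak lists alone
#'   are enough for classification).
#' @param true_sites optional pre-placed site data.frame (chrom, start,
#'   end), e.g. relocated to TSSs by \code{\link{generate_tss}}.
#' @return list of class \code{synthetic_condition}: \code{condition}
#'   (a \code{chip_condition}), \code{fragments} (named list of
#'   \code{fragment_set}s or NULL) and \code{truth} (true sites with
#'   strengths, per-replicate detectable/detected flags, intended class).
#' @export
generate_condition <- function(g, s, fragments = TRUE, true_sites = NULL) {
  stopifnot(inherits(g, "genome_spec"), inherits(s, "condition_spec"))
  set.seed(s$seed)
  sites <- if (is.null(true_sites))
    .place_sites(g, s$n_true_sites, s$site_width)
  else true_sites[order(true_sites$chrom, true_sites$start), , drop = FALSE]
  n <- nrow(sites)
  strength <- stats::rgamma(n, shape = 2, rate = 2)  # mean 1
  strength <- pmax(strength, 0.05)

  # replicate-exclusive detectable subsets for dissimilar conditions
  owner <- rep(0L, n)                      # 0 = shared by all
  if (s$site_overlap < 1) {
    excl <- stats::runif(n) >= s$site_overlap
    owner[excl] <- sample(seq_len(s$n_replicates), sum(excl),
                          replace = TRUE)
  }

  # differential enrichment between replicates 1 and 2 (direction
  # alternates so the normalization line stays centred)
  fold_mult <- matrix(1, n, s$n_replicates)
  if (s$differential_fraction > 0 && s$differential_ratio > 1) {
    diff_i <- which(stats::runif(n) < s$differential_fraction)
    up1 <- seq_along(diff_i) %% 2L == 1L
    fold_mult[diff_i[up1], 1L] <- s$differential_ratio
    fold_mult[diff_i[!up1], 2L] <- s$differential_ratio
  }

  site_bp <- sum(sites$end - sites$start)

  exps <- vector("list", s$n_replicates)
  fsets <- if (fragments) vector("list", s$n_replicates) else NULL
  detected_mat <- matrix(FALSE, n, s$n_replicates)
  for (r in seq_len(s$n_replicates)) {
    detectable <- owner == 0L | owner == r
    p <- .detect_probs(strength, s$sensitivity[r])
    detected <- detectable & stats::runif(n) < p
    detected_mat[, r] <- detected

    det <- sites[detected, , drop = FALSE]
    jit <- function(k) as.integer(round(stats::runif(k, -s$boundary_jitter,
                                                     s$boundary_jitter)))
    k <- nrow(det)
    pk_start <- pmax(0L, det$start + jit(k))
    pk_end <- pmax(pk_start + 20L, det$end + jit(k))
    n_false <- stats::rpois(1L, s$false_peak_rate * g$total / 1e6)
    fp <- .place_sites(g, max(n_false, 1L), s$site_width)
    fp <- fp[seq_len(n_false), , drop = FALSE]
    peaks <- data.frame(
      chrom = c(det$chrom, fp$chrom),
      start = c(pk_start, fp$start),
      end = c(pk_end, fp$end),
      stringsAsFactors = FALSE)
    peaks$name <- sprintf("%s_rep%d_pk%d", s$id, r, seq_len(nrow(peaks)))
    peaks$score <- 0L
    peaks$strand <- "."
    peaks$signal <- round(c(strength[detected] * s$enrichment_fold[r],
                            rep(1, n_false)), 3)
    peaks$pvalue <- NA_real_
    peaks$qvalue <- NA_real_
    peaks$summit <- (peaks$end - peaks$start) %/% 2L
    id <- sprintf("%s_rep%d", s$id, r)
    exps[[r]] <- chip_experiment(id = id, condition_id = s$id,
                                 peaks = peaks, lab = "synthetic",
                                 antibody = s$id)

    if (fragments) {
      bg <- if (!is.null(s$background_rate)) s$background_rate
            else s$library_size[r] /
              (g$total + (s$enrichment_fold[r] - 1) * site_bp)
      n_bg <- stats::rpois(1L, bg * g$total)
      bgf <- .sample_chrom_pos(g, n_bg)
      lambda <- (s$enrichment_fold[r] - 1) * bg *
        (sites$end - sites$start) * strength * fold_mult[, r]
      n_site <- stats::rpois(n, lambda)
      idx <- rep.int(seq_len(n), n_site)
      w <- sites$end[idx] - sites$start[idx]
      target <- (sites$start[idx] + sites$end[idx]) / 2 +
        stats::rnorm(length(idx), 0, w / 4)
      target <- pmin(pmax(round(target), sites$start[idx]),
                     sites$end[idx] - 1L)
      chrom <- c(bgf$chrom, sites$chrom[idx])
      tgt <- c(bgf$pos, target)
      strand <- sample(c("+", "-"), length(tgt), replace = TRUE)
      five <- ifelse(strand == "-", tgt + s$shift, tgt - s$shift)
      lens <- g$chromosomes$length[match(chrom, g$chromosomes$name)]
      five <- pmin(pmax(five, 0L), lens - 1L)
      fsets[[r]] <- fragment_set(id, chrom = chrom, pos = five,
                                 strand = strand, shift = s$shift)
    }
  }
  cond <- chip_condition(id = s$id, experiments = exps,
                         factor = s$id, cell_line = "synthetic",
                         treatment = "none")
  if (fragments) names(fsets) <- names(cond$experiments)
  truth <- sites
  truth$strength <- strength
  for (r in seq_len(s$n_replicates)) {
    truth[[paste0("detectable_rep", r)]] <- owner == 0L | owner == r
    truth[[paste0("detected_rep", r)]] <- detected_mat[, r]
  }
  structure(list(condition = cond, fragments = fsets,
                 truth = truth, intended_class = s$intended_class,
                 spec = s),
            class = "synthetic_condition")
}

#' Generate a synthetic transcript annotation (and optionally relocate
#' binding sites to promoters)
#'
#' Transcripts get uniform starts, lengths uniform on 1-100 kb (clipped to
#' the chromosome) and random strands. When \code{sites} is given,
#' \code{promoter_bias} of them are recentred on sampled TSSs, which makes
#' promoter-bound factors simulable.
#'
#' @param g a \code{\link{genome_spec}}.
#' @param n_genes number of transcripts.
#' @param promoter_bias fraction of \code{sites} recentred on TSSs.
#' @param sites optional site data.frame (chrom, start, end).
#' @param seed RNG seed.
#' @return list: \code{index} (a \code{tss_index}), \code{transcripts}
#'   (data.frame), \code{sites} (possibly relocated copy of the input).
#' @export
generate_tss <- function(g, n_genes, promoter_bias = 0, sites = NULL,
                         seed = 1L) {
  stopifnot(inherits(g, "genome_spec"), n_genes > 0)
  set.seed(seed)
  pos <- .sample_chrom_pos(g, n_genes)
  lens <- g$chromosomes$length[match(pos$chrom, g$chromosomes$name)]
  txlen <- pmin(floor(stats::runif(n_genes, 1e3, 1e5)), lens - pos$pos - 1)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tx <- data.frame(chrom = pos$chrom, start = pos$pos,
                   end = pos$pos + pmax(txlen, 200L), strand = strand,
                   transcript_id = sprintf("tx%04d", seq_len(n_genes)),
                   stringsAsFactors = FALSE)
  idx <- build_tss_index(tx)
  if (!is.null(sites) && promoter_bias > 0) {
    tss_pos <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
    move <- which(stats::runif(nrow(sites)) < promoter_bias)
    pick <- sample(n_genes, length(move), replace = TRUE)
    w <- sites$end[move] - sites$start[move]
    sites$chrom[move] <- tx$chrom[pick]
    sites$start[move] <- pmax(0L, as.integer(tss_pos[pick] - w %/% 2L))
    sites$end[move] <- sites$start[move] + w
    sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
    rownames(sites) <- NULL
  }
  list(index = idx, transcripts = tx, sites = sites)
}

.write_gtf <- function(tx, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   sub("tx", "g", tx$transcript_id), tx$transcript_id)
  lines <- paste(tx$chrom, "synthetic", "transcript", tx$start + 1L,
                 tx$end, ".", tx$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

.write_fragments_bed <- function(f_raw, path, read_len = 50L) {
  # f_raw: data.frame chrom, five (0-based 5' position), strand
  start <- ifelse(f_raw$strand == "-", pmax(0L, f_raw$five - read_len + 1L),
                  f_raw$five)
  end <- ifelse(f_raw$strand == "-", f_raw$five + 1L, f_raw$five + read_len)
  lines <- paste(f_raw$chrom, start, end, ".", 0L, f_raw$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a dataset of synthetic conditions on disk
#'
#' Writes, per replicate, a narrowPeak file and (optionally) a fragment
#' BED6 file, plus a manifest TSV, a ground-truth table and (optionally) a
#' GTF of synthetic transcripts -- the same formats the pipeline consumes.
#'
#' @param specs list of \code{\link{condition_spec}} objects with unique
#'   ids.
#' @param dir output directory (created if needed).
#' @param g a \code{\link{genome_spec}}.
#' @param fragments write fragment BED files.
#' @param n_genes when > 0, also write \code{genes.gtf}.
#' @param seed base seed added to each spec's own seed, so the whole
#'   dataset moves with one number while conditions stay independent.
#' @return list: \code{manifest} (path), \code{truth} (data.frame of
#'   per-condition intended classes), \code{dir}.
#' @export
generate_dataset <- function(specs, dir, g = genome_spec(),
                             fragments = FALSE, n_genes = 0L, seed = 0L) {
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate condition ids in specs")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  for (sp in specs) {
    sp$seed <- (sp$seed + 1009L * as.integer(seed)) %% 2147483647L
    gen <- generate_condition(g, sp, fragments = fragments)
    for (e in gen$condition$experiments) {
      pk_path <- file.path(dir, paste0(e$id, ".narrowPeak"))
      write_narrowpeak(e$peaks, pk_path)
      fr_path <- ""
      if (fragments) {
        fs <- gen$fragments[[e$id]]
        # recover raw 5' positions from the shifted representation
        raw <- do.call(rbind, lapply(names(fs$shifted), function(ch) {
          data.frame(chrom = ch, shifted = fs$shifted[[ch]],
                     stringsAsFactors = FALSE)
        }))
        strand <- sample(c("+", "-"), nrow(raw), replace = TRUE)
        # a + read's 5' end would be negative near the chromosome start;
        # flip those to - so the shifted position survives the round trip
        strand[raw$shifted - fs$shift < 0] <- "-"
        raw$five <- ifelse(strand == "-", raw$shifted + fs$shift,
                           raw$shifted - fs$shift)
        raw$strand <- strand
        fr_path <- file.path(dir, paste0(e$id, "_fragments.bed"))
        .write_fragments_bed(raw, fr_path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = e$id, condition_id = sp$id, factor = sp$id,
        cell_line = "synthetic", treatment = "none", lab = "synthetic",
        antibody = sp$id, peak_path = basename(pk_path),
        fragment_path = if (nzchar(fr_path)) basename(fr_path) else "",
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      condition_id = sp$id, intended_class = sp$intended_class,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- data.frame(experiment_id = character(0),
                           condition_id = character(0),
                           factor = character(0), cell_line = character(0),
                           treatment = character(0), lab = character(0),
                           antibody = character(0),
                           peak_path = character(0),
                           fragment_path = character(0))
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (n_genes > 0L) {
    tss <- generate_tss(g, n_genes, seed = seed + 1L)
    .write_gtf(tss$transcripts, file.path(dir, "genes.gtf"))
  }
  list(manifest = manifest_path, truth = truth, dir = dir)
}

#' The frozen margin-separated recovery specifications
#'
#' Sixty conditions, twenty per intended class, whose generating
#' parameters keep every classification decision quantity at least 0.10
#' away from the 0.50 / 2x / 0.70 thresholds. Stored as a plain-text
#' fixture in \code{inst/extdata/recovery_specs.tsv}.
#'
#' @return data.frame of spec parameters.
#' @export
recovery_specs <- function() {
  path <- system.file("extdata", "recovery_specs.tsv",
                      package = "chipconcord")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Generate the 60-condition recovery dataset in memory
#'
#' @param seed base seed mixed into each frozen spec's own seed.
#' @param fragments simulate fragments too (slower; not needed for
#'   classification).
#' @param g genome to simulate on.
#' @return list of \code{synthetic_condition} objects, one per fixture
#'   row.
#' @export
generate_recovery_dataset <- function(seed = 1L, fragments = FALSE,
                                      g = genome_spec()) {
  tab <- recovery_specs()
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sp <- condition_spec(
      id = r$condition_id, intended_class = r$intended_class,
      n_replicates = r$n_replicates, n_true_sites = r$n_true_sites,
      site_width = c(r$site_width_min, r$site_width_max),
      sensitivity = as.numeric(strsplit(r$sensitivity, ",")[[1]]),
      site_overlap = r$site_overlap, false_peak_rate = r$false_peak_rate,
      boundary_jitter = r$boundary_jitter,
      enrichment_fold = r$enrichment_fold, library_size = r$library_size,
      seed = (r$seed + 1009L * as.integer(seed)) %% 2147483647L)
    generate_condition(g, sp, fragments = fragments)
  })
}
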