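#' MA transform of two counts
#'
#' \code{M = log2((x1+c)/(x2+c))}, \code{A = 0.5*log2((x1+c)*(x2+c))} with
#' pseudocount \code{c} (default 0.5).
#'
#' @param x1,x2 non-negative counts (vectorized).
#' @param c pseudocount, > 0.
#' @return list with numeric vectors \code{M} and \code{A}.
#' @export
ma_transform <- function(x1, x2, c = 0.5) {
  stopifnot(all(x1 >= 0), all(x2 >= 0), c > 0)
  list(M = log2((x1 + c) / (x2 + c)),
       A = 0.5 * log2((x1 + c) * (x2 + c)))
}

#' Robust MA normalization line fitted on common regions
#'
#' Fits \code{M = a + b*A} by iteratively reweighted least squares with
#' Huber weights (k = 1.345), at most 50 iterations, convergence tolerance
#' 1e-8 on the coefficients. Only regions detected in both replicates
#' (common regions) should be supplied: the model assumes those are, on
#' average, equally bound, so the fitted line captures the global
#' efficiency/depth difference.
#'
#' @param M,A numeric vectors from \code{\link{ma_transform}} at common
#'   regions; at least 10 values.
#' @param k Huber tuning constant.
#' @param maxit,tol IRLS iteration cap and coefficient tolerance.
#' @return object of class \code{ma_fit}: \code{intercept}, \code{slope},
#'   \code{n_common}, \code{iterations}.
#' @export
fit_normalization <- function(M, A, k = 1.345, maxit = 50L, tol = 1e-8) {
  stopifnot(length(M) == length(A))
  if (length(M) < 10L)
    stop("fewer than 10 common regions: condition too discordant to ",
         "normalize")
  X <- cbind(1, A)
  beta <- stats::lm.fit(X, M)$coefficients
  it <- 0L
  repeat {
    it <- it + 1L
    r <- M - X %*% beta
    s <- stats::median(abs(r - stats::median(r))) / 0.6744898
    if (s < 1e-12) break   # (near-)perfect fit; weights undefined
    w <- pmin(1, k * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    beta_new <- stats::lm.wfit(X, M, as.vector(w))$coefficients
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done || it >= maxit) break
  }
  structure(list(intercept = unname(beta[1L]), slope = unname(beta[2L]),
                 n_common = length(M), iterations = it),
            class = "ma_fit")
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf(
    "MA normalization: M = %.4f + %.4f * A (fit on %d common regions, %d iterations)\n",
    x$intercept, x$slope, x$n_common, x$iterations))
  invisible(x)
}

# two-sided exact binomial p-value of x successes in n trials at p = 1/2;
# the symmetric case reduces to twice the smaller tail
.binom_p <- function(x, n) {
  p <- rep(1, length(x))
  nz <- n > 0L
  p[nz] <- pmin(1, 2 * stats::pbinom(pmin(x[nz], n[nz] - x[nz]), n[nz], 0.5))
  p
}

#' Normalize an MA table and test each region for differential binding
#'
#' \code{M_norm = M - (a + b*A)}; normalized counts are reconstructed so
#' that the pseudocounted product (\code{A}) is preserved and
#' \code{log2} of the pseudocounted ratio equals \code{M_norm}; the
#' pseudocount is then removed and counts rounded to non-negative
#' integers, so a zero fit returns the raw counts unchanged. Each
#' region is then tested with a two-sided exact binomial test of \code{x1'}
#' successes in \code{x1'+x2'} trials at p = 1/2; a region is significant
#' at \code{p < alpha} (default 0.01, no multiple-testing correction;
#' Benjamini-Hochberg available via \code{fdr = TRUE}).
#'
#' @param tab data.frame with at least \code{x1}, \code{x2}, \code{M},
#'   \code{A} (as built by \code{\link{run_ma_analysis}}, or by hand).
#' @param fit an \code{\link{fit_normalization}} result.
#' @param alpha significance threshold on the p-value.
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @param pseudocount the pseudocount used in \code{\link{ma_transform}},
#'   removed again when reconstructing normalized counts.
#' @return the table completed with \code{M_norm}, \code{x1_norm},
#'   \code{x2_norm}, \code{p_value}, \code{significant}; the fraction of
#'   significant regions in \code{attr(, "fraction_significant")}.
#' @export
normalize_and_test <- function(tab, fit, alpha = 0.01, fdr = FALSE,
                               pseudocount = 0.5) {
  stopifnot(inherits(fit, "ma_fit"),
            all(c("x1", "x2", "M", "A") %in% names(tab)))
  tab$M_norm <- tab$M - (fit$intercept + fit$slope * tab$A)
  # back-transform on the pseudocounted scale, then remove the pseudocount
  # so an identity normalization returns the raw counts exactly
  x1n <- pmax(0L, as.integer(round(2^(tab$A + tab$M_norm / 2) - pseudocount)))
  x2n <- pmax(0L, as.integer(round(2^(tab$A - tab$M_norm / 2) - pseudocount)))
  tab$x1_norm <- x1n
  tab$x2_norm <- x2n
  tab$p_value <- .binom_p(x1n, x1n + x2n)
  p_used <- if (fdr) stats::p.adjust(tab$p_value, "BH") else tab$p_value
  tab$significant <- p_used < alpha
  attr(tab, "fraction_significant") <- mean(tab$significant)
  tab
}

# summary band for the fraction of significantly different regions
ma_band <- function(frac) {
  if (frac > 0.5) "majority-differential"
  else if (frac < 0.25) "concordant"
  else "intermediate"
}

# fragment counts for a whole interval data.frame
.count_regions <- function(regions, f) {
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- regions$chrom == ch
    out[i] <- .count_in(f, ch, regions$start[i], regions$end[i])
  }
  as.integer(out)
}

#' MA-based differential-binding analysis between two replicates
#'
#' Builds the merged union of both replicates' peaks, counts shifted
#' fragments per region, MA-transforms, fits the robust normalization line
#' on regions detected in both replicates, tests every region, and reports
#' the fraction of significantly different regions together with the
#' summary band: more than 50\% significant is "majority-differential",
#' less than 25\% is "concordant", anything between is "intermediate".
#'
#' @param cond a two-replicate \code{chip_condition} (run pairs separately
#'   for larger conditions).
#' @param fsets named list of \code{\link{fragment_set}}s keyed by
#'   experiment id; both replicates must be present.
#' @param pseudocount MA pseudocount (default 0.5).
#' @param alpha significance threshold (default 0.01).
#' @param fdr apply Benjamini-Hochberg before thresholding.
#' @return object of class \code{ma_result}: \code{table} (regions with
#'   counts, M/A, normalized values, p-values), \code{fit},
#'   \code{fraction_significant}, \code{band}.
#' @export
run_ma_analysis <- function(cond, fsets, pseudocount = 0.5, alpha = 0.01,
                            fdr = FALSE) {
  stopifnot(inherits(cond, "chip_condition"))
  if (length(cond$experiments) != 2L)
    stop("run_ma_analysis() needs exactly 2 replicates; run pairs ",
         "separately for larger conditions")
  ids <- names(cond$experiments)
  f1 <- fsets[[ids[1L]]]; f2 <- fsets[[ids[2L]]]
  if (is.null(f1) || is.null(f2))
    stop("missing fragment data for condition ", cond$id)
  p1 <- cond$experiments[[1L]]$peaks
  p2 <- cond$experiments[[2L]]$peaks
  regions <- merge_regions(list(p1, p2))
  x1 <- .count_regions(regions, f1)
  x2 <- .count_regions(regions, f2)
  ma <- ma_transform(x1, x2, c = pseudocount)
  tab <- cbind(regions, data.frame(x1 = x1, x2 = x2, M = ma$M, A = ma$A))
  common <- .count_hits(regions, p1) > 0L & .count_hits(regions, p2) > 0L
  fit <- fit_normalization(tab$M[common], tab$A[common])
  tab <- normalize_and_test(tab, fit, alpha = alpha, fdr = fdr,
                            pseudocount = pseudocount)
  frac <- attr(tab, "fraction_significant")
  band <- ma_band(frac)
  structure(list(condition_id = cond$id, table = tab, fit = fit,
                 n_regions = nrow(tab), n_common = sum(common),
                 fraction_significant = frac, band = band),
            class = "ma_result")
}

#' @export
print.ma_result <- function(x, ...) {
  cat("MA differential binding,", x$condition_id, ":", x$n_regions,
      "union regions,", x$n_common, "common\n")
  print(x$fit)
  cat(sprintf("  fraction significant: %.3f (%s)\n",
              x$fraction_significant, x$band))
  invisible(x)
}
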