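#' Binary occupancy matrix over a merged region universe
#'
#' The universe is the merged union of all experiments' peaks; entry
#' (region, experiment) is 1 when the experiment has at least one peak
#' overlapping the region. Every row has at least one 1 by construction.
#'
#' @param experiments list of \code{chip_experiment} objects (>= 2).
#' @return object of class \code{occupancy_matrix}: \code{regions}
#'   (interval data.frame), \code{experiments} (ids), \code{values}
#'   (binary matrix regions x experiments).
#' @export
build_occupancy <- function(experiments) {
  stopifnot(length(experiments) >= 2L,
            all(vapply(experiments, inherits, logical(1),
                       "chip_experiment")))
  ids <- vapply(experiments, `[[`, character(1), "id")
  universe <- merge_regions(lapply(experiments, `[[`, "peaks"))
  values <- vapply(experiments, function(e)
    as.integer(.count_hits(universe, e$peaks) > 0L),
    integer(nrow(universe)))
  if (nrow(universe) == 1L) values <- matrix(values, nrow = 1L)
  colnames(values) <- ids
  structure(list(regions = universe, experiments = ids, values = values),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Occupancy matrix:", nrow(x$values), "regions x",
      ncol(x$values), "experiments ( fill",
      sprintf("%.1f%%", 100 * mean(x$values)), ")\n")
  invisible(x)
}

#' Pearson correlation between binary occupancy columns
#'
#' For binary columns this is the phi coefficient of the 2x2 overlap
#' table. Constant columns (all 0 or all 1) have undefined correlation and
#' yield \code{NA} with a warning.
#'
#' @param m an \code{\link{build_occupancy}} result, or a binary matrix
#'   with column names.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  values <- if (inherits(m, "occupancy_matrix")) m$values else m
  if (is.null(dim(values)) || ncol(values) < 2L)
    stop("correlation_matrix() needs >= 2 experiment columns")
  const <- apply(values, 2L, function(x) stats::var(x) == 0)
  if (any(const))
    warning("constant occupancy column(s): ",
            paste(colnames(values)[const], collapse = ", "),
            " (correlations set to NA)")
  r <- suppressWarnings(stats::cor(values))
  diag(r) <- 1
  r
}

#' Hierarchical clustering of experiments on 1 - r
#'
#' Agglomerative clustering with the distance \code{d = 1 - r} between
#' occupancy columns. Complete linkage by default; rows/columns are
#' ordered lexicographically by experiment id first so ties resolve
#' deterministically.
#'
#' @param corr correlation matrix from \code{\link{correlation_matrix}}.
#' @param method linkage: "complete" (default), "average" or "single".
#' @param strict error (rather than warn) on missing correlations.
#' @return object of class \code{occupancy_dendrogram} wrapping the
#'   \code{\link[stats]{hclust}} result (\code{$hclust}) with
#'   \code{$leaf_order} (labels in dendrogram order).
#' @export
hier_cluster <- function(corr, method = c("complete", "average", "single"),
                         strict = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (anyNA(corr)) {
    if (strict) stop("missing correlations; cannot cluster in strict mode")
    warning("missing correlations: experiments with NA dropped")
    keep <- rowSums(is.na(corr)) == 0
    corr <- corr[keep, keep, drop = FALSE]
  }
  ord <- order(colnames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - corr), method = method)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 method = method),
            class = "occupancy_dendrogram")
}

#' @export
print.occupancy_dendrogram <- function(x, ...) {
  cat("Occupancy dendrogram (", x$method, "linkage ):",
      length(x$leaf_order), "experiments\n")
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram as Newick with branch heights
#'
#' @param dend an \code{\link{hier_cluster}} result.
#' @param path output file path.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "occupancy_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Most-correlated experiments for a query experiment
#'
#' Ranks the other experiments by correlation with the query, ties broken
#' lexicographically by id. Used to arbitrate between dissimilar
#' replicates: the replicate whose occupancy clusters with biologically
#' related experiments is the better candidate.
#'
#' @param corr correlation matrix.
#' @param query experiment id present in the matrix.
#' @param k number of neighbors to return.
#' @return data.frame \code{experiment_id}, \code{r}, ranked; carries
#'   attribute \code{truncated = TRUE} when fewer than \code{k} neighbors
#'   exist.
#' @export
nearest_neighbors <- function(corr, query, k = 5L) {
  if (!query %in% colnames(corr)) stop("unknown experiment id: ", query)
  r <- corr[query, colnames(corr) != query]
  ord <- order(-r, names(r))
  out <- data.frame(experiment_id = names(r)[ord], r = unname(r[ord]),
                    stringsAsFactors = FALSE)
  truncated <- k > nrow(out)
  out <- utils::head(out, k)
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}
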