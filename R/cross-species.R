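#' Collapse a matrix onto the target gene space via 1:1 homologs
#'
#' Only strict one-to-one pairs are kept — source and target identifiers
#' that each appear exactly once in the map — and the retained genes are
#' renamed to their target identifiers. Many-to-one and one-to-many entries
#' are dropped, with the count reported in a message.
#'
#' @param m An [expr_matrix] in the source gene space.
#' @param homologs A data frame with columns `source`, `target`.
#' @return An [expr_matrix] on target identifiers (same scale as `m`).
#' @export
collapse_homologs <- function(m, homologs) {
  stopifnot(inherits(m, "expr_matrix"))
  homologs <- tibble::as_tibble(homologs)
  stopifnot(all(c("source", "target") %in% names(homologs)))
  homologs <- dplyr::distinct(homologs)
  keep <- !(homologs$source %in% homologs$source[duplicated(homologs$source)]) &
    !(homologs$target %in% homologs$target[duplicated(homologs$target)])
  n_drop <- sum(!keep)
  pairs <- homologs[keep, ]
  pairs <- pairs[pairs$source %in% rownames(m), ]
  if (!nrow(pairs)) {
    stop("no 1:1 homolog pairs overlap the matrix gene space", call. = FALSE)
  }
  if (n_drop) message(n_drop, " non-1:1 homolog pair(s) dropped")
  out <- unclass(m)[pairs$source, , drop = FALSE]
  rownames(out) <- pairs$target
  expr_matrix(out, expr_scale(m))
}

#' Concatenate cohorts after per-cohort gene-wise median centring
#'
#' A light-weight batch adjustment for cohort-constant offsets: within each
#' cohort every gene is centred on its cohort median, then the cohorts are
#' concatenated. Afterwards every gene's within-cohort median is exactly 0,
#' so any shift that is constant across a cohort's samples is gone. (This
#' removes only cohort-constant structure; it is not a surrogate-variable
#' method.)
#'
#' @param cohorts Named list of log2-scale [expr_matrix] objects on the
#'   identical gene space (same identifiers, same order not required).
#' @return A list: `expr` (combined log2 [expr_matrix]) and `cohort`
#'   (tibble mapping `sample` to cohort name).
#' @export
adjust_batches <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            !is.null(names(cohorts)), all(nzchar(names(cohorts))))
  genes <- rownames(cohorts[[1]])
  for (nm in names(cohorts)) {
    assert_scale(cohorts[[nm]], "log2", nm)
    miss <- union(setdiff(genes, rownames(cohorts[[nm]])),
                  setdiff(rownames(cohorts[[nm]]), genes))
    if (length(miss)) {
      stop("gene space mismatch in cohort ", nm, "; differing gene(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  centred <- lapply(cohorts, function(co) {
    unclass(median_center_genes(co[genes, , drop = FALSE]))
  })
  combined <- do.call(cbind, centred)
  check_unique_ids(colnames(combined), "sample")
  list(expr = expr_matrix(combined, "log2"),
       cohort = tibble::tibble(
         sample = unlist(lapply(centred, colnames), use.names = FALSE),
         cohort = rep(names(cohorts), vapply(centred, ncol, 0L))))
}

#' Median centroid of a sample cohort
#'
#' Per-gene median expression across the cohort's samples (midpoint
#' convention for even cohort sizes) — the cohort's transcriptome
#' representative for correlation comparisons.
#'
#' @param m An [expr_matrix].
#' @param cohort_samples Sample identifiers forming the cohort (non-empty).
#' @param label Optional cohort label attached to the result.
#' @return A named numeric vector (genes), with attributes `label`.
#' @export
centroid <- function(m, cohort_samples, label = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!length(cohort_samples)) stop("empty cohort", call. = FALSE)
  assert_samples(m, cohort_samples)
  v <- apply(unclass(m)[, cohort_samples, drop = FALSE], 1, stats::median)
  attr(v, "label") <- label
  v
}

#' Pearson correlations between two lists of centroids
#'
#' @param a,b Named lists of centroids (see [centroid()]) on the identical
#'   gene space. With `b` missing, `a` is correlated against itself.
#' @return A correlation matrix (rows `a`, columns `b`).
#' @export
centroid_correlations <- function(a, b = a) {
  stopifnot(is.list(a), is.list(b), !is.null(names(a)), !is.null(names(b)))
  genes <- names(a[[1]])
  all_cent <- c(a, b)
  for (i in seq_along(all_cent)) {
    if (!identical(names(all_cent[[i]]), genes)) {
      stop("centroids are not on the identical gene space", call. = FALSE)
    }
  }
  zerovar <- vapply(all_cent, function(v) stats::sd(v) == 0, TRUE)
  if (any(zerovar)) {
    stop("zero-variance centroid(s): ",
         paste(names(all_cent)[zerovar], collapse = ", "), call. = FALSE)
  }
  out <- stats::cor(do.call(cbind, a), do.call(cbind, b), method = "pearson")
  dimnames(out) <- list(names(a), names(b))
  out
}

#' Assign samples to the nearest centroid by Pearson correlation
#'
#' @param m An [expr_matrix].
#' @param centroids Named list of centroids on `m`'s gene space.
#' @return A tibble: `sample`, `assigned` (centroid name), `correlation`.
#' @export
nearest_centroid <- function(m, centroids) {
  stopifnot(inherits(m, "expr_matrix"), is.list(centroids),
            !is.null(names(centroids)))
  genes <- names(centroids[[1]])
  cors <- stats::cor(unclass(m)[genes, , drop = FALSE],
                     do.call(cbind, centroids), method = "pearson")
  best <- max.col(cors, ties.method = "first")
  tibble::tibble(sample = colnames(m),
                 assigned = names(centroids)[best],
                 correlation = cors[cbind(seq_len(nrow(cors)), best)])
}

#' Centred average-linkage co-clustering of samples
#'
#' Distance between samples is 1 minus the Pearson correlation of their
#' mean-centred profiles over the most variable genes; samples are then
#' agglomerated by average linkage and the tree cut at a requested cluster
#' count.
#'
#' @param m An [expr_matrix] with at least 2 samples.
#' @param gene_filter_fraction Fraction of most-variable genes to use, in
#'   (0, 1] (default 1, i.e. all genes).
#' @param k Number of flat clusters to cut (default 2).
#' @return A list: `hclust` (the dendrogram), `labels` (named integer
#'   cluster memberships), `genes_used`.
#' @export
average_linkage_cluster <- function(m, gene_filter_fraction = 1, k = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  genes <- top_variable_genes(m, gene_filter_fraction)
  x <- unclass(m)[genes, , drop = FALSE]
  # Pearson is the centred correlation (each profile centred on its mean)
  d <- stats::as.dist(1 - stats::cor(x, method = "pearson"))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = k), genes_used = genes)
}
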