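#' Upper-quartile normalization of a count matrix
#'
#' Scales each sample so its 75th percentile of nonzero counts equals the
#' across-sample mean of those percentiles. Within-sample gene ordering is
#' unchanged; applying the operation twice equals applying it once.
#'
#' @param m A counts-scale [expr_matrix]; every sample needs at least one
#'   nonzero count.
#' @return A counts-scale [expr_matrix] of the same shape.
#' @export
upper_quartile_normalize <- function(m) {
  assert_scale(m, "counts")
  uq <- apply(unclass(m), 2, function(x) {
    x <- x[x > 0]
    if (!length(x)) return(NA_real_)
    stats::quantile(x, 0.75, names = FALSE)
  })
  bad <- names(uq)[is.na(uq)]
  if (length(bad)) {
    stop("all-zero sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(unclass(m), 2, mean(uq) / uq, `*`)
  expr_matrix(scaled, "counts")
}

#' Log2 transform with a pseudocount
#'
#' @param m A counts-scale [expr_matrix].
#' @param pseudocount Positive offset added before taking log2 (default 1).
#' @return A log2-scale [expr_matrix].
#' @export
log2_with_pseudocount <- function(m, pseudocount = 1) {
  assert_scale(m, "counts")
  stopifnot(pseudocount > 0)
  expr_matrix(log2(unclass(m) + pseudocount), "log2")
}

#' Median-centre each gene across samples
#'
#' After centring, every gene's across-sample median is exactly 0 (midpoint
#' convention for even sample counts). Idempotent.
#'
#' @param m A log2-scale [expr_matrix].
#' @return A log2-scale [expr_matrix].
#' @export
median_center_genes <- function(m) {
  assert_scale(m, "log2")
  med <- apply(unclass(m), 1, stats::median)
  expr_matrix(unclass(m) - med, "log2")
}

#' Per-gene Welch two-sample t-statistics
#'
#' Unequal-variance (Welch) t per gene with group 2 minus group 1 in the
#' numerator, plus Welch-Satterthwaite degrees of freedom and a two-sided
#' p-value. Degenerate genes follow a fixed convention: zero variance in
#' both groups with equal means gives t = 0 (p = 1); zero variance with
#' unequal means gives t = +/-Inf (p = 0), signed by the mean difference.
#'
#' @param m A log2-scale [expr_matrix].
#' @param group1,group2 Disjoint sample-identifier vectors, each of size
#'   >= 2.
#' @return A tibble: `gene`, `mean1`, `mean2`, `log2fc` (mean2 - mean1),
#'   `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(m, group1, group2) {
  assert_scale(m, "log2")
  assert_samples(m, c(group1, group2))
  if (length(intersect(group1, group2))) {
    stop("groups overlap: ", paste(intersect(group1, group2), collapse = ", "),
         call. = FALSE)
  }
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples", call. = FALSE)
  x1 <- unclass(m)[, group1, drop = FALSE]
  x2 <- unclass(m)[, group2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m2 - m1
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              0)
  p[t == 0 & se2 == 0] <- 1
  tibble::tibble(gene = rownames(m), mean1 = unname(m1), mean2 = unname(m2),
                 log2fc = unname(diff), statistic = unname(t),
                 df = unname(df), p_value = unname(p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving with the input; each adjusted value lies in `[0, 1]` and
#' is never smaller than its raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes by fold change and FDR
#'
#' The published filter: a gene is `up` when its log2 fold change exceeds
#' `log2(fc_threshold)` and its BH-adjusted Welch p-value falls below `fdr`;
#' `down` symmetrically; `none` otherwise. Run on log2 values (typically
#' upper-quartile-normalized counts after [log2_with_pseudocount()]).
#'
#' @param m A log2-scale [expr_matrix].
#' @param group1,group2 Sample-identifier vectors (see [welch_t()]).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2, i.e. |log2fc| > 1).
#' @param fdr FDR level for the adjusted p-value (default 0.05).
#' @return A `de_result` tibble: [welch_t()] columns plus `q_value` and
#'   `call` in `{"up", "down", "none"}`.
#' @export
call_de <- function(m, group1, group2, fc_threshold = 2, fdr = 0.05) {
  stopifnot(fc_threshold > 1, fdr > 0, fdr < 1)
  res <- welch_t(m, group1, group2)
  lfc_min <- log2(fc_threshold)
  res <- dplyr::mutate(
    res,
    q_value = bh_adjust(.data$p_value),
    call = dplyr::case_when(
      .data$log2fc > lfc_min & .data$q_value < fdr ~ "up",
      .data$log2fc < -lfc_min & .data$q_value < fdr ~ "down",
      TRUE ~ "none"))
  class(res) <- c("de_result", class(res))
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "fdr") <- fdr
  res
}

#' Venn counts between two up/down gene-list pairs
#'
#' Tabulates shared and exclusive genes between two differential-expression
#' outcomes, separately for up- and down-regulated lists.
#'
#' @param a_up,a_down,b_up,b_down Character gene vectors; a gene may not sit
#'   in both the up and down list of the same outcome.
#' @return A tibble: `direction`, `both`, `a_only`, `b_only`.
#' @export
overlap_counts <- function(a_up, a_down, b_up, b_down) {
  if (length(intersect(a_up, a_down))) {
    stop("gene(s) in both up and down lists of A: ",
         paste(utils::head(intersect(a_up, a_down), 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(b_up, b_down))) {
    stop("gene(s) in both up and down lists of B: ",
         paste(utils::head(intersect(b_up, b_down), 5), collapse = ", "),
         call. = FALSE)
  }
  one <- function(direction, a, b) {
    a <- unique(a); b <- unique(b)
    tibble::tibble(direction = direction,
                   both = length(intersect(a, b)),
                   a_only = length(setdiff(a, b)),
                   b_only = length(setdiff(b, a)))
  }
  dplyr::bind_rows(one("up", a_up, b_up), one("down", a_down, b_down))
}

#' Most variable genes of a matrix
#'
#' Genes ranked by across-sample variance; the top `ceiling(fraction * N)`
#' are returned. Ties are broken by gene identifier so the selection is
#' deterministic.
#'
#' @param m An [expr_matrix].
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return Character vector of gene identifiers, highest variance first.
#' @export
top_variable_genes <- function(m, fraction = 0.1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m) == 0) stop("empty matrix", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  v <- apply(unclass(m), 1, stats::var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(ceiling(fraction * nrow(m)))]
}
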