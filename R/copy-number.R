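#' Mean gene-level copy number by genomic position
#'
#' Arithmetic mean of the segmented copy values across samples for each
#' gene, ordered by (chromosome, start) so the result can be plotted along
#' the genome. Genes whose values are missing in every sample are excluded
#' with a warning.
#'
#' @param cn A copy-number tibble (see [read_copy_number_tsv()]).
#' @return A tibble: `gene`, `chrom`, `start`, `end`, `mean_cn`, sorted by
#'   genomic position.
#' @export
mean_gene_cn <- function(cn) {
  cn <- validate_copy_number(cn)
  samples <- cn_sample_cols(cn)
  if (!length(samples)) stop("copy-number table has no sample columns", call. = FALSE)
  vals <- as.matrix(cn[samples])
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " gene(s) with all-missing values excluded",
            call. = FALSE)
  }
  out <- tibble::tibble(gene = cn$gene, chrom = cn$chrom, start = cn$start,
                        end = cn$end,
                        mean_cn = rowMeans(vals, na.rm = TRUE))[!all_na, ]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Minimal common region of copy-number gain or loss
#'
#' A sample is altered when some gene exceeds `threshold` in the stated
#' direction. For each altered sample, the altered run is the maximal block
#' of consecutive genes (genome order) beyond threshold that contains the
#' cohort peak gene — the gene with the most extreme cohort mean — so
#' multi-peak chromosomes do not conflate regions. The minimal common
#' region is the intersection of those runs; its genes are the candidate
#' drivers. An empty intersection is reported as such, with the per-sample
#' runs as diagnostics.
#'
#' @param cn A copy-number tibble; all genes on one chromosome arm of
#'   interest (rows on other chromosomes are used only for sorting).
#' @param direction `"gain"` (values above threshold) or `"loss"` (below).
#' @param threshold Copy-value threshold on the segmented scale; default
#'   2 + 0.3 for gain, 2 - 0.3 for loss.
#' @return An `mcr_result` list: `genes` (character, possibly empty),
#'   `interval` (first/last gene index in genome order, or `NULL`),
#'   `altered_samples`, `runs` (tibble of per-sample run bounds), `peak_gene`.
#' @export
minimal_common_region <- function(cn, direction = c("gain", "loss"),
                                  threshold = NULL) {
  direction <- match.arg(direction)
  cn <- validate_copy_number(cn)
  if (is.null(threshold)) threshold <- if (direction == "gain") 2.3 else 1.7
  samples <- cn_sample_cols(cn)
  cn <- dplyr::arrange(cn, .data$chrom, .data$start)
  vals <- as.matrix(cn[samples])
  beyond <- if (direction == "gain") vals > threshold else vals < threshold
  altered <- colSums(beyond, na.rm = TRUE) > 0
  if (!any(altered)) {
    stop("no altered samples at threshold ", threshold, " (", direction, ")",
         call. = FALSE)
  }
  means <- rowMeans(vals, na.rm = TRUE)
  peak <- if (direction == "gain") which.max(means) else which.min(means)
  runs <- purrr::map_dfr(samples[altered], function(s) {
    b <- beyond[, s] & !is.na(beyond[, s])
    if (!b[peak]) {
      return(tibble::tibble(sample = s, run_start = NA_integer_,
                            run_end = NA_integer_))
    }
    lo <- as.integer(peak)
    while (lo > 1L && b[lo - 1L]) lo <- lo - 1L
    hi <- as.integer(peak)
    while (hi < length(b) && b[hi + 1L]) hi <- hi + 1L
    tibble::tibble(sample = s, run_start = lo, run_end = hi)
  })
  usable <- !is.na(runs$run_start)
  if (!any(usable)) {
    interval <- NULL
  } else {
    lo <- max(runs$run_start[usable])
    hi <- min(runs$run_end[usable])
    interval <- if (lo <= hi && all(usable)) as.integer(c(lo, hi)) else NULL
  }
  structure(list(
    genes = if (is.null(interval)) character() else cn$gene[interval[1]:interval[2]],
    interval = interval,
    altered_samples = samples[altered],
    runs = runs,
    peak_gene = cn$gene[peak],
    direction = direction, threshold = threshold),
    class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<mcr_result> %s, threshold %.3g: %d altered sample(s)\n",
              x$direction, x$threshold, length(x$altered_samples)))
  if (length(x$genes)) {
    cat(sprintf("MCR: %d gene(s), %s .. %s (peak %s)\n", length(x$genes),
                x$genes[1], x$genes[length(x$genes)], x$peak_gene))
  } else {
    cat("MCR empty: altered runs do not all overlap the peak; see $runs\n")
  }
  invisible(x)
}

#' Percentile rank of a gene's mean copy number within a region
#'
#' The fraction of the other region genes whose mean copy value lies
#' strictly below the query's — the sense in which a driver's mean copy
#' number can exceed, say, 70% of the region's gene-level means.
#'
#' @param region_means A data frame with columns `gene` and `mean_cn`
#'   (e.g. [mean_gene_cn()] restricted to an MCR); at least 2 genes.
#' @param query Gene identifier inside the region.
#' @return Numeric fraction in `[0, 1]`.
#' @export
percentile_rank <- function(region_means, query) {
  region_means <- tibble::as_tibble(region_means)
  stopifnot(all(c("gene", "mean_cn") %in% names(region_means)))
  if (nrow(region_means) < 2) stop("region must contain >= 2 genes", call. = FALSE)
  idx <- match(query, region_means$gene)
  if (is.na(idx)) stop("query gene not in region: ", query, call. = FALSE)
  q <- region_means$mean_cn[idx]
  others <- region_means$mean_cn[-idx]
  mean(others < q)
}
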