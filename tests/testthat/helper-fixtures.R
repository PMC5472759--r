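# Shared fixture builders; everything is generated in code at test time.

toy_expr <- function(values, scale = "log2", genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, scale, gene_ids = genes, sample_ids = samples)
}

random_counts <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  toy_expr(matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples),
           scale = "counts")
}

# Brute-force B-H step-up: sort, q_(i) = min_{j >= i} m p_(j) / j, unsort.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# Brute-force partial AUC: literal walk of the top-k positions.
pauc_bruteforce <- function(member_logical, fraction) {
  n <- length(member_logical)
  k <- ceiling(fraction * n)
  m <- sum(member_logical)
  seen <- 0
  total <- 0
  for (j in seq_len(k)) {
    if (member_logical[j]) seen <- seen + 1
    total <- total + seen / m
  }
  total / k
}

# A ranked list over n genes with the given member ranks flagged.
ranked_fixture <- function(n, member_ranks) {
  genes <- sprintf("g%05d", seq_len(n))
  ranked <- rank_by_t(stats::setNames(rev(seq_len(n)), genes))
  list(ranked = ranked, members = ranked$gene[member_ranks])
}
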