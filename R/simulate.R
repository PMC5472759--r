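#' Simulation settings for synthetic cohorts
#'
#' Bundles the knobs shared by all generators. Defaults describe the cohort
#' sizes and effect sizes the package's own validation experiments use:
#' 5,000 genes, 10 samples per group, one 100-gene signal set shifted by one
#' within-gene standard deviation, negative-binomial counts of moderate
#' overdispersion, 30% censoring, and genotype hazard ratios of 1/2/3 for
#' V/VM/VIM.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples per group (or per cohort cell).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); must be positive.
#' @param base_mean Baseline mean count per gene.
#' @param effect_log2fc Log2 shift applied to signal genes in group 2. For
#'   the Gaussian log2-scale generators this equals the shift in
#'   standard-deviation units when `noise_sd = 1`.
#' @param signal_set_size Number of genes in the planted signal set.
#' @param noise_sd Within-group standard deviation on the log2 scale used by
#'   the Gaussian generators.
#' @param censor_rate Target fraction of censored records in `[0, 1]`.
#' @param hazard_ratios Named positive vector: hazard ratio per genotype
#'   label (reference value 1).
#' @return A `simulation_spec` (validated list).
#' @export
simulation_spec <- function(n_genes = 5000, n_samples_per_group = 10,
                            seed = 1L, dispersion = 0.1, base_mean = 500,
                            effect_log2fc = 1, signal_set_size = 100,
                            noise_sd = 1, censor_rate = 0.3,
                            hazard_ratios = c(V = 1, VM = 2, VIM = 3)) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_group = as.integer(n_samples_per_group),
               seed = as.integer(seed), dispersion = dispersion,
               base_mean = base_mean, effect_log2fc = effect_log2fc,
               signal_set_size = as.integer(signal_set_size),
               noise_sd = noise_sd, censor_rate = censor_rate,
               hazard_ratios = hazard_ratios)
  with(spec, {
    stopifnot(n_genes >= 1, n_samples_per_group >= 1, signal_set_size >= 1,
              dispersion > 0, base_mean > 0, noise_sd > 0)
    if (censor_rate < 0 || censor_rate > 1) {
      stop("censor_rate must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(names(hazard_ratios)) || any(hazard_ratios <= 0)) {
      stop("hazard_ratios must be a named vector of positive values",
           call. = FALSE)
    }
  })
  structure(spec, class = "simulation_spec")
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

group_sample_ids <- function(n) {
  list(group1 = sprintf("g1_s%02d", seq_len(n)),
       group2 = sprintf("g2_s%02d", seq_len(n)))
}

#' Simulate a two-group RNA-seq count matrix with a planted signal set
#'
#' Emulates a two-condition culture experiment (e.g. cells grown with or
#' without an inducer): counts are negative-binomial around a common base
#' mean, each sample carries a log-normal library-size factor, and a chosen
#' set of signal genes has its group-2 mean multiplied by
#' `2^effect_log2fc`.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `expr` (counts-scale [expr_matrix]), `groups` (tibble of
#'   `sample`, `group`), `signal_genes` (character truth vector).
#' @export
simulate_two_group_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$signal_set_size > spec$n_genes) {
    stop("signal_set_size exceeds n_genes", call. = FALSE)
  }
  with_sim_seed(spec$seed, {
    genes <- sprintf("gene%05d", seq_len(spec$n_genes))
    ids <- group_sample_ids(spec$n_samples_per_group)
    samples <- c(ids$group1, ids$group2)
    signal <- sort(sample(genes, spec$signal_set_size))
    libsize <- stats::rlnorm(length(samples), meanlog = 0, sdlog = 0.2)
    mu <- matrix(spec$base_mean, spec$n_genes, length(samples),
                 dimnames = list(genes, samples))
    mu[signal, ids$group2] <- mu[signal, ids$group2] * 2^spec$effect_log2fc
    mu <- sweep(mu, 2, libsize, `*`)
    vals <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                   nrow = spec$n_genes, dimnames = dimnames(mu))
    list(expr = expr_matrix(vals, "counts"),
         groups = tibble::tibble(sample = samples,
                                 group = rep(c("group1", "group2"),
                                             each = spec$n_samples_per_group)),
         signal_genes = signal)
  })
}

#' Simulate a log2-scale cohort with one activated gene set
#'
#' Builds `collection_size` disjoint gene sets of `signal_set_size` genes
#' each; exactly one set is up-shifted by `effect_log2fc` (log2 units; equal
#' to standard-deviation units at the default `noise_sd = 1`) in group 2,
#' the rest are null. Per-gene baselines are drawn once and shared by both
#' groups, so all between-group signal sits in the activated set.
#'
#' @param spec A [simulation_spec()].
#' @param collection_size Number of sets (>= 2).
#' @return A list: `expr` (log2-scale [expr_matrix]), `groups`,
#'   `collection` (a `gene_set_collection`), `activated_set` (truth).
#' @export
simulate_gene_set_cohort <- function(spec, collection_size = 20) {
  stopifnot(inherits(spec, "simulation_spec"))
  collection_size <- as.integer(collection_size)
  if (collection_size < 2) stop("collection_size must be >= 2", call. = FALSE)
  if (collection_size * spec$signal_set_size > spec$n_genes) {
    stop("collection_size * signal_set_size exceeds n_genes", call. = FALSE)
  }
  with_sim_seed(spec$seed, {
    genes <- sprintf("gene%05d", seq_len(spec$n_genes))
    ids <- group_sample_ids(spec$n_samples_per_group)
    samples <- c(ids$group1, ids$group2)
    member_pool <- sample(genes, collection_size * spec$signal_set_size)
    sets <- split(member_pool,
                  rep(seq_len(collection_size), each = spec$signal_set_size))
    names(sets) <- sprintf("SET%02d", seq_len(collection_size))
    activated <- sample(names(sets), 1)
    base <- stats::rnorm(spec$n_genes, mean = log2(spec$base_mean + 1), sd = 2)
    vals <- base + matrix(stats::rnorm(spec$n_genes * length(samples),
                                       sd = spec$noise_sd),
                          spec$n_genes, length(samples),
                          dimnames = list(genes, samples))
    vals[sets[[activated]], ids$group2] <-
      vals[sets[[activated]], ids$group2] + spec$effect_log2fc
    list(expr = expr_matrix(vals, "log2"),
         groups = tibble::tibble(sample = samples,
                                 group = rep(c("group1", "group2"),
                                             each = spec$n_samples_per_group)),
         collection = gene_set_collection(sets),
         activated_set = activated)
  })
}

#' Simulate two species sharing latent subtype centroids
#'
#' Each latent gene has one subtype-specific centroid value shared by both
#' species; every sample is its subtype centroid plus Gaussian noise plus a
#' gene-wise species offset (constant across the species' samples, standard
#' deviation `batch_shift`) — the structure a cohort-constant batch
#' adjustment must remove. The homolog map covers `frac_one_to_one` of the
#' latent genes with clean 1:1 pairs; the remaining latent genes are covered
#' by two source genes each (many-to-one pairs a strict 1:1 filter drops).
#'
#' @param spec A [simulation_spec()]; `n_samples_per_group` samples are drawn
#'   per species x subtype cell.
#' @param n_subtypes Number of shared latent subtypes (>= 2).
#' @param batch_shift Standard deviation of the gene-wise species offset.
#' @param frac_one_to_one Fraction of latent genes with 1:1 homolog pairs,
#'   in (0, 1].
#' @param snr Signal-to-noise ratio: sd of centroid values over `noise_sd`.
#' @return A list: `source`, `target` (log2 [expr_matrix] objects),
#'   `homologs` (source/target tibble), `truth` (tibble of `sample`,
#'   `species`, `subtype`).
#' @export
simulate_cross_species <- function(spec, n_subtypes = 2, batch_shift = 2,
                                   frac_one_to_one = 0.8, snr = 3) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_subtypes <- as.integer(n_subtypes)
  if (n_subtypes < 2) stop("n_subtypes must be >= 2", call. = FALSE)
  if (frac_one_to_one <= 0 || frac_one_to_one > 1) {
    stop("frac_one_to_one must lie in (0, 1]", call. = FALSE)
  }
  with_sim_seed(spec$seed, {
    n <- spec$n_genes
    target_ids <- sprintf("HUM%05d", seq_len(n))
    n11 <- max(1L, round(frac_one_to_one * n))
    # latent genes 1..n11 are 1:1; each remaining latent gene has two
    # source genes mapping to the same target (dropped by a 1:1 filter)
    src_of_latent <- c(as.list(sprintf("mus%05d", seq_len(n11))),
                       lapply(seq_len(n - n11), function(i) {
                         sprintf("mus%05d%s", n11 + i, c("a", "b"))
                       }))
    source_ids <- unlist(src_of_latent)
    homologs <- tibble::tibble(
      source = source_ids,
      target = rep(target_ids, lengths(src_of_latent)))
    centroids <- matrix(stats::rnorm(n * n_subtypes, sd = snr * spec$noise_sd),
                        n, n_subtypes)
    per <- spec$n_samples_per_group
    make_cohort <- function(species, gene_ids, latent_of_gene) {
      offset <- stats::rnorm(n, sd = batch_shift)
      subtype <- rep(seq_len(n_subtypes), each = per)
      samples <- sprintf("%s_k%d_s%02d", species, subtype,
                         rep(seq_len(per), times = n_subtypes))
      vals <- centroids[latent_of_gene, subtype, drop = FALSE] +
        offset[latent_of_gene] +
        matrix(stats::rnorm(length(gene_ids) * length(samples),
                            sd = spec$noise_sd),
               length(gene_ids), length(samples))
      dimnames(vals) <- list(gene_ids, samples)
      list(expr = expr_matrix(vals, "log2"),
           truth = tibble::tibble(sample = samples, species = species,
                                  subtype = paste0("subtype", subtype)))
    }
    src <- make_cohort("mouse", source_ids,
                       rep(seq_len(n), lengths(src_of_latent)))
    tgt <- make_cohort("human", target_ids, seq_len(n))
    list(source = src$expr, target = tgt$expr, homologs = homologs,
         truth = dplyr::bind_rows(src$truth, tgt$truth))
  })
}

#' Simulate a gene-level copy-number cohort with a planted focal alteration
#'
#' Baseline segmented copy values are Normal(2, `baseline_sd`). Each altered
#' sample gains (or loses) a contiguous gene interval that strictly contains
#' the requested amplicon; the planted minimal common region is the
#' intersection of the sampled intervals. A designated driver gene receives
#' an extra copy change in `driver_frac` of the altered samples.
#'
#' @param spec A [simulation_spec()]; `n_genes` genes on one chromosome,
#'   `n_samples_per_group` altered and as many unaltered samples.
#' @param amplicon Integer gene-index interval `c(first, last)` that every
#'   sampled alteration must strictly contain.
#' @param driver Gene index of the driver (must lie inside `amplicon`).
#' @param direction `"gain"` or `"loss"`.
#' @param delta Magnitude of the planted copy change (default 1).
#' @param driver_frac Fraction of altered samples with the extra driver
#'   change (default 1).
#' @param driver_delta Extra copy change on the driver gene (default 0.5).
#' @param baseline_sd Baseline noise standard deviation (default 0.05;
#'   segmented values scatter tightly around segment means).
#' @param max_pad Largest random extension of an altered interval beyond the
#'   amplicon on each side (default 10 genes).
#' @param n_altered Number of altered samples (default
#'   `spec$n_samples_per_group`; 0 gives a baseline-only cohort with a
#'   `NULL` truth interval).
#' @return A list: `cn` (copy-number tibble), `truth` (list with `interval`,
#'   `genes`, `driver`, `altered_samples`, `direction`).
#' @export
simulate_copy_number <- function(spec, amplicon, driver,
                                 direction = c("gain", "loss"), delta = 1,
                                 driver_frac = 1, driver_delta = 0.5,
                                 baseline_sd = 0.05, max_pad = 10,
                                 n_altered = spec$n_samples_per_group) {
  stopifnot(inherits(spec, "simulation_spec"))
  direction <- match.arg(direction)
  n <- spec$n_genes
  amplicon <- as.integer(amplicon)
  if (length(amplicon) != 2 || amplicon[1] > amplicon[2] ||
      amplicon[1] <= 1 || amplicon[2] >= n) {
    stop("amplicon must lie strictly inside the gene range", call. = FALSE)
  }
  driver <- as.integer(driver)
  if (driver < amplicon[1] || driver > amplicon[2]) {
    stop("driver must lie inside the amplicon", call. = FALSE)
  }
  sgn <- if (direction == "gain") 1 else -1
  n_altered <- as.integer(n_altered)
  stopifnot(n_altered >= 0)
  with_sim_seed(spec$seed, {
    genes <- sprintf("cngene%04d", seq_len(n))
    n_alt <- n_altered
    samples <- c(sprintf("alt_s%02d", seq_len(n_alt)),
                 sprintf("wt_s%02d", seq_len(spec$n_samples_per_group)))
    vals <- matrix(stats::rnorm(n * length(samples), mean = 2,
                                sd = baseline_sd),
                   n, length(samples), dimnames = list(genes, samples))
    if (n_alt > 0) {
      pad_left <- sample(seq_len(min(max_pad, amplicon[1] - 1L)), n_alt,
                         replace = TRUE)
      pad_right <- sample(seq_len(min(max_pad, n - amplicon[2])), n_alt,
                          replace = TRUE)
      for (i in seq_len(n_alt)) {
        run <- (amplicon[1] - pad_left[i]):(amplicon[2] + pad_right[i])
        vals[run, i] <- vals[run, i] + sgn * delta
      }
      n_driver <- round(driver_frac * n_alt)
      if (n_driver > 0) {
        vals[driver, seq_len(n_driver)] <-
          vals[driver, seq_len(n_driver)] + sgn * driver_delta
      }
      interval <- c(amplicon[1] - min(pad_left), amplicon[2] + min(pad_right))
    } else {
      interval <- NULL
    }
    cn <- tibble::tibble(gene = genes, chrom = "chr8",
                         start = (seq_len(n) - 1L) * 100000L + 1L,
                         end = seq_len(n) * 100000L)
    cn <- dplyr::bind_cols(cn, tibble::as_tibble(vals))
    list(cn = cn,
         truth = list(interval = interval,
                      genes = if (is.null(interval)) character()
                              else genes[interval[1]:interval[2]],
                      driver = genes[driver],
                      altered_samples = if (n_alt > 0) samples[seq_len(n_alt)]
                                        else character(),
                      direction = direction))
  })
}

#' Simulate genotype-stratified survival records
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_ratios[genotype]`; censoring times are independent exponentials
#' with rate tuned so the expected censored fraction matches `censor_rate`.
#' Stage and grade are drawn with means that increase with the genotype's
#' hazard ratio, so covariate adjustment has something to adjust for.
#'
#' @param spec A [simulation_spec()]; `hazard_ratios` must cover every label
#'   in `genotypes`.
#' @param genotypes Character vector, one genotype label per subject.
#' @param baseline_hazard Events per day for a hazard-ratio-1 subject.
#' @return A clinical tibble: `sample`, `genotype`, `time` (days), `event`,
#'   `stage`, `grade`.
#' @export
simulate_survival <- function(spec, genotypes, baseline_hazard = 0.001) {
  stopifnot(inherits(spec, "simulation_spec"))
  genotypes <- as.character(genotypes)
  missing <- setdiff(unique(genotypes), names(spec$hazard_ratios))
  if (length(missing)) {
    stop("no hazard ratio for genotype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with_sim_seed(spec$seed, {
    n <- length(genotypes)
    hr <- spec$hazard_ratios[genotypes]
    hazard <- baseline_hazard * hr
    t_event <- stats::rexp(n, rate = hazard)
    if (spec$censor_rate > 0) {
      cens_rate <- spec$censor_rate / (1 - spec$censor_rate) * mean(hazard)
      t_cens <- stats::rexp(n, rate = cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    severity <- log(hr) # 0 at reference, grows with hazard
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    tibble::tibble(
      sample = sprintf("pt%04d", seq_len(n)),
      genotype = genotypes,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stage = clamp(round(stats::rnorm(n, mean = 2 + severity, sd = 1)), 1, 4),
      grade = clamp(round(stats::rnorm(n, mean = 2 + 0.5 * severity, sd = 1)),
                    1, 4))
  })
}
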