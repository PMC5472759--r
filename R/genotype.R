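#' Classify samples into V / VM / VIM genotype strata
#'
#' From three per-sample alteration flags: `V` is VHL inactivation alone,
#' `VM` adds MYC activation, `VIM` adds CDKN2A deletion on top of both.
#' Every other combination — including VHL-intact samples and the
#' VHL + CDKN2A without MYC case, which the stratification never assigns —
#' is `other`. The labels partition the cohort.
#'
#' @param profiles A data frame with columns `sample`, `vhl_inactivated`,
#'   `myc_activated`, `cdkn2a_deleted`; flags must be non-missing logicals
#'   (or 0/1).
#' @return A tibble: `sample`, `genotype` (factor with levels V, VM, VIM,
#'   other).
#' @export
classify_genotype <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  need <- c("sample", "vhl_inactivated", "myc_activated", "cdkn2a_deleted")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    stop("profiles missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  flags <- profiles[c("vhl_inactivated", "myc_activated", "cdkn2a_deleted")]
  for (nm in names(flags)) {
    f <- flags[[nm]]
    if (anyNA(f) || !all(f %in% c(0, 1))) {
      stop("`", nm, "` must be non-missing 0/1 or logical; resolve unknowns ",
           "upstream or drop the sample", call. = FALSE)
    }
    flags[[nm]] <- as.logical(f)
  }
  v <- flags$vhl_inactivated; m <- flags$myc_activated; i <- flags$cdkn2a_deleted
  label <- dplyr::case_when(
    v & m & i ~ "VIM",
    v & m & !i ~ "VM",
    v & !m & !i ~ "V",
    TRUE ~ "other")
  tibble::tibble(sample = as.character(profiles$sample),
                 genotype = factor(label, levels = c("V", "VM", "VIM", "other")))
}

#' Frequency of an alteration (or genotype) by TNM stage
#'
#' For each stage present, the fraction of samples carrying the flag,
#' reported with the underlying counts. Samples with missing stage are
#' excluded with a warning; stages with no samples are simply absent.
#'
#' @param clinical A data frame with columns `sample` and `stage`
#'   (ordinal 1-4, `NA` allowed).
#' @param flags A data frame with columns `sample` and the logical/0-1
#'   column named by `flag` (for genotype frequencies, pass the output of
#'   [classify_genotype()] mutated to an indicator).
#' @param flag Name of the flag column in `flags`.
#' @return A tibble: `stage`, `n`, `n_flag`, `frequency`.
#' @export
frequency_by_stage <- function(clinical, flags, flag) {
  clinical <- tibble::as_tibble(clinical)
  flags <- tibble::as_tibble(flags)
  stopifnot(all(c("sample", "stage") %in% names(clinical)),
            "sample" %in% names(flags))
  if (!flag %in% names(flags)) {
    stop("flag column not found: ", flag, call. = FALSE)
  }
  df <- dplyr::inner_join(clinical[c("sample", "stage")],
                          flags[c("sample", flag)], by = "sample")
  if (!nrow(df)) stop("empty cohort", call. = FALSE)
  n_missing <- sum(is.na(df$stage))
  if (n_missing) {
    warning(n_missing, " sample(s) without stage excluded", call. = FALSE)
    df <- df[!is.na(df$stage), ]
  }
  if (!nrow(df)) stop("no samples with a recorded stage", call. = FALSE)
  f <- df[[flag]]
  if (anyNA(f) || !all(f %in% c(0, 1))) {
    stop("`", flag, "` must be non-missing 0/1 or logical", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(df, stage = .data$stage),
                   n = dplyr::n(),
                   n_flag = sum(as.logical(.data[[flag]])),
                   frequency = .data$n_flag / .data$n,
                   .groups = "drop")
}

#' Chi-square enrichment test on a 2 x k contingency table
#'
#' Pearson chi-square without continuity correction, df = k - 1; the test
#' used for stage/metastasis enrichment of genotype strata.
#'
#' @param counts A 2 x k numeric matrix of counts; every expected cell
#'   count must be positive.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
chisq_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2) {
    stop("counts must be a 2 x k table with k >= 2", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("zero expected cell count; merge sparse categories first",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
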