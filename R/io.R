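#' Read and write gene-by-sample expression tables
#'
#' Tab-separated text with a header row of sample identifiers and gene
#' identifiers in the first column is the canonical expression dialect here
#' (the flat-file convention of the large public tumour compendia). Row and
#' column order are preserved; identifier collisions and non-numeric cells
#' are rejected, never repaired.
#'
#' @param path Path to a tab-separated file.
#' @param scale Value scale of the body: `"counts"` or `"log2"`.
#' @return [read_expression_tsv()] returns an [expr_matrix];
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  raw <- read_tsv_strict(path, min_fields = 2)
  header <- raw[[1]]
  body <- raw[-1]
  gene_ids <- vapply(body, `[[`, "", 1L)
  sample_ids <- header[-1]
  n <- length(sample_ids)
  vals <- matrix(NA_real_, length(body), n)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n + 1L) {
      stop(sprintf("%s: line %d has %d fields, expected %d", basename(path),
                   i + 1L, length(row), n + 1L), call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(x) & row[-1] != "NA")
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' at row %d (gene %s), column %d (sample %s)",
                   basename(path), row[-1][bad[1]], i, gene_ids[i], bad[1],
                   sample_ids[bad[1]]), call. = FALSE)
    }
    vals[i, ] <- x
  }
  expr_matrix(vals, scale, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' @rdname read_expression_tsv
#' @param m An [expr_matrix].
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then one or more gene identifiers,
#' tab-separated (the MSigDB container format). Genes repeated within a line
#' are deduplicated with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of unique gene-identifier
#'   vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_strict(path, min_fields = 0)
  sets <- vector("list", length(lines))
  names(sets) <- rep("", length(lines))
  descriptions <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- lines[[i]]
    if (length(f) < 3L) {
      stop(sprintf("%s: line %d has %d fields; a GMT line needs a name, a description and at least one gene",
                   basename(path), i, length(f)), call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set %s: %d duplicated gene id(s) collapsed", f[1],
                      sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    names(sets)[i] <- f[1]
    descriptions[i] <- f[2]
    sets[[i]] <- genes
  }
  check_unique_ids(names(sets), "set")
  gene_set_collection(sets, descriptions)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (unique, non-empty).
#' @param descriptions Optional character vector of set descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = rep("", length(sets))) {
  stopifnot(is.list(sets), length(descriptions) == length(sets))
  check_unique_ids(names(sets), "set")
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) stop("set ", nm, " is empty", call. = FALSE)
    if (anyDuplicated(sets[[nm]])) {
      stop("set ", nm, " contains duplicate genes", call. = FALSE)
    }
  }
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a mouse-to-human homolog map
#'
#' Two tab-separated columns: source (e.g. mouse) and target (e.g. human)
#' gene identifiers. Duplicate pairs are collapsed with a warning. Whether
#' the first line is a header is decided by the `header` flag, never
#' guessed.
#'
#' @param path Path to the two-column file.
#' @param header Does the file start with a header line?
#' @return A tibble with columns `source` and `target` (a homolog map).
#' @export
read_homolog_map <- function(path, header = FALSE) {
  rows <- read_tsv_strict(path, min_fields = 0)
  if (header && length(rows)) rows <- rows[-1]
  if (!length(rows)) {
    warning("empty homolog map: ", basename(path), call. = FALSE)
    return(tibble::tibble(source = character(), target = character()))
  }
  nf <- lengths(rows)
  if (any(nf != 2L)) {
    stop(sprintf("%s: line %d has %d fields, expected 2", basename(path),
                 which(nf != 2L)[1] + header, nf[nf != 2L][1]), call. = FALSE)
  }
  map <- tibble::tibble(source = vapply(rows, `[[`, "", 1L),
                        target = vapply(rows, `[[`, "", 2L))
  ndup <- sum(duplicated(map))
  if (ndup) {
    warning(ndup, " duplicated homolog pair(s) collapsed", call. = FALSE)
    map <- dplyr::distinct(map)
  }
  map
}

#' Read a per-sample clinical table
#'
#' Tab-separated with a header; one row per sample. Recognised columns:
#' `sample`, `time` (days, positive), `event` (1 = death observed,
#' 0 = censored), `stage` (ordinal 1-4 or the literal `NA`), `grade`
#' (ordinal or `NA`), plus any logical alteration-flag columns (values
#' 0/1/TRUE/FALSE). `NA` is the single missing-value sentinel.
#'
#' @param path Path to the file.
#' @return A tibble, validated against the clinical-record invariants.
#' @export
read_clinical_tsv <- function(path) {
  df <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                        progress = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"sample" %in% names(df)) stop("clinical table needs a `sample` column", call. = FALSE)
  check_unique_ids(as.character(df$sample), "sample")
  if ("time" %in% names(df)) {
    bad <- which(!is.na(df$time) & df$time <= 0)
    if (length(bad)) {
      stop("non-positive survival time for sample(s): ",
           paste(df$sample[utils::head(bad, 5)], collapse = ", "), call. = FALSE)
    }
  }
  if ("event" %in% names(df)) {
    if (!all(df$event %in% c(0, 1, NA))) {
      stop("`event` must be 0 or 1", call. = FALSE)
    }
  }
  df
}

#' @rdname read_clinical_tsv
#' @param df A clinical tibble.
#' @export
write_clinical_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a gene-level copy-number table
#'
#' Tab-separated with header `gene`, `chrom`, `start`, `end` followed by one
#' column per sample holding segmented copy values (diploid = 2). Genomic
#' coordinates are 1-based inclusive. Genes must be sortable by
#' (chromosome, start) and satisfy start <= end.
#'
#' @param path Path to the file.
#' @return A tibble with the four annotation columns and sample columns.
#' @export
read_copy_number_tsv <- function(path) {
  df <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                        progress = FALSE)
  validate_copy_number(df)
}

validate_copy_number <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("gene", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("copy-number table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_unique_ids(as.character(df$gene), "gene")
  if (any(df$start > df$end)) {
    stop("copy-number table has start > end for gene(s): ",
         paste(utils::head(df$gene[df$start > df$end], 5), collapse = ", "),
         call. = FALSE)
  }
  df
}

cn_sample_cols <- function(cn) {
  setdiff(names(cn), c("gene", "chrom", "start", "end"))
}

#' @rdname read_copy_number_tsv
#' @param df A copy-number tibble.
#' @export
write_copy_number_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Split a tab-separated text file into fields per line, rejecting files with
# fewer than `min_fields` fields on any line. Blank trailing lines dropped.
read_tsv_strict <- function(path, min_fields) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  out <- strsplit(lines, "\t", fixed = TRUE)
  if (min_fields > 0) {
    nf <- lengths(out)
    if (!length(out)) stop("empty file: ", basename(path), call. = FALSE)
    if (any(nf < min_fields)) {
      stop(sprintf("%s: line %d has fewer than %d fields", basename(path),
                   which(nf < min_fields)[1], min_fields), call. = FALSE)
    }
  }
  out
}
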