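#' Gene-by-sample expression matrix
#'
#' The central container of the package: a numeric matrix with genes as rows
#' and samples as columns, tagged with the scale its values live on
#' (`"counts"` for non-negative abundance estimates, `"log2"` for
#' log-transformed values).
#'
#' Invariants enforced at construction: gene and sample identifiers are
#' unique and non-empty, dimensions match the identifier vectors, and
#' counts-scale matrices contain no negative and no missing values.
#'
#' @param values Numeric matrix (genes x samples). Row and column names, if
#'   present, are used when `gene_ids`/`sample_ids` are not given.
#' @param scale One of `"counts"` or `"log2"`.
#' @param gene_ids,sample_ids Character vectors of identifiers; default to
#'   the dimnames of `values`.
#' @return An object of class `expr_matrix` (a named numeric matrix with a
#'   `scale` attribute).
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("Vhl", "Myc", "Cdkn2a"), c("s1", "s2"))), "counts")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("counts", "log2"),
                        gene_ids = rownames(values),
                        sample_ids = colnames(values)) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  if (scale == "counts") {
    if (anyNA(values)) stop("counts-scale matrix contains missing values", call. = FALSE)
    if (any(values < 0)) stop("counts-scale matrix contains negative values", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("missing/empty %s identifier", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "scale")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

# Subsetting keeps the class and scale tag when the result is still a matrix.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expr_matrix", "matrix", "array"))
  }
  out
}

#' @export
#' @method as_tibble expr_matrix
as_tibble.expr_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "gene")
}

assert_scale <- function(m, scale, arg = deparse(substitute(m))) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != scale) {
    stop(sprintf("`%s` must be on the %s scale (got %s)", arg, scale,
                 expr_scale(m)), call. = FALSE)
  }
  invisible(m)
}

assert_samples <- function(m, samples) {
  missing <- setdiff(samples, colnames(m))
  if (length(missing)) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(samples)
}
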