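#' Gene-by-sample expression matrix
#'
#' The central container of the package: a numeric matrix with genes in rows
#' and samples (genotypes, conditions, replicates) in columns, plus a flag
#' recording whether the values are raw read counts or already normalized.
#'
#' Invariants enforced at construction: dimnames present and unique, all
#' values finite and non-negative. Duplicate gene names are an error, never
#' silently merged. Gene and sample names are whitespace-trimmed and matched
#' case-sensitively everywhere in the package.
#'
#' @param values numeric matrix (genes x samples) with rownames (gene ids)
#'   and colnames (sample ids).
#' @param is_raw_counts logical flag; if `NULL`, inferred as `TRUE` iff every
#'   value is a non-negative whole number. The inference is a heuristic
#'   (normalized data can be integer-valued by coincidence), so callers may
#'   always override it.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` and `is_raw_counts`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' is_raw_counts(m)
#' @export
expression_matrix <- function(values, is_raw_counts = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    tt_stop("'values' must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    tt_stop("'values' must carry gene rownames and sample colnames")
  gid <- trimws(gid)
  sid <- trimws(sid)
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    tt_stop("duplicate gene names: %s", paste(dup, collapse = ", "),
            class = "transtat_duplicate_genes")
  }
  if (anyDuplicated(sid))
    tt_stop("duplicate sample names: %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    tt_stop("expression values must all be finite")
  if (any(values < 0))
    tt_stop("expression values must be non-negative")
  dimnames(values) <- list(gid, sid)
  if (is.null(is_raw_counts))
    is_raw_counts <- all(values == floor(values))
  structure(list(values = values, is_raw_counts = isTRUE(is_raw_counts)),
            class = "expression_matrix")
}

#' @rdname expression_matrix
#' @param m an `expression_matrix`.
#' @export
gene_ids <- function(m) rownames(expr_values(m))

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) colnames(expr_values(m))

#' @rdname expression_matrix
#' @export
expr_values <- function(m) {
  if (!inherits(m, "expression_matrix"))
    tt_stop("expected an expression_matrix")
  m$values
}

#' @rdname expression_matrix
#' @export
is_raw_counts <- function(m) {
  if (!inherits(m, "expression_matrix"))
    tt_stop("expected an expression_matrix")
  m$is_raw_counts
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              d[1], d[2],
              if (x$is_raw_counts) "raw counts" else "normalized"))
  n <- min(5L, d[1])
  p <- min(6L, d[2])
  print(x$values[seq_len(n), seq_len(p), drop = FALSE])
  if (d[1] > n || d[2] > p) cat("...\n")
  invisible(x)
}

# replace the value slab, preserving dimnames, with a possibly new flag
replace_values <- function(m, values, is_raw_counts) {
  expression_matrix(values, is_raw_counts = is_raw_counts)
}
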