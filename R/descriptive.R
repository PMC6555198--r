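#' Paired gene-expression coordinates for two samples
#'
#' One row per gene with its expression in each of the two requested
#' samples — the plot-ready table behind a transcriptome-wide scatter plot.
#' The tighter the scatter around the identity line, the more similar the
#' two global responses.
#'
#' @param m an [expression_matrix()].
#' @param sample_a,sample_b sample ids (may be identical, giving the
#'   diagonal case).
#' @param log_transform apply `log10(x + 1)` to both axes.
#' @return data.frame with columns `gene`, `x` (sample_a), `y` (sample_b).
#' @export
scatter_pairs <- function(m, sample_a, sample_b, log_transform = FALSE) {
  v <- expr_values(m)
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(v)) tt_stop("unknown sample '%s'", s)
  x <- v[, sample_a]
  y <- v[, sample_b]
  if (log_transform) {
    x <- log10p1(x)
    y <- log10p1(y)
  }
  data.frame(gene = rownames(v), x = unname(x), y = unname(y),
             stringsAsFactors = FALSE)
}

#' Pearson or Spearman correlation matrix between samples
#'
#' All pairwise coefficients between sample columns. Spearman is computed on
#' mid-ranks (average ranks for ties), i.e. it equals Pearson applied to the
#' ranked data. A zero-variance sample makes the Pearson coefficient
#' undefined: such entries are returned as `NA` with a warning, never
#' silently zeroed.
#'
#' @inheritParams scatter_pairs
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform apply `log10(x + 1)` before correlating (off by
#'   default; the matrix is used as provided).
#' @return object of class `correlation_matrix`: the symmetric coefficient
#'   matrix with attribute `method`.
#' @export
correlation_matrix <- function(m, method = c("pearson", "spearman"),
                               log_transform = FALSE) {
  method <- match.arg(method)
  v <- expr_values(m)
  if (ncol(v) < 2) tt_stop("need at least 2 samples")
  if (nrow(v) < 3) tt_stop("need at least 3 genes")
  if (log_transform) v <- log10p1(v)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    tt_warn("zero-variance sample(s) %s: correlations undefined (NA)",
            paste(colnames(v)[sds == 0], collapse = ", "))
  cc <- suppressWarnings(stats::cor(v, method = method))
  # exact symmetry and unit diagonal where defined
  cc <- (cc + t(cc)) / 2
  d <- diag(cc)
  d[sds > 0] <- 1
  diag(cc) <- d
  structure(cc, method = method, class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s, %d samples)\n",
              attr(x, "method"), ncol(x)))
  print(unclass(x)[seq_len(min(8, nrow(x))), seq_len(min(8, ncol(x)))],
        digits = 4)
  invisible(x)
}
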