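#' Filter lowly expressed genes
#'
#' Keeps exactly the genes whose expression strictly exceeds `min_value` in
#' at least `min_samples` samples; everything else is removed. The
#' comparison is strict (`>`), reading "minimum value required to exceed" as
#' strict exceedance. Filtering is idempotent.
#'
#' @param m an [expression_matrix()].
#' @param min_value expression threshold (>= 0).
#' @param min_samples minimum number of samples that must exceed the
#'   threshold (integer >= 1, at most the number of samples).
#' @return the filtered `expression_matrix`, with attributes
#'   `n_removed` (count) and `removed_genes` (their ids).
#' @export
filter_low_expression <- function(m, min_value, min_samples) {
  v <- expr_values(m)
  if (!is_scalar_number(min_value) || min_value < 0)
    tt_stop("'min_value' must be a non-negative number")
  if (!is_scalar_number(min_samples) || min_samples < 1 ||
      min_samples != floor(min_samples))
    tt_stop("'min_samples' must be a positive integer")
  if (min_samples > ncol(v))
    tt_stop("'min_samples' (%d) exceeds the number of samples (%d)",
            min_samples, ncol(v))
  keep <- rowSums(v > min_value) >= min_samples
  if (!any(keep))
    tt_stop("filter removed every gene; downstream analyses are undefined")
  out <- expression_matrix(v[keep, , drop = FALSE],
                           is_raw_counts = is_raw_counts(m))
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_genes") <- rownames(v)[!keep]
  out
}

# shared validation for length-based normalizations
check_lengths_for <- function(m, lengths) {
  if (!inherits(lengths, "gene_length_table"))
    tt_stop("'lengths' must be a gene_length_table")
  missing <- setdiff(gene_ids(m), names(lengths))
  if (length(missing))
    tt_stop("genes missing from the length table: %s",
            paste(missing, collapse = ", "))
  unclass(lengths)[gene_ids(m)]
}

#' FPKM / RPKM normalization
#'
#' Fragments (reads) per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (column_total * length_bp)`. RPKM is arithmetically
#' identical and provided as an alias. Requires raw counts and a length for
#' every gene.
#'
#' @inheritParams filter_low_expression
#' @param lengths a [gene_length_table()] covering every gene in `m`.
#' @return a normalized `expression_matrix` (flagged not raw).
#' @export
normalize_fpkm <- function(m, lengths) {
  v <- expr_values(m)
  if (!is_raw_counts(m))
    tt_stop("FPKM/RPKM normalization requires raw counts")
  len <- check_lengths_for(m, lengths)
  cs <- colSums(v)
  if (any(cs == 0))
    tt_stop("zero column sum in sample(s): %s",
            paste(colnames(v)[cs == 0], collapse = ", "))
  out <- sweep(v * 1e9 / len, 2, cs, "/")
  replace_values(m, out, is_raw_counts = FALSE)
}

#' @rdname normalize_fpkm
#' @export
normalize_rpkm <- normalize_fpkm

#' TPM normalization
#'
#' Transcripts per million: length-normalized rates `count/length` rescaled
#' so every sample column sums to exactly 1e6. Equivalently, FPKM rescaled
#' per column to sum 1e6.
#'
#' @inheritParams normalize_fpkm
#' @return a normalized `expression_matrix`; every column sums to 1e6
#'   (relative tolerance 1e-6).
#' @export
normalize_tpm <- function(m, lengths) {
  v <- expr_values(m)
  if (!is_raw_counts(m))
    tt_stop("TPM normalization requires raw counts")
  len <- check_lengths_for(m, lengths)
  rate <- v / len
  rs <- colSums(rate)
  if (any(rs == 0))
    tt_stop("all-zero column(s): %s — TPM rate sum undefined",
            paste(colnames(v)[rs == 0], collapse = ", "))
  out <- sweep(rate, 2, rs, "/") * 1e6
  replace_values(m, out, is_raw_counts = FALSE)
}

#' Upper-quartile normalization
#'
#' Bullard-style scheme: genes with zero counts in every sample are set
#' aside, each column is divided by the 75th percentile (linear
#' interpolation between order statistics) of the remaining counts, and all
#' columns are rescaled by the mean of those percentiles so magnitudes stay
#' count-like.
#'
#' @inheritParams filter_low_expression
#' @return a normalized `expression_matrix` whose 75th percentiles (over
#'   never-all-zero genes) are equal across samples.
#' @export
normalize_upper_quartile <- function(m) {
  v <- expr_values(m)
  if (!is_raw_counts(m))
    tt_stop("upper-quartile normalization requires raw counts")
  nonzero <- rowSums(v) > 0
  if (!any(nonzero)) tt_stop("matrix has no expressed genes")
  uq <- apply(v[nonzero, , drop = FALSE], 2, quantile_linear, p = 0.75)
  if (any(uq == 0))
    tt_stop("75th percentile is zero in sample(s): %s",
            paste(colnames(v)[uq == 0], collapse = ", "))
  out <- sweep(v, 2, uq, "/") * mean(uq)
  replace_values(m, out, is_raw_counts = FALSE)
}

#' RUV normalization with negative-control genes
#'
#' Removes unwanted technical variation between samples using the
#' control-gene (RUVg-style) factor-analysis route. On `log(count +
#' pseudocount)`: the row-centered control-gene submatrix is decomposed by
#' SVD, the top `k` right singular vectors are taken as unwanted sample
#' factors, every gene is regressed on them and the fitted component is
#' subtracted. Values are returned on the original scale
#' (`exp(cleaned) - pseudocount`, floored at 0) and flagged not raw.
#'
#' Factors with singular values numerically indistinguishable from zero are
#' dropped: if the controls carry no between-sample signal the data are
#' returned unchanged.
#'
#' @inheritParams filter_low_expression
#' @param controls a [control_gene_set()]; every member must be in the
#'   matrix, and there must be at least `k` of them.
#' @param k number of unwanted factors to remove (1 <= k < number of
#'   samples).
#' @param pseudocount added before taking logs; default 1.
#' @return a normalized `expression_matrix`, with attribute `unwanted_factors`
#'   (samples x k matrix of factor scores, zero columns for dropped factors).
#' @export
normalize_ruv <- function(m, controls, k = 1, pseudocount = 1) {
  v <- expr_values(m)
  if (!inherits(controls, "control_gene_set"))
    tt_stop("'controls' must be a control_gene_set")
  missing <- setdiff(unclass(controls), gene_ids(m))
  if (length(missing))
    tt_stop("control genes absent from the matrix: %s",
            paste(missing, collapse = ", "))
  if (!is_scalar_number(k) || k < 1 || k != floor(k))
    tt_stop("'k' must be a positive integer")
  if (k >= ncol(v))
    tt_stop("'k' (%d) must be smaller than the number of samples (%d)",
            k, ncol(v))
  if (length(controls) < k)
    tt_stop("need at least k = %d control genes, have %d", k, length(controls))
  if (!is_scalar_number(pseudocount) || pseudocount <= 0)
    tt_stop("'pseudocount' must be > 0")

  L <- log(v + pseudocount)
  Lc <- L[unclass(controls), , drop = FALSE]
  Lc <- Lc - rowMeans(Lc)
  sv <- svd(Lc, nu = 0, nv = min(k, ncol(v)))
  keep <- sv$d[seq_len(ncol(sv$v))] > max(sv$d[1] * 1e-8, 1e-12)
  W <- matrix(0, nrow = ncol(v), ncol = k,
              dimnames = list(colnames(v), paste0("W", seq_len(k))))
  if (any(keep))
    W[, which(keep)] <- sv$v[, keep, drop = FALSE]
  # W columns are orthonormal and sum to zero, so the intercept-adjusted
  # regression coefficients are just L %*% W
  cleaned <- L - (L %*% W) %*% t(W)
  out <- pmax(exp(cleaned) - pseudocount, 0)
  res <- replace_values(m, out, is_raw_counts = FALSE)
  attr(res, "unwanted_factors") <- W
  res
}

#' Relative log expression (RLE) profile
#'
#' Per gene, the natural-log expression (after adding a pseudocount) minus
#' that gene's median log expression across samples. Tight boxplots of these
#' log-ratios, centered at zero, indicate comparable samples; the profile is
#' the standard QC view before/after normalization.
#'
#' @inheritParams filter_low_expression
#' @param pseudocount added before taking logs; must be > 0.
#' @return object of class `rle_profile`: list with `log_ratios`
#'   (gene x sample matrix) and `summary` (per-sample quartiles
#'   min/q25/median/q75/max).
#' @export
rle_profile <- function(m, pseudocount = 1) {
  v <- expr_values(m)
  if (ncol(v) < 2) tt_stop("RLE needs at least 2 samples")
  if (!is_scalar_number(pseudocount) || pseudocount <= 0)
    tt_stop("'pseudocount' must be > 0")
  L <- log(v + pseudocount)
  med <- apply(L, 1, stats::median)
  lr <- L - med
  qs <- t(apply(lr, 2, function(x)
    stats::quantile(x, c(0, .25, .5, .75, 1), type = 7, names = FALSE)))
  colnames(qs) <- c("min", "q25", "median", "q75", "max")
  structure(list(log_ratios = lr,
                 summary = data.frame(sample = colnames(v), qs,
                                      row.names = NULL)),
            class = "rle_profile")
}

#' @export
print.rle_profile <- function(x, ...) {
  cat("rle_profile over", nrow(x$summary), "samples\n")
  print(x$summary)
  invisible(x)
}
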