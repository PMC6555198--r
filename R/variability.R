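#' Doane's rule for histogram bin counts
#'
#' Sturges' formula plus a skewness correction:
#' `ceil(1 + log2(n) + log2(1 + |g1| / sigma_g1))`, where `g1` is the
#' moment (sample) skewness and `sigma_g1 = sqrt(6 (n - 2) / ((n + 1) (n +
#' 3)))` is its standard error under normality. A constant vector has
#' undefined skewness and gets a single bin.
#'
#' @param values numeric vector, `n >= 3` (skewness is undefined below).
#' @return integer bin count >= 1.
#' @export
doane_bins <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 3) tt_stop("Doane's rule needs n >= 3 (skewness undefined)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(1L)
  g1 <- mean((x - m)^3) / m2^1.5
  sg1 <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  as.integer(ceiling(1 + log2(n) + log2(1 + abs(g1) / sg1)))
}

#' Shannon entropy of a sample's expression histogram
#'
#' The expression vector of one sample (by default `log10(x + 1)`
#' transformed, since raw RNA-seq spans decades and makes linear bins
#' degenerate) is binned into equal-width bins over its range, with the bin
#' count set by [doane_bins()]; the entropy is `H = -sum p_i log2 p_i` over
#' non-empty bins, in bits. `0 <= H <= log2(bins)` always.
#'
#' @param m an [expression_matrix()].
#' @param sample sample id; if `NULL`, all samples are profiled and a
#'   data.frame is returned.
#' @param log_transform apply `log10(x + 1)` before binning (default
#'   `TRUE`).
#' @return for one sample, an object of class `entropy_result` (list with
#'   `sample`, `bins`, `edges`, `counts`, `entropy_bits`); for all samples,
#'   a data.frame with columns `sample`, `bins`, `entropy_bits`.
#' @export
shannon_entropy <- function(m, sample = NULL, log_transform = TRUE) {
  v <- expr_values(m)
  if (nrow(v) < 3) tt_stop("entropy needs at least 3 genes")
  if (is.null(sample)) {
    rows <- lapply(colnames(v), function(s) {
      e <- shannon_entropy(m, s, log_transform)
      data.frame(sample = s, bins = e$bins, entropy_bits = e$entropy_bits,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (!sample %in% colnames(v)) tt_stop("unknown sample '%s'", sample)
  x <- v[, sample]
  if (log_transform) x <- log10p1(x)
  if (max(x) == min(x)) {
    tt_warn("sample '%s' is constant: single bin, entropy 0", sample)
    return(structure(list(sample = sample, bins = 1L,
                          edges = c(min(x), max(x)),
                          counts = length(x), entropy_bits = 0),
                     class = "entropy_result"))
  }
  bins <- doane_bins(x)
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  p <- counts[counts > 0] / length(x)
  structure(list(sample = sample, bins = bins, edges = edges,
                 counts = counts, entropy_bits = -sum(p * log2(p))),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("entropy_result: sample %s, %d bins, H = %.4f bits\n",
              x$sample, x$bins, x$entropy_bits))
  invisible(x)
}

#' Squared-coefficient-of-variation noise matrix
#'
#' Transcriptome noise between two samples is the squared coefficient of
#' variation, CV^2 = sigma^2 / mu^2, computed per gene on the pair of values
#' and averaged over genes. The two-point variance uses the population
#' convention (divide by 2), so a gene with values `(x, 3x)` contributes
#' exactly 0.25; note the sample convention would double every entry. Genes
#' whose pair mean is zero are excluded from the average (their count is
#' recorded).
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @return object of class `noise_matrix`: list with `values` (symmetric
#'   sample-pair matrix, zero diagonal, `NA` where every gene was
#'   excluded) and `genes_used` (matrix of included-gene counts).
#' @export
noise_matrix <- function(m) {
  v <- expr_values(m)
  S <- ncol(v)
  if (S < 2) tt_stop("noise needs at least 2 samples")
  nm <- matrix(0, S, S, dimnames = list(colnames(v), colnames(v)))
  gu <- matrix(nrow(v), S, S, dimnames = dimnames(nm))
  for (i in seq_len(S - 1)) {
    for (j in seq((i + 1), S)) {
      cv2 <- pair_cv2(v[, i], v[, j])
      used <- sum(!is.na(cv2))
      gu[i, j] <- gu[j, i] <- used
      if (used == 0) {
        tt_warn("all genes excluded for pair (%s, %s); entry is NA",
                colnames(v)[i], colnames(v)[j])
        nm[i, j] <- nm[j, i] <- NA_real_
      } else {
        nm[i, j] <- nm[j, i] <- mean(cv2, na.rm = TRUE)
      }
    }
  }
  structure(list(values = nm, genes_used = gu), class = "noise_matrix")
}

#' @rdname noise_matrix
#' @param sample_a,sample_b sample ids of one pair.
#' @return `noise_pair()` returns the per-gene CV^2 vector for a single
#'   pair (`NA` for genes with zero pair mean), for users who want the
#'   distribution rather than its mean.
#' @export
noise_pair <- function(m, sample_a, sample_b) {
  v <- expr_values(m)
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(v)) tt_stop("unknown sample '%s'", s)
  stats::setNames(pair_cv2(v[, sample_a], v[, sample_b]), rownames(v))
}

# population CV^2 of each two-point gene pair; NA where the mean is zero
pair_cv2 <- function(x, y) {
  mu <- (x + y) / 2
  var_pop <- ((x - mu)^2 + (y - mu)^2) / 2
  ifelse(mu > 0, var_pop / mu^2, NA_real_)
}

#' @export
print.noise_matrix <- function(x, ...) {
  cat("noise_matrix (mean CV^2 per sample pair)\n")
  print(x$values, digits = 4)
  invisible(x)
}
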