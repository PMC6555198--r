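#' Select genes by minimum fold change between two conditions
#'
#' Per gene, the fold change is `(mean over cond_b samples + pseudocount) /
#' (mean over cond_a samples + pseudocount)`; a gene is kept iff the fold is
#' `>= min_fold` or `<= 1/min_fold`. The rule is symmetric in the two
#' conditions: swapping the labels selects the identical gene set. The
#' pseudocount (default 1) guards against division by zero.
#'
#' @param m an [expression_matrix()].
#' @param meta a [sample_metadata()] covering every sample of `m`.
#' @param cond_a,cond_b condition labels present in `meta`.
#' @param min_fold minimum fold change, `>= 1`.
#' @param pseudocount added to both condition means.
#' @return character vector of selected gene ids, with attribute `fold`
#'   (the named per-gene fold-change vector, b over a).
#' @export
select_by_fold_change <- function(m, meta, cond_a, cond_b, min_fold = 2,
                                  pseudocount = 1) {
  v <- expr_values(m)
  meta <- validate_metadata(meta, m)
  for (cond in c(cond_a, cond_b))
    if (!any(meta == cond))
      tt_stop("condition '%s' has no samples", cond)
  if (!is_scalar_number(min_fold) || min_fold < 1)
    tt_stop("'min_fold' must be >= 1")
  ma <- rowMeans(v[, names(meta)[meta == cond_a], drop = FALSE])
  mb <- rowMeans(v[, names(meta)[meta == cond_b], drop = FALSE])
  fold <- (mb + pseudocount) / (ma + pseudocount)
  keep <- fold >= min_fold | fold <= 1 / min_fold
  structure(rownames(v)[keep], fold = fold)
}

#' Row-wise z-scoring of an expression matrix
#'
#' Each gene j is standardized across samples: `Z_j(p_i) = (x_j(p_i) -
#' mean_j) / sd_j`, with the sample (n - 1) standard deviation. Genes with
#' zero variance across samples cannot be scaled and are dropped with a
#' report.
#'
#' @param m an [expression_matrix()] or plain numeric matrix with dimnames.
#' @return object of class `scaled_matrix`: list with `values` (Z matrix),
#'   `means`, `sds` (the scaling provenance, per retained gene) and
#'   `dropped` (zero-variance gene ids).
#' @export
zscale <- function(m) {
  v <- if (inherits(m, "expression_matrix")) expr_values(m) else as.matrix(m)
  if (ncol(v) < 2) tt_stop("z-scaling needs at least 2 samples")
  mu <- rowMeans(v)
  sd_ <- apply(v, 1, stats::sd)
  dropped <- rownames(v)[sd_ == 0]
  if (length(dropped) == nrow(v))
    tt_stop("every gene has zero variance; nothing to scale")
  if (length(dropped))
    tt_warn("dropping %d zero-variance gene(s)", length(dropped))
  keep <- sd_ > 0
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  structure(list(values = z, means = mu[keep], sds = sd_[keep],
                 dropped = dropped),
            class = "scaled_matrix")
}

#' Ward hierarchical clustering of scaled genes
#'
#' Agglomerative clustering of gene rows under Ward's minimum-variance
#' criterion on Euclidean distances (the "Ward.D2" convention: the
#' Lance-Williams update is applied to squared distances and merge heights
#' are their square roots — stated explicitly because two incompatible
#' "Ward" conventions circulate). The tree is cut into `n_clusters` groups
#' and the gene names of every cluster are listed.
#'
#' @param z a `scaled_matrix` from [zscale()] (or plain matrix with gene
#'   rownames).
#' @param n_clusters number of clusters, `2 <= n_clusters <= genes`.
#' @return object of class `clustering_result`: list with `hclust` (merge
#'   history), `k`, `assignment` (named integer vector), `leaf_order`
#'   (gene ids in dendrogram order) and `clusters` (list of per-cluster
#'   gene id vectors).
#' @export
ward_cluster <- function(z, n_clusters) {
  v <- if (inherits(z, "scaled_matrix")) z$values else as.matrix(z)
  n <- nrow(v)
  if (!is_scalar_number(n_clusters) || n_clusters != floor(n_clusters) ||
      n_clusters < 2)
    tt_stop("'n_clusters' must be an integer >= 2")
  if (n_clusters > n)
    tt_stop("more clusters (%d) than genes (%d)", n_clusters, n)
  hc <- stats::hclust(stats::dist(v), method = "ward.D2")
  assignment <- stats::cutree(hc, k = n_clusters)
  clusters <- split(names(assignment), assignment)
  names(clusters) <- paste0("cluster_", names(clusters))
  structure(list(hclust = hc, k = as.integer(n_clusters),
                 assignment = assignment,
                 leaf_order = hc$labels[hc$order],
                 clusters = clusters),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("clustering_result: %d genes in %d Ward clusters (sizes: %s)\n",
              length(x$assignment), x$k, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Heatmap layout from a clustering
#'
#' Reorders the scaled matrix rows into dendrogram leaf order (cluster
#' blocks are contiguous) and optionally Ward-orders the sample axis too,
#' emitting a plot-ready layout.
#'
#' @param z the `scaled_matrix` that was clustered.
#' @param clustering the matching `clustering_result`.
#' @param cluster_samples also order columns by Ward clustering of samples.
#' @return list of class `heatmap_layout`: `matrix` (reordered Z values),
#'   `row_order`, `col_order`, `row_merges` (data.frame of merge heights)
#'   and `assignment` in row order.
#' @export
heatmap_layout <- function(z, clustering, cluster_samples = FALSE) {
  v <- if (inherits(z, "scaled_matrix")) z$values else as.matrix(z)
  if (!inherits(clustering, "clustering_result"))
    tt_stop("'clustering' must be a clustering_result")
  if (!setequal(rownames(v), names(clustering$assignment)))
    tt_stop("gene sets of matrix and clustering do not match")
  row_order <- clustering$leaf_order
  col_order <- colnames(v)
  if (cluster_samples && ncol(v) >= 2) {
    hc_s <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
    col_order <- hc_s$labels[hc_s$order]
  }
  hc <- clustering$hclust
  structure(list(matrix = v[row_order, col_order, drop = FALSE],
                 row_order = row_order, col_order = col_order,
                 row_merges = data.frame(left = hc$merge[, 1],
                                         right = hc$merge[, 2],
                                         height = hc$height),
                 assignment = clustering$assignment[row_order]),
            class = "heatmap_layout")
}

#' Categorize genes for a volcano plot
#'
#' Given an external differential-expression table, classifies each gene:
#' `sig-up` iff `p < p_threshold` and `log2fc >= fc_threshold`; `sig-down`
#' iff `p < p_threshold` and `log2fc <= -fc_threshold`; otherwise
#' `not-sig`. The y coordinate is `-log10(p)`, with p-values of 0 (or below
#' the floor) mapped to a finite floor of 1e-300 with a warning.
#'
#' @param de a [de_table()].
#' @param p_threshold significance level in (0, 1).
#' @param fc_threshold absolute log2 fold-change threshold, `>= 0`.
#' @return data.frame of class `volcano_table` with columns `gene`,
#'   `log2fc`, `neg_log10_p`, `category`.
#' @export
volcano_categorize <- function(de, p_threshold = 0.05, fc_threshold = 1) {
  if (!inherits(de, "de_table")) de <- de_table(de)
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    tt_stop("'p_threshold' must lie in (0, 1)")
  if (!is_scalar_number(fc_threshold) || fc_threshold < 0)
    tt_stop("'fc_threshold' must be >= 0")
  p_floor <- 1e-300
  if (any(de$pvalue < p_floor))
    tt_warn("%d p-value(s) at or below 0 mapped to the 1e-300 floor",
            sum(de$pvalue < p_floor))
  p <- pmax(de$pvalue, p_floor)
  category <- rep("not-sig", nrow(de))
  sig <- de$pvalue < p_threshold
  category[sig & de$log2fc >= fc_threshold] <- "sig-up"
  category[sig & de$log2fc <= -fc_threshold] <- "sig-down"
  structure(data.frame(gene = de$gene, log2fc = de$log2fc,
                       neg_log10_p = -log10(p), category = category,
                       stringsAsFactors = FALSE),
            class = c("volcano_table", "data.frame"))
}
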