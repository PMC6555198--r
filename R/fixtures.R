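#' Specification for a synthetic expression dataset
#'
#' Describes a fully seeded synthetic world: per-gene baseline expression
#' drawn from one of the six supported heavy-tailed families, a two-(or
#' more-)condition design, a planted fraction of differentially expressed
#' genes with a known fold change, an optional multiplicative per-sample
#' unwanted factor (the technical artifact RUV is meant to remove, applied
#' to all genes including the controls), and multiplicative lognormal
#' replicate noise.
#'
#' Defaults emulate a small bulk RNA-seq experiment: 2000 genes, two
#' conditions with 3 replicates each, lognormal(meanlog 2, sdlog 1)
#' baselines, 10% DE genes at fold 4, 50 negative-control genes, replicate
#' noise sdlog 0.1.
#'
#' @param n_genes,n_samples dimensions of the matrix.
#' @param conditions condition label per sample (length `n_samples`).
#' @param family baseline expression family, one of [dist_families].
#' @param params named list of family parameters.
#' @param de_fraction fraction of genes planted as DE (in condition
#'   `de_condition`).
#' @param fold_change multiplicative fold applied to DE genes (half up,
#'   half down).
#' @param de_condition which condition carries the fold (default the last).
#' @param unwanted_factors multiplicative per-sample technical factor
#'   (length `n_samples`); `NULL` for none.
#' @param noise_sdlog sdlog of multiplicative lognormal replicate noise; 0
#'   for a noise-free world.
#' @param n_controls number of negative-control genes (picked among non-DE
#'   genes).
#' @param seed integer seed; mandatory — there is no unseeded generation.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2000, n_samples = 6,
                         conditions = rep(c("Control", "Treated"),
                                          length.out = n_samples),
                         family = "lognormal",
                         params = list(meanlog = 2, sdlog = 1),
                         de_fraction = 0.1, fold_change = 4,
                         de_condition = NULL,
                         unwanted_factors = NULL,
                         noise_sdlog = 0.1,
                         n_controls = 50, seed) {
  if (missing(seed) || !is_scalar_number(seed))
    tt_stop("'seed' is mandatory: fixtures are never generated unseeded")
  if (n_genes < 1 || n_samples < 2) tt_stop("need >= 1 gene and >= 2 samples")
  conditions <- rep(conditions, length.out = n_samples)
  family <- match.arg(family, dist_families)
  if (n_controls > n_genes)
    tt_stop("more control genes (%d) than genes (%d)", n_controls, n_genes)
  if (!is.null(unwanted_factors)) {
    if (length(unwanted_factors) != n_samples || any(unwanted_factors <= 0))
      tt_stop("'unwanted_factors' needs one positive factor per sample")
  }
  if (de_fraction < 0 || de_fraction > 1) tt_stop("'de_fraction' in [0, 1]")
  if (fold_change < 1) tt_stop("'fold_change' must be >= 1")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 conditions = conditions, family = family, params = params,
                 de_fraction = de_fraction, fold_change = fold_change,
                 de_condition = de_condition %||% conditions[n_samples],
                 unwanted_factors = unwanted_factors,
                 noise_sdlog = noise_sdlog, n_controls = n_controls,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# one draw of n baseline expression values from the named family
draw_family <- function(n, family, params) {
  p <- params
  switch(family,
    lognormal   = stats::rlnorm(n, p$meanlog, p$sdlog),
    pareto      = rpareto(n, p$shape, p$minimum %||% 1),
    loglogistic = rloglogis(n, p$shape, p$scale %||% 1),
    gamma       = stats::rgamma(n, shape = p$shape, rate = p$rate %||% 1),
    weibull     = stats::rweibull(n, p$shape, p$scale %||% 1),
    burr        = rburr(n, p$shape1, p$shape2, p$scale %||% 1))
}

#' Generate a complete synthetic dataset bundle
#'
#' Draws per-gene baselines from the spec's family, plants the fold change
#' in the DE condition (half of the DE genes up, half down), applies the
#' per-sample unwanted factor and replicate noise multiplicatively, and
#' rounds to integer counts (rounding, not truncation, to preserve means).
#' Also emits the four supporting inputs (gene lengths, control genes,
#' metadata, a DE results table consistent with the planted truth) and a
#' truth record of every planted parameter. The same seed yields the same
#' bundle, byte for byte.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture_bundle`: `matrix`
#'   ([expression_matrix()]), `lengths`, `controls`, `metadata`, `de`
#'   (a [de_table()]) and `truth` (planted DE genes and directions, factors,
#'   family, parameters, seed).
#' @export
generate_fixtures <- function(spec) {
  if (!inherits(spec, "fixture_spec")) tt_stop("'spec' must be a fixture_spec")
  with_seed(spec$seed, {
    G <- spec$n_genes
    S <- spec$n_samples
    genes <- sprintf("gene_%04d", seq_len(G))
    samples <- sprintf("S%02d_%s", seq_len(S), spec$conditions)

    base <- draw_family(G, spec$family, spec$params)
    n_de <- round(spec$de_fraction * G)
    de_genes <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
    de_up <- rep_len(c(TRUE, FALSE), n_de)   # alternate up/down regulation

    mult <- matrix(1, G, S)
    in_de_cond <- spec$conditions == spec$de_condition
    if (n_de > 0) {
      mult[de_genes[de_up], in_de_cond] <- spec$fold_change
      mult[de_genes[!de_up], in_de_cond] <- 1 / spec$fold_change
    }
    fac <- spec$unwanted_factors %||% rep(1, S)
    vals <- base * mult
    vals <- sweep(vals, 2, fac, "*")
    if (spec$noise_sdlog > 0)
      vals <- vals * matrix(stats::rlnorm(G * S, 0, spec$noise_sdlog), G, S)
    counts <- round(vals)
    dimnames(counts) <- list(genes, samples)

    lengths <- gene_length_table(
      stats::setNames(sample(200:10000, G, replace = TRUE), genes))
    non_de <- setdiff(seq_len(G), de_genes)
    if (length(non_de) < spec$n_controls)
      tt_stop("not enough non-DE genes to pick %d controls", spec$n_controls)
    controls <- control_gene_set(genes[sort(sample(non_de, spec$n_controls))])
    meta <- sample_metadata(stats::setNames(spec$conditions, samples))

    # DE table consistent with the truth: planted genes get the planted
    # log2 fold and a small p-value, the rest are null
    log2fc <- numeric(G)
    pval <- stats::runif(G)
    if (n_de > 0) {
      log2fc[de_genes] <- ifelse(de_up, 1, -1) * log2(spec$fold_change)
      pval[de_genes] <- 10^(-stats::runif(n_de, 3, 8))
    }
    log2fc <- log2fc + stats::rnorm(G, 0, 0.05)
    de <- de_table(data.frame(gene = genes, log2fc = log2fc, pvalue = pval,
                              stringsAsFactors = FALSE))

    structure(list(
      matrix = expression_matrix(counts, is_raw_counts = TRUE),
      lengths = lengths, controls = controls, metadata = meta, de = de,
      truth = list(family = spec$family, params = spec$params,
                   de_genes = genes[de_genes],
                   de_up = genes[de_genes[de_up]],
                   de_down = genes[de_genes[!de_up]],
                   fold_change = spec$fold_change,
                   de_condition = spec$de_condition,
                   unwanted_factors = stats::setNames(fac, samples),
                   noise_sdlog = spec$noise_sdlog,
                   seed = spec$seed)),
      class = "fixture_bundle")
  })
}

#' Write a fixture bundle to a directory of CSV/JSON files
#'
#' Emits `matrix.csv`, `lengths.csv`, `controls.csv`, `metadata.csv`,
#' `de.csv` and `truth.json` into `dir` (created if absent). Deterministic:
#' the same bundle writes identical bytes.
#'
#' @param bundle a `fixture_bundle` from [generate_fixtures()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  if (!inherits(bundle, "fixture_bundle")) tt_stop("not a fixture_bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(bundle$matrix, file.path(dir, "matrix.csv"))
  write_table(data.frame(gene = names(bundle$lengths),
                         length = as.integer(bundle$lengths)),
              file.path(dir, "lengths.csv"))
  writeLines(unclass(bundle$controls), file.path(dir, "controls.csv"))
  write_table(data.frame(sample = names(bundle$metadata),
                         condition = as.character(bundle$metadata)),
              file.path(dir, "metadata.csv"))
  write_table(as.data.frame(unclass(bundle$de)), file.path(dir, "de.csv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
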