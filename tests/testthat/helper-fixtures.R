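# shared builders for in-code fixtures; everything is seeded

with_seed <- transtat:::with_seed

make_em <- function(values, genes = NULL, samples = NULL, raw = NULL) {
  v <- as.matrix(values)
  rownames(v) <- genes %||% sprintf("g%03d", seq_len(nrow(v)))
  colnames(v) <- samples %||% sprintf("s%02d", seq_len(ncol(v)))
  expression_matrix(v, is_raw_counts = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_local_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# random integer count matrix, lognormal baselines with poisson-ish jitter
rand_counts <- function(n_genes, n_samples, seed) {
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 4, sdlog = 1.2)
    v <- matrix(rpois(n_genes * n_samples, rep(base, n_samples)),
                n_genes, n_samples)
    make_em(v, raw = TRUE)
  })
}

rand_lengths <- function(m, seed) {
  with_seed(seed,
    gene_length_table(setNames(sample(200:5000, nrow(expr_values(m))),
                               gene_ids(m))))
}

# independent O(n^3) Lance-Williams Ward oracle ("ward.D2" convention:
# update on squared Euclidean distances, merge height = sqrt of criterion)
naive_ward_heights <- function(x) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  diag(D2) <- Inf
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    sub <- D2
    sub[!active, ] <- Inf
    sub[, !active] <- Inf
    idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    heights <- c(heights, sqrt(D2[i, j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    D2[j, ] <- D2[, j] <- Inf
  }
  heights
}

# draw n values from a named family with the package's generators
draw_values <- function(n, family, p) {
  switch(family,
    lognormal   = rlnorm(n, p$meanlog, p$sdlog),
    pareto      = rpareto(n, p$shape, p$minimum),
    loglogistic = rloglogis(n, p$shape, p$scale),
    gamma       = rgamma(n, shape = p$shape, rate = p$rate),
    weibull     = rweibull(n, p$shape, p$scale),
    burr        = rburr(n, p$shape1, p$shape2, p$scale))
}

# reference parameters for the model-recovery simulations: magnitudes a
# scientist would call typical for normalized bulk expression
recovery_params <- list(
  lognormal   = list(meanlog = 2, sdlog = 1),
  pareto      = list(shape = 1.5, minimum = 1),
  loglogistic = list(shape = 2.5, scale = 8),
  gamma       = list(shape = 2, rate = 0.2),
  weibull     = list(shape = 1.5, scale = 10),
  burr        = list(shape1 = 2, shape2 = 0.8, scale = 10))
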