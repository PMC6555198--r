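test_that("low-expression filter applies strict exceedance and is idempotent", {
  m <- make_em(rbind(c(0, 0, 0), c(10, 10, 10), c(6, 4, 4)),
               genes = c("zero", "high", "edge"))
  f <- filter_low_expression(m, min_value = 5, min_samples = 2)
  expect_identical(gene_ids(f), "high")
  expect_identical(attr(f, "n_removed"), 2L)
  expect_setequal(attr(f, "removed_genes"), c("zero", "edge"))
  # (6,4,4) passes with min_samples = 1: one sample strictly exceeds 5
  f1 <- filter_low_expression(m, 5, 1)
  expect_setequal(gene_ids(f1), c("high", "edge"))
  # idempotence
  f2 <- filter_low_expression(f1, 5, 1)
  expect_identical(expr_values(f2), expr_values(f1))
  expect_error(filter_low_expression(m, 100, 1), "every gene")
  expect_error(filter_low_expression(m, 5, 4), "exceeds the number of samples")
})

test_that("FPKM matches the hand formula and is column-scale invariant", {
  m <- make_em(cbind(c(100, 1e6 - 100)), genes = c("a", "b"), raw = TRUE)
  lens <- gene_length_table(c(a = 1000, b = 1000))
  fp <- normalize_fpkm(m, lens)
  # count 100, length 1000 bp, library 1e6 -> 100
  expect_equal(expr_values(fp)["a", 1], 100)
  expect_false(is_raw_counts(fp))

  m0 <- make_em(rbind(c(0, 5), c(10, 20)), genes = c("a", "b"), raw = TRUE)
  lens2 <- gene_length_table(c(a = 3000, b = 500))
  expect_equal(expr_values(normalize_fpkm(m0, lens2))["a", 1], 0)

  # doubling every count in a column leaves that column's FPKM unchanged
  doubled <- make_em(expr_values(m0) %*% diag(c(2, 1)), genes = c("a", "b"),
                     raw = TRUE)
  expect_equal(expr_values(normalize_fpkm(doubled, lens2)),
               expr_values(normalize_fpkm(m0, lens2)))

  expect_identical(normalize_rpkm(m, lens), normalize_fpkm(m, lens))
  expect_error(normalize_fpkm(m, gene_length_table(c(a = 1000))), "\\bb\\b")
  norm <- make_em(rbind(c(1.5, 2)), raw = FALSE)
  expect_error(normalize_fpkm(norm, lens), "raw counts")
})

test_that("TPM matches hand values and conserves 1e6 per column", {
  m <- make_em(cbind(c(10, 40)), genes = c("a", "b"), raw = TRUE)
  lens <- gene_length_table(c(a = 1000, b = 2000))
  tp <- expr_values(normalize_tpm(m, lens))
  # rates (0.01, 0.02) -> shares 1/3 and 2/3 of 1e6
  expect_equal(tp[, 1], c(a = 1e6 / 3, b = 2e6 / 3))

  single <- make_em(cbind(c(50)), genes = "a", raw = TRUE)
  expect_equal(expr_values(normalize_tpm(single, lens))[1, 1], 1e6)

  zerocol <- make_em(cbind(c(0, 0), c(1, 2)), genes = c("a", "b"), raw = TRUE)
  expect_error(normalize_tpm(zerocol, lens), "all-zero")

  # conservation + consistency with FPKM on random fixtures
  for (seed in 1:3) {
    m <- rand_counts(100, 5, seed)
    lens <- rand_lengths(m, seed + 100)
    tp <- expr_values(normalize_tpm(m, lens))
    expect_lt(max(abs(colSums(tp) - 1e6)) / 1e6, 1e-6)
    fp <- expr_values(normalize_fpkm(m, lens))
    rescaled <- sweep(fp, 2, colSums(fp), "/") * 1e6
    expect_lt(max(abs(tp - rescaled)) / max(tp), 1e-9)
  }
})

test_that("upper-quartile normalization equalizes the 75th percentile", {
  with_seed(11, {
    a <- rpois(60, 40)
    a[1:5] <- 0   # all-zero genes must not influence the quartile
  })
  m <- make_em(cbind(a, 2 * a), samples = c("A", "B"), raw = TRUE)
  uq <- expr_values(normalize_upper_quartile(m))
  # column B = 2 x column A collapses to equality after normalization
  expect_equal(uq[, "A"], uq[, "B"], tolerance = 1e-12, ignore_attr = TRUE)

  # two identical columns: ratio between columns is exactly 1, and the
  # rescaling constant makes output equal input
  m2 <- make_em(cbind(a, a), raw = TRUE)
  expect_equal(expr_values(normalize_upper_quartile(m2)), expr_values(m2))

  # all-zero gene present gives same result as deleting and re-inserting it
  drop0 <- make_em(cbind(a[a > 0], 2 * a[a > 0]), raw = TRUE)
  expect_equal(unname(expr_values(normalize_upper_quartile(m))[a > 0, ]),
               unname(expr_values(normalize_upper_quartile(drop0))))
  expect_equal(unname(expr_values(normalize_upper_quartile(m))[a == 0, ]),
               matrix(0, 5, 2))

  sparse <- make_em(rbind(c(0, 1), c(0, 1), c(0, 1), c(0, 1), c(1, 1)),
                    raw = TRUE)
  expect_error(normalize_upper_quartile(sparse), "75th percentile is zero")

  # equalization invariant over never-all-zero genes
  m3 <- rand_counts(150, 4, seed = 5)
  out <- expr_values(normalize_upper_quartile(m3))
  nz <- rowSums(expr_values(m3)) > 0
  uqs <- apply(out[nz, ], 2, quantile, probs = 0.75, type = 7)
  expect_lt(diff(range(uqs)), 1e-9)
})

test_that("RUV removes a planted sample factor and is inert without one", {
  bundle <- generate_fixtures(fixture_spec(
    n_genes = 400, n_samples = 6, seed = 19, noise_sdlog = 0,
    unwanted_factors = c(1, 1.6, 0.7, 2.2, 1.1, 0.6), n_controls = 40))
  m <- bundle$matrix
  ruv <- normalize_ruv(m, bundle$controls, k = 1)
  ctrl <- unclass(bundle$controls)
  logvar <- function(M) mean(apply(log(expr_values(M)[ctrl, ] + 1), 1, var))
  expect_lt(logvar(ruv) / logvar(m), 0.10)   # >= 90% reduction

  # removed-factor scores are orthogonal to the control residuals
  W <- attr(ruv, "unwanted_factors")
  resid <- log(expr_values(ruv)[ctrl, ] + 1)
  resid <- resid - rowMeans(resid)
  expect_lt(max(abs(resid %*% W)), 1e-6)

  # constant controls carry no signal: output == input
  flat <- make_em(rbind(c(7, 7, 7), c(3, 9, 27), c(50, 50, 50)),
                  genes = c("c1", "g1", "c2"), raw = TRUE)
  out <- normalize_ruv(flat, control_gene_set(c("c1", "c2")), k = 1)
  expect_lt(max(abs(expr_values(out) - expr_values(flat)) /
                  pmax(expr_values(flat), 1)), 1e-6)

  expect_error(normalize_ruv(m, bundle$controls, k = 6), "smaller than")
  expect_error(normalize_ruv(m, control_gene_set("nope"), k = 1), "absent")
  expect_error(normalize_ruv(m, control_gene_set(ctrl[1]), k = 2),
               "at least k")
})

test_that("RLE log-ratios are centered per gene and detect a global shift", {
  m <- make_em(cbind(c(4, 16, 64), c(4, 16, 64), c(4, 16, 64)), raw = TRUE)
  prof <- rle_profile(m)
  expect_true(all(prof$log_ratios == 0))

  # sample B globally 2x sample A: columns sit log(2) apart, symmetric
  x <- c(10, 100, 1000)
  m2 <- make_em(cbind(x, 2 * x), samples = c("A", "B"))
  prof2 <- rle_profile(m2, pseudocount = 1e-9)
  expect_equal(unname(prof2$log_ratios[, "B"] - prof2$log_ratios[, "A"]),
               rep(log(2), 3), tolerance = 1e-6)
  expect_equal(unname(prof2$log_ratios[, "B"] + prof2$log_ratios[, "A"]),
               rep(0, 3), tolerance = 1e-12)

  # per-gene median of RLE values is 0 (odd sample count)
  m3 <- rand_counts(50, 5, seed = 3)
  prof3 <- rle_profile(m3)
  expect_lt(max(abs(apply(prof3$log_ratios, 1, median))), 1e-12)

  expect_error(rle_profile(make_em(cbind(c(1, 2)))), "2 samples")
})
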