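meta4 <- function(m) {
  sample_metadata(setNames(rep(c("Control", "Treated"), each = 2),
                           sample_ids(m)))
}

test_that("fold-change selection applies the symmetric reciprocal rule", {
  v <- rbind(c(10, 10, 45, 45),    # fold (45+1)/(10+1) = 46/11 ~ 4.18
             c(20, 20, 20, 20),    # fold exactly 1
             c(80, 80, 10, 10))    # down-regulated ~ 1/4.6
  m <- make_em(v, genes = c("up", "flat", "down"))
  meta <- meta4(m)
  sel <- select_by_fold_change(m, meta, "Control", "Treated", min_fold = 2)
  expect_setequal(as.character(sel), c("up", "down"))
  expect_equal(unname(attr(sel, "fold")["up"]), 46 / 11)

  # equal means excluded for any min_fold > 1, kept at the boundary
  expect_false("flat" %in% select_by_fold_change(m, meta, "Control",
                                                 "Treated", 1.0001))
  expect_setequal(as.character(
    select_by_fold_change(m, meta, "Control", "Treated", min_fold = 1)),
    c("up", "flat", "down"))

  # swapping condition labels selects the identical set
  swapped <- select_by_fold_change(m, meta, "Treated", "Control", min_fold = 2)
  expect_setequal(as.character(swapped), as.character(sel))

  expect_error(select_by_fold_change(m, meta, "Control", "Missing", 2),
               "no samples")
})

test_that("z-scaling standardizes rows and drops zero-variance genes", {
  m <- make_em(rbind(c(1, 2, 3), c(5, 5, 5)), genes = c("g", "flat"))
  expect_warning(z <- zscale(m), "zero-variance")
  expect_equal(unname(z$values["g", ]), c(-1, 0, 1))   # n-1 sd convention
  expect_identical(z$dropped, "flat")
  expect_equal(z$means[["g"]], 2)
  expect_equal(z$sds[["g"]], 1)

  zz <- with_seed(8, zscale(make_em(matrix(rlnorm(60, 3, 1), 15, 4))))
  expect_lt(max(abs(rowMeans(zz$values))), 1e-9)
  expect_lt(max(abs(apply(zz$values, 1, sd) - 1)), 1e-9)
  # idempotence: scaling a scaled matrix changes nothing
  z2 <- zscale(zz$values)
  expect_lt(max(abs(z2$values - zz$values)), 1e-9)

  expect_error(zscale(make_em(matrix(4, 3, 3))), "zero variance")
})

test_that("Ward clustering matches the naive Lance-Williams oracle", {
  for (seed in 1:4) {
    x <- with_seed(seed + 70, {
      n <- sample(8:12, 1)
      matrix(rnorm(n * 5), n, 5)
    })
    n <- nrow(x)
    rownames(x) <- sprintf("g%02d", seq_len(n))
    cl <- ward_cluster(x, 2)
    expect_lt(max(abs(sort(cl$hclust$height) - sort(naive_ward_heights(x)))),
              1e-9)
    # criterion monotonicity
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
    # nesting: cutting at k-1 merges exactly two of the k clusters
    for (k in seq(n, 3)) {
      ck <- cutree(cl$hclust, k)
      ck1 <- cutree(cl$hclust, k - 1)
      merged <- tapply(ck1, ck, function(v) length(unique(v)))
      expect_true(all(merged == 1))
      expect_equal(length(unique(ck1)), k - 1)
    }
  }
})

test_that("Ward recovers constructed groups and emits gene lists", {
  pattern <- c(1.2, -0.8, 0.3, -1.5)
  z <- rbind(matrix(rep(pattern, 4), 4, byrow = TRUE),
             matrix(rep(-pattern, 4), 4, byrow = TRUE))
  z <- z + with_seed(99, matrix(rnorm(32, 0, 0.01), 8, 4))
  rownames(z) <- c(paste0("plus", 1:4), paste0("minus", 1:4))
  colnames(z) <- paste0("s", 1:4)
  cl <- ward_cluster(z, 2)
  expect_length(cl$clusters, 2)
  groups <- lapply(cl$clusters, function(g) sub("[0-9]+$", "", g))
  expect_true(all(vapply(groups, function(g) length(unique(g)) == 1,
                         logical(1))))

  # singleton boundary
  cl8 <- ward_cluster(z, 8)
  expect_equal(lengths(cl8$clusters), setNames(rep(1L, 8),
                                               names(cl8$clusters)))
  expect_error(ward_cluster(z, 9), "more clusters")

  # heatmap layout: leaf order is a permutation, cluster blocks contiguous
  lay <- heatmap_layout(z, cl)
  expect_setequal(lay$row_order, rownames(z))
  runs <- rle(unname(lay$assignment))
  expect_equal(length(runs$values), 2)
  bad <- ward_cluster(z[1:6, ], 2)
  expect_error(heatmap_layout(z, bad), "do not match")
})

test_that("volcano categorization follows the threshold rules", {
  de <- de_table(data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log2fc = c(3, 3, -2, 0.5, 1.5),
    pvalue = c(0.001, 0.5, 0.001, 0.001, 0)))
  expect_warning(vt <- volcano_categorize(de, 0.05, 1), "floor")
  expect_equal(vt$category,
               c("sig-up", "not-sig", "sig-down", "not-sig", "sig-up"))
  expect_equal(vt$neg_log10_p[1], 3)
  expect_equal(vt$neg_log10_p[5], 300)      # p = 0 mapped to the 1e-300 floor
  expect_error(volcano_categorize(de, 0, 1), "p_threshold")
})
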