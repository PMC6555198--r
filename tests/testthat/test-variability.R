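test_that("Doane's rule matches its formula and handles edge cases", {
  # symmetric uniform grid, n = 1024: correction term vanishes -> 11 bins
  expect_equal(doane_bins((1:1024) / 1024), 11L)

  # independent hand evaluation on a skewed n = 100 fixture
  x <- exp(seq(0, 3, length.out = 100))
  n <- 100
  g1 <- (sum((x - mean(x))^3) / n) / (sum((x - mean(x))^2) / n)^1.5
  sg1 <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  expect_equal(doane_bins(x),
               as.integer(ceiling(1 + log2(n) + log2(1 + abs(g1) / sg1))))

  # more skew, same n: bin count cannot decrease
  sym <- rep(c(1, 2, 3), 30)
  skew <- c(rep(1, 85), 4000 * (1:5))
  expect_gte(doane_bins(skew), doane_bins(sym))

  expect_equal(doane_bins(rep(3, 50)), 1L)
  expect_error(doane_bins(c(1, 2)), "n >= 3")
})

test_that("entropy respects closed forms and bounds", {
  flat <- make_em(matrix(7, 10, 1))
  expect_warning(e0 <- shannon_entropy(flat, "s01"), "constant")
  expect_equal(e0$entropy_bits, 0)

  # 128 uniform grid values: Doane gives 8 bins, equal occupancy -> 3 bits
  grid <- make_em(matrix((0:127 + 0.5) / 128, 128, 1))
  e8 <- shannon_entropy(grid, "s01", log_transform = FALSE)
  expect_equal(e8$bins, 8L)
  expect_identical(e8$entropy_bits, 3)

  # bounds and shift invariance on random fixtures
  for (seed in 1:20) {
    v <- with_seed(seed, rlnorm(200, 2, 1))
    m <- make_em(cbind(v))
    e <- shannon_entropy(m, "s01", log_transform = FALSE)
    expect_gte(e$entropy_bits, 0)
    expect_lte(e$entropy_bits, log2(e$bins))
    shifted <- shannon_entropy(make_em(cbind(v + 100)), "s01",
                               log_transform = FALSE)
    expect_equal(shifted$entropy_bits, e$entropy_bits)
  }

  all_samples <- shannon_entropy(rand_counts(100, 3, seed = 2))
  expect_equal(nrow(all_samples), 3)
  expect_error(shannon_entropy(make_em(matrix(1:2, 2, 1)), "s01"), "3 genes")
})

test_that("noise matrix implements population CV^2 with exclusions", {
  x <- c(2, 8, 50)
  m <- make_em(cbind(x, 3 * x), samples = c("A", "B"))
  nm <- noise_matrix(m)
  expect_equal(nm$values["A", "B"], 0.25)     # (x, 3x) -> exactly 1/4
  expect_equal(diag(nm$values), setNames(c(0, 0), c("A", "B")))

  dup <- make_em(cbind(x, x), samples = c("A", "B"))
  expect_equal(noise_matrix(dup)$values["A", "B"], 0)

  # zero-mean gene pairs are excluded from the average
  with0 <- make_em(rbind(c(0, 0), c(4, 8)), genes = c("null", "g"),
                   samples = c("A", "B"))
  n0 <- noise_matrix(with0)
  expect_equal(n0$genes_used["A", "B"], 1)
  expect_true(is.na(noise_pair(with0, "A", "B")["null"]))
  expect_equal(n0$values["A", "B"],
               unname(noise_pair(with0, "A", "B")["g"]))

  # scale invariance of a pair
  scaled <- make_em(cbind(10 * x, 30 * x), samples = c("A", "B"))
  expect_equal(noise_matrix(scaled)$values["A", "B"], 0.25)

  onecol <- make_em(cbind(x))
  expect_error(noise_matrix(onecol), "2 samples")
})

test_that("noise matrix equals brute-force per-gene recomputation", {
  for (seed in 1:5) {
    m <- rand_counts(20, 4, seed = seed + 300)
    v <- expr_values(m)
    nm <- noise_matrix(m)$values
    oracle <- matrix(0, 4, 4)
    for (i in 1:3) for (j in (i + 1):4) {
      cv2 <- sapply(1:20, function(g) {
        pair <- c(v[g, i], v[g, j])
        mu <- mean(pair)
        if (mu == 0) return(NA_real_)
        mean((pair - mu)^2) / mu^2
      })
      oracle[i, j] <- oracle[j, i] <- mean(cv2, na.rm = TRUE)
    }
    expect_lt(max(abs(unclass(nm) - oracle)), 1e-12)
  }
})
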