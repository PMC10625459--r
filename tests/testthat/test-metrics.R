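test_that("hand-derived distances: 3-4-5 triangle, correlations, cosine", {
  x <- rbind(c(0, 0), c(3, 4))
  expect_equal(pairwise_distance(x, "euclidean")$values[1, 2], 5)
  expect_equal(pairwise_distance(x, "manhattan")$values[1, 2], 7)
  expect_equal(pairwise_distance(x, "maximum")$values[1, 2], 4)

  y <- rbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pairwise_distance(y, "pearson")$values[1, 2], 0)   # r = 1
  y2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pairwise_distance(y2, "pearson")$values[1, 2], 2)  # r = -1
  y3 <- rbind(c(1, 0), c(0, 1))
  expect_equal(pairwise_distance(y3, "cosine")$values[1, 2], sqrt(2))
  y4 <- rbind(c(1, 2, 3), c(1, 4, 9))                              # monotone
  expect_equal(pairwise_distance(y4, "spearman")$values[1, 2], 0)
})

test_that("every metric matches the naive double-loop oracle on random data", {
  set.seed(11)
  x <- matrix(rnorm(30 * 8, mean = 3), 30, 8)
  for (m in fusecyto:::METRIC_NAMES) {
    d <- pairwise_distance(x, m)
    expect_lt(max(abs(d$values - naive_metric_oracle(x, m))), 1e-10)
    expect_identical(d$values, t(d$values))   # exact symmetry
    expect_true(all(diag(d$values) == 0))
    expect_true(all(d$values >= 0))
  }
})

test_that("distance-class metrics satisfy the triangle inequality", {
  set.seed(12)
  x <- matrix(rnorm(60 * 5), 60, 5)
  for (m in c("euclidean", "manhattan", "maximum")) {
    v <- pairwise_distance(x, m)$values
    for (rep in seq_len(400)) {
      ijk <- sample.int(60, 3)
      expect_lte(v[ijk[1], ijk[3]],
                 v[ijk[1], ijk[2]] + v[ijk[2], ijk[3]] + 1e-12)
    }
  }
})

test_that("correlation-class metrics are scale-invariant, distance-class are not", {
  set.seed(13)
  x <- matrix(rnorm(12 * 10, mean = 5), 12, 10)
  a <- runif(12, 0.5, 3); b <- runif(12, -1, 1)
  x_scaled <- x * a + b          # per-cell affine
  x_pos <- x * a                 # per-cell positive scaling only
  p0 <- pairwise_distance(x, "pearson")$values
  expect_lt(max(abs(pairwise_distance(x_scaled, "pearson")$values - p0)), 1e-10)
  c0 <- pairwise_distance(x, "cosine")$values
  expect_lt(max(abs(pairwise_distance(x_pos, "cosine")$values - c0)), 1e-10)
  s0 <- pairwise_distance(x, "spearman")$values
  x_mono <- x^3 * a              # strictly increasing per-cell transform
  expect_lt(max(abs(pairwise_distance(x_mono, "spearman")$values - s0)), 1e-10)
  e0 <- pairwise_distance(x, "euclidean")$values
  expect_gt(max(abs(pairwise_distance(x_scaled, "euclidean")$values - e0)), 1e-6)
  expect_gt(max(abs(pairwise_distance(x_scaled, "manhattan")$values -
                      pairwise_distance(x, "manhattan")$values)), 1e-6)
})

test_that("constant rows are an error under correlation metrics", {
  x <- rbind(c(1, 1, 1), c(1, 2, 3), c(2, 1, 0))
  rownames(x) <- c("cellA", "cellB", "cellC")
  for (m in c("pearson", "spearman", "cosine"))
    expect_error(pairwise_distance(x, m), "cellA")
  expect_silent(pairwise_distance(x, "euclidean"))
  expect_error(pairwise_distance(x, "mahalanobis"), "unknown metric")
})

test_that("correlation_to_distance endpoints, monotonicity and domain", {
  expect_identical(correlation_to_distance(1), 0)
  expect_identical(correlation_to_distance(-1), 2)
  expect_equal(correlation_to_distance(0), sqrt(2))
  r <- seq(-1, 1, length.out = 101)
  expect_true(all(diff(correlation_to_distance(r)) < 0))
  expect_equal(correlation_to_distance(1 + 1e-13), 0)  # clamped
  expect_error(correlation_to_distance(1.001), "outside")
})

test_that("sqrt(2(1-r)) equals z-score euclidean distance over sqrt(M)", {
  set.seed(14)
  for (i in seq_len(50)) {
    m <- sample(3:30, 1)
    a <- rnorm(m); b <- rnorm(m)
    z <- function(v) (v - mean(v)) / (sd(v) * sqrt((m - 1) / m))  # population z
    lhs <- correlation_to_distance(cor(a, b))
    rhs <- sqrt(sum((z(a) - z(b))^2)) / sqrt(m)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("rank transform uses average ranks for ties", {
  expect_equal(unname(rank_transform(rbind(c(10, 30, 20)))[1, ]), c(1, 3, 2))
  expect_equal(unname(rank_transform(rbind(c(5, 5, 1)))[1, ]), c(2.5, 2.5, 1))
  expect_equal(unname(rank_transform(rbind(c(7, 7, 7)))[1, ]), c(2, 2, 2))
})
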