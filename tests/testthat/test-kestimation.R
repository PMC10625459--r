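blob_protos <- function(k, n_per = 25, m = 6, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(runif(k * m, 0, 1), k)
  centers <- centers * sep * 2.5 / max(1e-9, min(dist(centers)))  # enforce sep
  make_blobs(n_per, centers, sd = 1, seed = seed + 100)
}

test_that("gap statistic finds well-separated blobs and k=1 for one Gaussian", {
  hits <- vapply(1:10, function(s) {
    b <- blob_protos(3, seed = s)
    gap_statistic(b$x, k_range = 1:8, seed = s)$k_hat == 3L
  }, logical(1))
  expect_gte(sum(hits), 8L)
  ones <- vapply(1:10, function(s) {
    set.seed(s)
    gap_statistic(matrix(rnorm(40 * 5), 40), k_range = 1:6, seed = s)$k_hat == 1L
  }, logical(1))
  expect_gte(sum(ones), 8L)
  est <- gap_statistic(blob_protos(3, seed = 3)$x, k_range = 1:8, seed = 3)
  expect_length(est$curve, 8L)
  x <- blob_protos(3, seed = 4)$x; x[, 2] <- 1
  expect_error(gap_statistic(x, seed = 4), "zero-range")
})

test_that("silhouette: k_hat for tight blobs, oracle widths, degenerate ties", {
  b <- blob_protos(2, n_per = 20, sep = 20, seed = 5)
  d <- pairwise_distance(b$x, "euclidean")
  est <- silhouette_statistic(d, k_range = 2:8)
  expect_equal(est$k_hat, 2L)
  expect_gt(max(est$curve), 0.8)

  # per-point widths against the textbook a/b definition (brute force)
  set.seed(6)
  v <- as.matrix(dist(matrix(rnorm(20 * 3), 20)))
  lab <- sample.int(3, 20, replace = TRUE); lab[1:3] <- 1:3
  got <- fusecyto:::silhouette_widths(v, lab)
  for (i in 1:20) {
    own <- which(lab == lab[i] & seq_len(20) != i)
    a <- if (length(own)) mean(v[i, own]) else NA
    bvals <- vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(v[i, lab == cl]), numeric(1))
    s_exp <- if (!length(own)) 0 else (min(bvals) - a) / max(a, min(bvals))
    expect_equal(got[i], s_exp, tolerance = 1e-12)
  }
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(lab, dmatrix = v)[, "sil_width"]
  expect_equal(got, unname(ref), tolerance = 1e-12)

  # all points equidistant: silhouette 0 everywhere, smallest k wins
  ve <- matrix(1, 10, 10); diag(ve) <- 0
  est0 <- silhouette_statistic(ve, k_range = 2:5)
  expect_true(all(abs(est0$curve) < 1e-12))
  expect_equal(est0$k_hat, 2L)
})

test_that("jump statistic peaks at the planted k with curve bookkeeping", {
  hits <- vapply(1:10, function(s) {
    b <- blob_protos(3, seed = s + 20)
    jump_statistic(b$x, k_range = 1:8)$k_hat == 3L
  }, logical(1))
  expect_gte(sum(hits), 8L)
  est <- jump_statistic(blob_protos(3, seed = 21)$x, k_range = 1:8)
  expect_length(est$curve, 8L)
  # duplicate prototypes: epsilon floor with warning, not an error
  dup <- rbind(matrix(0, 6, 3), matrix(5, 6, 3)) +
    rep(c(0, 0), each = 6)
  expect_warning(jump_statistic(dup, k_range = 1:4), "epsilon|monotone")
})

test_that("slope statistic finds the silhouette elbow", {
  hits <- vapply(1:10, function(s) {
    b <- blob_protos(4, seed = s + 40)
    d <- pairwise_distance(b$x, "euclidean")
    slope_statistic(d, k_range = 2:9)$k_hat == 4L
  }, logical(1))
  expect_gte(sum(hits), 8L)
  est <- slope_statistic(pairwise_distance(blob_protos(4, seed = 41)$x,
                                           "euclidean"), k_range = 2:9)
  expect_length(est$curve, 7L)   # |k_range| - 1
  # constant silhouette curve -> all-zero slope, smallest k
  ve <- matrix(1, 12, 12); diag(ve) <- 0
  est0 <- slope_statistic(ve, k_range = 2:6)
  expect_true(all(abs(est0$curve) < 1e-12))
  expect_equal(est0$k_hat, 2L)
})

test_that("WCD elbow bends at the planted k and handles linear curves", {
  hits <- vapply(1:10, function(s) {
    b <- blob_protos(3, seed = s + 60)
    wcd_elbow(b$x, k_range = 1:8)$k_hat == 3L
  }, logical(1))
  expect_gte(sum(hits), 8L)
  est <- wcd_elbow(blob_protos(3, seed = 61)$x, k_range = 1:8)
  # curve nonincreasing on separated blobs
  expect_true(all(diff(est$curve) <= 1e-8))
  expect_error(wcd_elbow(blob_protos(3, seed = 62)$x, k_range = 2:3),
               "at least 3")
})

test_that("dip statistic matches the exhaustive oracle and known anchors", {
  # two equal atoms: the maximal dip 0.25
  expect_equal(dip_test(rep(c(0, 1), each = 20), b = 200, seed = 1)$statistic, 0.25)
  # oracle equality on small random samples, with and without ties
  set.seed(71)
  for (i in seq_len(25)) {
    n <- sample(4:12, 1)
    x <- if (i %% 3 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    expect_equal(fusecyto:::dip_statistic_sorted(sort(x)), dip_oracle(x),
                 tolerance = 1e-10)
  }
  expect_error(dip_test(c(1, 2, 3)), "n >= 4")
})

test_that("dip p-values: null is calibrated, bimodal data rejected", {
  # p-values approximately U(0,1) under the uniform null
  set.seed(72)
  pvals <- vapply(seq_len(200), function(i)
    dip_test(runif(50), b = 300, seed = i)$p_value, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # a clear two-component sample is detected
  set.seed(73)
  x <- c(rnorm(100), rnorm(100, 8))
  expect_lt(dip_test(x, b = 500, seed = 74)$p_value, 0.01)
  # unimodal Gaussians are mostly not rejected at the 10% level
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    dip_test(rnorm(500), b = 500, seed = s + 500)$p_value > 0.1
  }, logical(1))
  expect_gte(sum(ok), 18L)
})

test_that("discriminant projection separates classes and is rotation-equivariant", {
  set.seed(75)
  x <- rbind(matrix(rnorm(30 * 2), 30), matrix(rnorm(30 * 2), 30) +
               matrix(c(10, 0), 30, 2, byrow = TRUE))
  split <- rep(1:2, each = 30)
  proj <- max_clusterability_projection(x, split)
  w <- attr(proj, "direction")
  expect_gte(abs(w[1]), 0.99)          # direction ~ axis 1
  # identical class means: still projects (regularized), no error
  x2 <- rbind(matrix(rnorm(20 * 3), 20), matrix(rnorm(20 * 3), 20))
  expect_silent(max_clusterability_projection(x2, rep(1:2, each = 20)))
  expect_error(max_clusterability_projection(x, c(1, rep(2, 59))), "at least 2")
  # rotating the data rotates the direction with it
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  proj_rot <- max_clusterability_projection(x %*% rot, split)
  w_rot <- attr(proj_rot, "direction")
  expect_lt(min(sum((as.vector(rot %*% w_rot) - w)^2),
                sum((as.vector(rot %*% w_rot) + w)^2)), 1e-4)
})

test_that("discriminant k: one Gaussian gives 1, blobs give the truth, alpha->0 gives 1", {
  ones <- vapply(1:20, function(s) {
    set.seed(s)
    discriminant_k(matrix(rnorm(100 * 5), 100), seed = s, b = 500)$k_hat == 1L
  }, logical(1))
  expect_gte(sum(ones), 18L)
  b <- blob_protos(3, n_per = 25, seed = 81)
  est <- discriminant_k(b$x, seed = 81, b = 500)
  expect_equal(est$k_hat, 3L)
  expect_equal(sum(est$details$p_adjusted < 0.05), 2L)
  est0 <- discriminant_k(b$x, alpha = 1e-12, seed = 81, b = 500)
  expect_equal(est0$k_hat, 1L)
  expect_error(discriminant_k(matrix(rnorm(10), 5)), "at least 8")
})

test_that("every estimator returns k_hat inside its searched range", {
  b <- blob_protos(4, seed = 91)
  d <- pairwise_distance(b$x, "euclidean")
  ests <- list(gap_statistic(b$x, k_range = 1:8, seed = 91),
               silhouette_statistic(d, 2:8),
               jump_statistic(b$x, 1:8),
               slope_statistic(d, 2:8),
               wcd_elbow(b$x, 2:8))
  for (e in ests)
    expect_true(e$k_hat >= min(e$k_range) && e$k_hat <= max(e$k_range))
})
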