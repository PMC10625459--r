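test_that("grid-size estimation: floor rule, errors, spike detection", {
  set.seed(31)
  x <- matrix(rnorm(500 * 10), 500, 10)
  s <- estimate_grid_side(x)
  expect_gte(as.integer(s), 5L)               # s_min floor under (near) noise
  expect_error(estimate_grid_side(x[, 1, drop = FALSE]), "2 markers")
  xz <- x; xz[, 3] <- 7
  colnames(xz) <- paste0("m", 1:10)
  expect_error(estimate_grid_side(xz), "m3")

  # 5 strong planted rank-1 signals are found in >= 18/20 seeds
  hits <- vapply(seq_len(20), function(seed) {
    set.seed(seed)
    f <- matrix(rnorm(600 * 5), 600, 5)
    l <- matrix(rnorm(5 * 16, sd = 1.5), 5, 16)
    x <- f %*% l + matrix(rnorm(600 * 16), 600, 16)
    attr(estimate_grid_side(x), "k_sig") >= 5L
  }, logical(1))
  expect_gte(sum(hits), 18L)
  # and the grid side scales as ceil(sqrt(5 * k_sig))
  set.seed(1)
  f <- matrix(rnorm(600 * 5), 600, 5)
  l <- matrix(rnorm(5 * 16, sd = 1.5), 5, 16)
  s2 <- estimate_grid_side(f %*% l + matrix(rnorm(600 * 16), 600, 16))
  expect_equal(as.integer(s2),
               max(5L, as.integer(ceiling(sqrt(5 * attr(s2, "k_sig"))))))
})

test_that("null calibration: false-positive rate of >=1 signal is ~ alpha", {
  # 200 iid-noise datasets; P(k_sig >= 1) should sit in the binomial 95%
  # band around alpha = 0.05, i.e. [4, 16] detections out of 200
  set.seed(32)
  fp <- vapply(seq_len(200), function(i) {
    x <- matrix(rnorm(2000 * 20), 2000, 20)
    attr(estimate_grid_side(x), "k_sig") >= 1L
  }, logical(1))
  expect_gte(sum(fp), qbinom(0.025, 200, 0.05))
  expect_lte(sum(fp), qbinom(0.975, 200, 0.05))
})

test_that("batch SOM: fixed point, QE decrease, determinism", {
  # all cells at one point: every prototype converges there
  x <- matrix(5, 40, 3) + 0  # identical cells
  m <- fit_som(x, som_grid(2), epochs = 8, seed = 1)
  expect_lt(max(abs(m$prototypes - 5)), 1e-6)

  blobs <- make_blobs(60, rbind(c(0, 0), c(12, 12)), seed = 2)
  m2 <- fit_som(blobs$x, som_grid(2), epochs = 10, seed = 3)
  qe <- m2$quantization_error_trace
  expect_lt(qe[length(qe)], qe[1])
  # prototypes split across the blobs
  bmu_lab <- cutree(hclust(dist(m2$prototypes), "average"), 2)[m2$bmu]
  expect_gt(adjusted_rand_index(bmu_lab, blobs$labels), 0.95)

  m3 <- fit_som(blobs$x, som_grid(2), epochs = 10, seed = 3)
  expect_identical(m2$prototypes, m3$prototypes)   # bitwise determinism
  expect_identical(m2$bmu, m3$bmu)

  expect_error(fit_som(blobs$x[1:3, ], som_grid(2)), "prototypes")
  expect_error(fit_som(blobs$x, som_grid(2), epochs = 0), "epochs")
})

test_that("BMU assignment matches a per-row scan oracle and breaks ties low", {
  set.seed(33)
  x <- matrix(rnorm(200 * 6), 200, 6)
  m <- fit_som(x, som_grid(3), epochs = 5, seed = 4)
  got <- assign_bmu(m, x)
  naive <- apply(x, 1, function(row)
    which.min(colSums((t(m$prototypes) - row)^2)))
  expect_identical(got, as.integer(naive))
  # exact prototype hit
  expect_identical(assign_bmu(m, m$prototypes[7, , drop = FALSE]), 7L)
  # equidistant between prototypes 2 and 5 -> lowest index (2) wins
  m_tie <- m
  m_tie$prototypes <- rbind(c(100, 0), c(0, 0), c(100, 100),
                            c(-100, 50), c(2, 0), c(100, -100))
  expect_identical(assign_bmu(m_tie, matrix(c(1, 0), 1)), 2L)
  expect_error(assign_bmu(m, x[, 1:3]), "columns")
})

test_that("quantization error: zero at prototypes, closed form, monotone", {
  set.seed(34)
  x <- matrix(rnorm(50 * 4), 50, 4)
  m <- fit_som(x, som_grid(3), epochs = 4, seed = 5)
  expect_equal(quantization_error(m, m$prototypes), 0)
  # single effective prototype at the mean of 3 points
  pts <- rbind(c(0, 0), c(3, 0), c(0, 3))
  m1 <- m; m1$prototypes <- matrix(colMeans(pts), 1, 2)
  expect_equal(quantization_error(m1, pts),
               mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))))
  # duplicating a prototype never increases QE
  m2 <- m; m2$prototypes <- rbind(m$prototypes, m$prototypes[1, ])
  expect_lte(quantization_error(m2, x), quantization_error(m, x) + 1e-12)
})

test_that("trained SOM preserves topology on smooth 2-D manifold data", {
  set.seed(35)
  n <- 1500
  latent <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  x <- cbind(latent, 0.5 * latent[, 1] + 0.5 * latent[, 2],
             latent[, 1] - latent[, 2]) +
    matrix(rnorm(n * 4, sd = 0.1), n, 4)
  m <- fit_som(x, som_grid(5), epochs = 10, seed = 6)
  pos <- m$grid$positions
  gd <- as.matrix(dist(pos))
  fd <- as.matrix(dist(m$prototypes))
  adj <- gd > 0 & gd < 1.5    # grid neighbors (incl. diagonal)
  far <- gd >= 1.5
  expect_lt(mean(fd[adj]), mean(fd[far]))
})
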