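sim_small <- function(seed = 71, n = 400, types = 3)
  simulate_cytometry(simulation_spec(n_cells = n, n_markers = 8,
                                     n_types = types, mean_separation = 8,
                                     seed = seed))

test_that("fixed-size subsampling: sizes, determinism, distinct repeats", {
  em <- sim_small()
  subs <- subsample_fixed(em, size = 100, n_repeats = 5, seed = 72)
  expect_length(subs, 5L)
  for (s in subs) expect_equal(nrow(s$values), 100L)
  ids <- lapply(subs, `[[`, "cell_ids")
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(ids[[i]], ids[[j]]))
  subs2 <- subsample_fixed(em, size = 100, n_repeats = 5, seed = 72)
  expect_identical(ids, lapply(subs2, `[[`, "cell_ids"))
  # size = N is a permutation of all cells
  full <- subsample_fixed(em, size = nrow(em$values), n_repeats = 1, seed = 73)
  expect_setequal(full[[1]]$cell_ids, em$cell_ids)
  expect_error(subsample_fixed(em, size = 0), "size")
  expect_error(subsample_fixed(em, size = nrow(em$values) + 1), "exceeds")
})

test_that("stratified splits take ceil(fraction * n_c) per class", {
  x <- matrix(rnorm(32), 16, 2)
  em <- expression_matrix(x, annotations = rep(c("a", "b"), c(10, 6)))
  subs <- stratified_split(em, fraction = 0.5, n_repeats = 3, seed = 74)
  for (s in subs) {
    expect_equal(sum(s$annotations == "a"), 5L)
    expect_equal(sum(s$annotations == "b"), 3L)
  }
  # fraction 1 returns the full dataset
  all_s <- stratified_split(em, fraction = 1, n_repeats = 1, seed = 75)
  expect_setequal(all_s[[1]]$cell_ids, em$cell_ids)
  em0 <- expression_matrix(x)
  expect_error(stratified_split(em0), "annotated")
})

test_that("combination sweep covers all 15 subsets consistently", {
  em <- sim_small(seed = 76)
  sw <- combination_sweep(em, k = 3, seed = 77,
                          config = run_config(seed = 77, grid_side = 5))
  expect_equal(nrow(sw), 15L)
  expect_equal(sum(sw$n_metrics == 1), 4L)
  expect_equal(sum(sw$n_metrics == 4), 1L)
  # the sweep's singleton-euclidean row reproduces a direct single-view run
  som <- fit_som(em$values, som_grid(5), epochs = 10, seed = 77)
  fused <- fuse_distances(default_view_set(som$prototypes, "euclidean"))
  pred <- project_labels(cut_to_k(hierarchical_average(fused), 3), som$bmu)
  direct <- evaluate_partitions(pred, em$annotations)
  eu_row <- sw[sw$metric_set == "euclidean", ]
  expect_equal(eu_row$ari, direct[["ari"]], tolerance = 1e-12)
  expect_equal(eu_row$nmi, direct[["nmi"]], tolerance = 1e-12)
})

test_that("benchmark bookkeeping: record counts, determinism, aggregation audit", {
  ds <- list(d1 = sim_small(seed = 78), d2 = sim_small(seed = 79, types = 4))
  cfg <- run_config(seed = 80, subsample_size = 150, n_repeats = 3,
                    grid_side = 5)
  methods <- benchmark_methods(metrics = c("pearson", "euclidean"))
  res <- run_benchmark(ds, methods, cfg)
  expect_s3_class(res, "benchmark_result")
  expect_equal(nrow(res$records), 2 * 3 * 3)  # datasets x methods x repeats
  expect_true(all(is.na(res$records$error)))
  res2 <- run_benchmark(ds, methods, cfg)
  expect_identical(res$records$ari, res2$records$ari)
  # aggregate means recomputable from raw records
  for (r in seq_len(nrow(res$aggregate))) {
    rows <- res$records[res$records$dataset == res$aggregate$dataset[r] &
                          res$records$method == res$aggregate$method[r], ]
    expect_equal(res$aggregate$ari[r], mean(rows$ari))
  }
  # ranks are a permutation per dataset per index
  for (d in unique(res$ranks$dataset))
    expect_setequal(res$ranks$rank_ari[res$ranks$dataset == d],
                    seq_len(length(methods)))
  # per-run failures are recorded, not fatal
  methods_bad <- c(methods[1],
                   list(broken = function(data, k, seed) stop("boom")))
  res3 <- run_benchmark(ds["d1"], methods_bad, cfg)
  expect_true(any(!is.na(res3$records$error)))
  expect_true(any(is.na(res3$records$ari)))
})
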