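#' Fixed-size resampling of an expression matrix
#'
#' Uniform without-replacement subsamples of exactly `size` cells, one per
#' repeat, with per-repeat seeds derived deterministically from the master
#' seed (`seed + repeat index`) so any single repeat can be reproduced in
#' isolation.
#'
#' @param data an [expression_matrix()].
#' @param size cells per subsample (`<= N`).
#' @param n_repeats number of subsamples.
#' @param seed master seed.
#' @return list of `n_repeats` expression matrices.
#' @export
subsample_fixed <- function(data, size, n_repeats = 5L, seed = 42L) {
  if (!inherits(data, "expression_matrix"))
    stop("`data` must be an expression_matrix", call. = FALSE)
  size <- stopifnot_scalar_int(size, "size", 2L)
  n <- nrow(data$values)
  if (size > n) stop("size (", size, ") exceeds N (", n, ")", call. = FALSE)
  lapply(seq_len(n_repeats), function(r) {
    idx <- with_seed(seed + r, sample.int(n, size))
    expression_matrix(data$values[idx, , drop = FALSE],
                      cell_ids = data$cell_ids[idx],
                      annotations = data$annotations[idx])
  })
}

#' Stratified per-class subsampling
#'
#' Per repeat, samples `ceiling(fraction * n_c)` cells without replacement
#' from every annotated class `c`, preserving class proportions to within
#' one cell. The default fraction of 0.5 with five repeats yields five
#' stratified half-datasets.
#'
#' @param data an [expression_matrix()] with annotations.
#' @param fraction per-class sampling fraction in (0, 1].
#' @param n_repeats number of stratified samples.
#' @param seed master seed (per-repeat seeds are `seed + repeat`).
#' @return list of `n_repeats` expression matrices.
#' @export
stratified_split <- function(data, fraction = 0.5, n_repeats = 5L, seed = 42L) {
  if (!inherits(data, "expression_matrix") || is.null(data$annotations))
    stop("`data` must be an annotated expression_matrix", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  classes <- split(seq_len(nrow(data$values)), data$annotations)
  if (min(lengths(classes)) < 2L)
    stop("every annotated class needs at least 2 cells", call. = FALSE)
  lapply(seq_len(n_repeats), function(r) {
    idx <- with_seed(seed + r, {
      sort(unlist(lapply(classes, function(ix)
        sample(ix, ceiling(fraction * length(ix))))))
    })
    expression_matrix(data$values[idx, , drop = FALSE],
                      cell_ids = data$cell_ids[idx],
                      annotations = data$annotations[idx])
  })
}

#' Sweep all metric combinations through the fused pipeline
#'
#' Fits one SOM on the data, then for each of the 15 nonempty subsets of
#' {pearson, spearman, cosine, euclidean} fuses that view subset over the
#' shared prototypes, clusters at `k`, projects to cells, and scores all
#' four indices against the annotations. Sharing the SOM isolates the
#' effect of the metric combination.
#'
#' @param data an annotated [expression_matrix()].
#' @param k number of clusters (defaults to the annotated class count).
#' @param seed integer seed.
#' @param config a [run_config()] (grid/epochs settings are honored).
#' @return data.frame with one row per metric subset: `metric_set`,
#'   `n_metrics`, `ari`, `nmi`, `fm`, `f`.
#' @export
combination_sweep <- function(data, k = NULL, seed = 42L,
                              config = run_config(seed = seed)) {
  if (!inherits(data, "expression_matrix") || is.null(data$annotations))
    stop("`data` must be an annotated expression_matrix", call. = FALSE)
  k <- k %||% length(unique(data$annotations))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  side <- config$grid_side %||%
    as.integer(estimate_grid_side(data$values, alpha = config$alpha))
  side <- max(side, as.integer(ceiling(sqrt(k))))
  som <- fit_som(data$values, som_grid(side), epochs = config$epochs,
                 seed = seed)
  base_metrics <- c("pearson", "spearman", "cosine", "euclidean")
  views <- setNames(default_view_set(som$prototypes, base_metrics), base_metrics)
  subsets <- unlist(lapply(seq_along(base_metrics), function(m)
    combn(base_metrics, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ms) {
    fused <- fuse_distances(views[ms])
    pred <- project_labels(cut_to_k(hierarchical_average(fused), k), som$bmu)
    sc <- evaluate_partitions(pred, data$annotations)
    data.frame(metric_set = paste(ms, collapse = "+"), n_metrics = length(ms),
               ari = sc[["ari"]], nmi = sc[["nmi"]], fm = sc[["fm"]],
               f = sc[["f"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a resampled clustering benchmark
#'
#' For every dataset x method x repeat: draw a subsample (stratified by
#' annotation when `stratified = TRUE`, else fixed-size uniform), cluster
#' it at the dataset's annotated class count, and score all four external
#' indices. Per-run failures are recorded, not fatal. Methods are
#' functions `f(expression_matrix, k, seed)` returning a partition or
#' label vector; [benchmark_methods()] supplies the built-ins.
#'
#' @param datasets named list of annotated [expression_matrix()] objects.
#' @param methods named list of clustering functions.
#' @param config a [run_config()]; `subsample_size`, `n_repeats`, `seed`
#'   and `alpha` are honored.
#' @param stratified use [stratified_split()] instead of
#'   [subsample_fixed()].
#' @param fraction stratified fraction when `stratified = TRUE`.
#' @return A `benchmark_result`: list with per-run `records`, mean
#'   `aggregate` per dataset x method, and descending `ranks` per index.
#' @export
run_benchmark <- function(datasets, methods = benchmark_methods(),
                          config = run_config(), stratified = FALSE,
                          fraction = 0.5) {
  if (is.null(names(datasets)) || is.null(names(methods)))
    stop("`datasets` and `methods` must be named", call. = FALSE)
  records <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    if (!inherits(ds, "expression_matrix") || is.null(ds$annotations))
      stop("dataset '", ds_name, "' must be an annotated expression_matrix",
           call. = FALSE)
    subs <- if (stratified)
      stratified_split(ds, fraction = fraction, n_repeats = config$n_repeats,
                       seed = config$seed)
    else
      subsample_fixed(ds, size = min(config$subsample_size, nrow(ds$values)),
                      n_repeats = config$n_repeats, seed = config$seed)
    for (r in seq_along(subs)) {
      sub <- subs[[r]]
      k <- length(unique(sub$annotations))
      for (m_name in names(methods)) {
        run_seed <- config$seed + r
        res <- tryCatch({
          pred <- methods[[m_name]](sub, k, run_seed)
          sc <- evaluate_partitions(part_labels(pred), sub$annotations)
          data.frame(dataset = ds_name, method = m_name, repeat_ = r,
                     seed = run_seed, ari = sc[["ari"]], nmi = sc[["nmi"]],
                     fm = sc[["fm"]], f = sc[["f"]], error = NA_character_)
        }, error = function(e)
          data.frame(dataset = ds_name, method = m_name, repeat_ = r,
                     seed = run_seed, ari = NA_real_, nmi = NA_real_,
                     fm = NA_real_, f = NA_real_,
                     error = conditionMessage(e)))
        records[[length(records) + 1L]] <- res
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  idx_cols <- c("ari", "nmi", "fm", "f")
  agg <- stats::aggregate(records[idx_cols],
                          by = records[c("dataset", "method")],
                          FUN = mean)
  ranks <- do.call(rbind, lapply(split(agg, agg$dataset), function(g) {
    for (col in idx_cols)
      g[[paste0("rank_", col)]] <- rank(-g[[col]], ties.method = "first")
    g
  }))
  rownames(ranks) <- NULL
  structure(list(records = records, aggregate = agg, ranks = ranks,
                 config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d runs (%d dataset(s) x %d method(s))\n",
              nrow(x$records), length(unique(x$records$dataset)),
              length(unique(x$records$method))))
  print(x$aggregate)
  invisible(x)
}

#' Built-in benchmark methods
#'
#' `fusesom` runs the full fused pipeline; `hclust_<metric>` clusters the
#' cells directly by average linkage under one metric. External tools
#' (graph-based or k-means baselines) can be added by the caller as
#' further `f(data, k, seed)` adapters.
#'
#' @param metrics metrics to expose as direct hierarchical baselines.
#' @return named list of clustering functions.
#' @export
benchmark_methods <- function(metrics = c("pearson", "euclidean")) {
  out <- list(
    fusesom = function(data, k, seed)
      fusesom_cluster(data, k, run_config(seed = seed))$partition)
  for (m in metrics) {
    out[[paste0("hclust_", m)]] <- local({
      metric <- m
      function(data, k, seed)
        cut_to_k(hierarchical_average(pairwise_distance(data$values, metric)), k)
    })
  }
  out
}
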