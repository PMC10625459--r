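#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering where the dissimilarity between two clusters is
#' the mean of all cross-pair dissimilarities. Average linkage is monotone:
#' merge heights never decrease, so the dendrogram has no inversions.
#'
#' @param d a `distance_matrix`, `fused_distance`, or symmetric numeric
#'   matrix with zero diagonal (`P >= 2` items).
#' @return An object of class `hclust` (the dendrogram), with item ids as
#'   labels.
#' @export
hierarchical_average <- function(d) {
  v <- dm_values(d)
  if (nrow(v) < 2L) stop("need at least 2 items", call. = FALSE)
  if (max(abs(v - t(v))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  ids <- rownames(v) %||% paste0("item", seq_len(nrow(v)))
  dd <- as.dist(v)
  attr(dd, "Labels") <- ids
  hclust(dd, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges; labels are contiguous `1..k` with no
#' empty cluster.
#'
#' @param tree an `hclust` dendrogram.
#' @param k number of clusters, `1 <= k <= P`.
#' @return A `partition` over the tree's leaves.
#' @export
cut_to_k <- function(tree, k) {
  if (!inherits(tree, "hclust")) stop("`tree` must be an hclust", call. = FALSE)
  p <- length(tree$order)
  k <- stopifnot_scalar_int(k, "k")
  if (k > p) stop("k = ", k, " exceeds number of items (", p, ")", call. = FALSE)
  labels <- unname(cutree(tree, k = k))
  new_partition(labels, method = "hierarchical_average", k = k,
                ids = tree$labels)
}

#' Project prototype cluster labels back to cells
#'
#' Each cell inherits the cluster label of its best-matching prototype.
#' Prototype clusters that own no cells are dropped and the remaining
#' labels re-compacted to `1..k'` (with a warning), so downstream
#' evaluation always sees contiguous labels.
#'
#' @param proto_partition `partition` over `P` prototypes.
#' @param bmu integer vector of per-cell prototype indices in `1..P`.
#' @return A `partition` over cells.
#' @export
project_labels <- function(proto_partition, bmu) {
  plab <- part_labels(proto_partition)
  if (any(bmu < 1L | bmu > length(plab)))
    stop("bmu index outside 1..", length(plab), call. = FALSE)
  lab <- plab[bmu]
  present <- sort(unique(lab))
  if (length(present) < length(unique(plab))) {
    warning(length(unique(plab)) - length(present),
            " prototype cluster(s) received no cells; labels re-compacted")
  }
  lab <- match(lab, present)
  new_partition(lab, method = "fusesom", k = length(present),
                seed = if (inherits(proto_partition, "partition"))
                  proto_partition$seed else NA_integer_)
}

#' FuseSOM-style end-to-end clustering
#'
#' The full pipeline: (i) estimate the SOM grid side from significant
#' covariance eigenvalues (unless `config$grid_side` overrides it) and
#' train a batch SOM; (ii) compute the configured metric views between the
#' prototypes and fuse them by max-scaled weighted summation; (iii)
#' cluster the fused dissimilarity with average linkage, cut at `k`, and
#' project prototype labels back to the cells through their best-matching
#' units. Deterministic given `config$seed`. All intermediates are
#' returned so that cluster-number estimators and benchmarks can reuse
#' them.
#'
#' @param data [expression_matrix()] or numeric matrix, `N >= 10` cells.
#' @param k desired number of clusters (>= 2).
#' @param config a [run_config()]; `metric_set` selects the views.
#' @return list with `partition` (cells), `som`, `views`, `fused`, `tree`,
#'   `proto_partition`, and `grid_side`.
#' @export
fusesom_cluster <- function(data, k, config = run_config()) {
  x <- as_values(data)
  k <- stopifnot_scalar_int(k, "k")
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (nrow(x) < 10L) stop("need at least 10 cells", call. = FALSE)
  side <- config$grid_side %||%
    as.integer(estimate_grid_side(x, alpha = config$alpha))
  ## the grid must offer at least k prototypes (and never exceed N)
  side <- max(side, as.integer(ceiling(sqrt(k))))
  side <- min(side, as.integer(floor(sqrt(nrow(x)))))
  grid <- som_grid(side)
  som <- fit_som(x, grid, epochs = config$epochs, seed = config$seed)
  views <- default_view_set(som$prototypes, metrics = config$metric_set)
  fused <- fuse_distances(views)
  tree <- hierarchical_average(fused)
  proto_part <- cut_to_k(tree, k)
  proto_part$seed <- config$seed
  cells <- project_labels(proto_part, som$bmu)
  if (inherits(data, "expression_matrix")) cells$ids <- data$cell_ids
  list(partition = cells, som = som, views = views, fused = fused,
       tree = tree, proto_partition = proto_part, grid_side = side)
}
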