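#' Fuse several distance views into one dissimilarity matrix
#'
#' Multiview integration of distance matrices computed over the same items
#' (typically SOM prototypes) under different metrics. Metrics live on
#' incommensurate scales (a Manhattan distance can dwarf a correlation
#' distance), so each view is first range-normalized by its own maximum
#' off-diagonal entry; the fused matrix is then the weighted sum
#' \eqn{D_{fused} = \sum_i w_i D_i} with the weights normalized to sum to
#' 1 (equal by default). Every fused entry is therefore a convex
#' combination of the normalized view entries.
#'
#' @param views list of `distance_matrix` objects (or plain symmetric
#'   matrices), all of the same dimension and item order.
#' @param weights optional positive weights, one per view; equal when
#'   omitted.
#' @return A `fused_distance`: symmetric, zero diagonal, entries in
#'   `[0, 1]`, with the views and weights recorded.
#' @export
fuse_distances <- function(views, weights = NULL) {
  if (length(views) < 1L) stop("need at least one view", call. = FALSE)
  vals <- lapply(views, dm_values)
  p <- nrow(vals[[1L]])
  if (!all(vapply(vals, function(v) nrow(v) == p && ncol(v) == p, logical(1L))))
    stop("views have mismatched dimensions", call. = FALSE)
  metrics <- vapply(seq_along(views), function(i) {
    if (inherits(views[[i]], "distance_matrix")) views[[i]]$metric
    else paste0("view", i)
  }, character(1L))
  weights <- weights %||% rep(1, length(views))
  if (length(weights) != length(views))
    stop("need one weight per view", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  w <- weights / sum(weights)
  fused <- matrix(0, p, p)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    mx <- max(v[row(v) != col(v)])
    if (mx <= 0)
      stop("degenerate view '", metrics[i], "': all off-diagonal entries zero",
           call. = FALSE)
    fused <- fused + w[i] * (v / mx)
  }
  item_ids <- if (inherits(views[[1L]], "distance_matrix"))
    views[[1L]]$item_ids else rownames(vals[[1L]]) %||% paste0("item", seq_len(p))
  dimnames(fused) <- list(item_ids, item_ids)
  structure(list(values = fused,
                 views = data.frame(metric = metrics, weight = w),
                 normalization = "max-scaled", item_ids = item_ids),
            class = "fused_distance")
}

#' @export
print.fused_distance <- function(x, ...) {
  cat(sprintf("fused_distance: %d x %d, views: %s\n", nrow(x$values),
              ncol(x$values), paste(x$views$metric, collapse = "+")))
  invisible(x)
}

#' The canonical four-view set over prototypes
#'
#' Pearson, Spearman, cosine and Euclidean dissimilarities, in that order —
#' the metric combination that performed best across combinations of the
#' four when fused.
#'
#' @param prototypes numeric matrix of `P >= 3` prototypes.
#' @param metrics metric names to compute (default the canonical four).
#' @return list of `distance_matrix` objects, one per metric, in order.
#' @export
default_view_set <- function(prototypes,
                             metrics = c("pearson", "spearman", "cosine",
                                         "euclidean")) {
  x <- as_values(prototypes)
  if (nrow(x) < 3L) stop("need at least 3 prototypes", call. = FALSE)
  lapply(metrics, function(m) pairwise_distance(x, m))
}
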