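new_k_estimate <- function(method, k_hat, k_range, curve, alpha = NA_real_,
                           details = NULL) {
  structure(list(method = method, k_hat = as.integer(k_hat),
                 k_range = as.integer(k_range), curve = curve,
                 alpha = alpha, details = details),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("k_estimate (%s): k_hat = %d (searched %d..%d)\n", x$method,
              x$k_hat, min(x$k_range), max(x$k_range)))
  invisible(x)
}

## average-linkage tree on Euclidean prototype distances; all estimators
## cut this same tree so their W_k path matches the clustering path
proto_tree <- function(x) hierarchical_average(pairwise_distance(x, "euclidean"))

## within-cluster sum of squares for cutting `tree` at each k
wss_for_cuts <- function(x, tree, ks) {
  vapply(ks, function(k) {
    lab <- cutree(tree, k = k)
    sum(vapply(split(seq_len(nrow(x)), lab), function(idx) {
      xs <- x[idx, , drop = FALSE]
      sum(sweep(xs, 2L, colMeans(xs))^2)
    }, numeric(1L)))
  }, numeric(1L))
}

check_k_range <- function(k_range, p, lo = 1L) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 1L || any(k_range < lo) || any(k_range > p - 1L))
    stop("k_range must lie within [", lo, ", P-1]", call. = FALSE)
  sort(unique(k_range))
}

#' Gap statistic for the number of clusters
#'
#' Compares the log within-cluster sum of squares (WSS) of the observed
#' prototypes, cut from the average-linkage tree at each `k`, with its
#' expectation under `B` reference datasets drawn uniformly over each
#' feature's observed range. `Gap(k) = mean_b log W_k(ref_b) - log W_k`;
#' the estimate is the smallest `k` with
#' `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error rule), where
#' `s_k` is the reference standard deviation inflated by `sqrt(1 + 1/B)`.
#'
#' @param prototypes numeric matrix (`P` items).
#' @param k_range candidate cluster counts, within `[1, P-1]`.
#' @param B number of uniform reference datasets (>= 10).
#' @param seed integer seed for the reference draws.
#' @return A `k_estimate` with the Gap curve.
#' @export
gap_statistic <- function(prototypes, k_range = 1:10, B = 50L, seed = 42L) {
  x <- as_values(prototypes)
  k_range <- check_k_range(k_range, nrow(x), lo = 1L)
  B <- stopifnot_scalar_int(B, "B", 10L)
  rng <- apply(x, 2L, range)
  if (any(rng[2L, ] - rng[1L, ] == 0))
    stop("degenerate reference: zero-range feature(s): ",
         paste(colnames(x)[rng[2L, ] == rng[1L, ]], collapse = ", "),
         call. = FALSE)
  tree <- proto_tree(x)
  w_obs <- pmax(wss_for_cuts(x, tree, k_range), .Machine$double.xmin)
  log_w_ref <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      ref <- vapply(seq_len(ncol(x)),
                    function(j) runif(nrow(x), rng[1L, j], rng[2L, j]),
                    numeric(nrow(x)))
      log(pmax(wss_for_cuts(ref, proto_tree(ref), k_range),
               .Machine$double.xmin))
    }, numeric(length(k_range))))
  })
  gap <- colMeans(log_w_ref) - log(w_obs)
  s <- apply(log_w_ref, 2L, sd) * sqrt(1 + 1 / B)
  k_hat <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - s[i + 1L]) { k_hat <- k_range[i]; break }
  }
  new_k_estimate("gap", k_hat, k_range, setNames(gap, k_range),
                 details = list(s = s, log_w_obs = log(w_obs)))
}

## per-item silhouette widths from a full distance matrix
silhouette_widths <- function(v, labels) {
  n <- nrow(v)
  ks <- sort(unique(labels))
  z <- outer(labels, ks, "==") + 0
  sums <- v %*% z                      # n x k: summed distance to each cluster
  sizes <- colSums(z)
  own <- match(labels, ks)
  a <- sums[cbind(seq_len(n), own)] / pmax(sizes[own] - 1L, 1L)
  meand <- sweep(sums, 2L, sizes, "/")
  meand[cbind(seq_len(n), own)] <- Inf
  b <- apply(meand, 1L, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[own] == 1L] <- 0             # singleton convention
  s
}

#' Mean-silhouette estimate of the number of clusters
#'
#' Cuts the average-linkage tree of `d` at each `k` and scores the mean
#' silhouette width (how much closer each item is to its own cluster than
#' to the nearest other cluster, in `[-1, 1]`); the estimate is the `k`
#' maximizing it (ties to the smallest `k`).
#'
#' @param d a `distance_matrix`/`fused_distance` or symmetric matrix.
#' @param k_range candidate counts, within `[2, P-1]`.
#' @return A `k_estimate` with the mean-silhouette curve.
#' @export
silhouette_statistic <- function(d, k_range = 2:10) {
  v <- dm_values(d)
  k_range <- check_k_range(k_range, nrow(v), lo = 2L)
  tree <- hierarchical_average(v)
  curve <- vapply(k_range, function(k)
    mean(silhouette_widths(v, cutree(tree, k = k))), numeric(1L))
  new_k_estimate("silhouette", k_range[which.max(curve)], k_range,
                 setNames(curve, k_range))
}

#' Jump statistic for the number of clusters
#'
#' The distortion `d_k = W_k / (P * M)` is raised to a negative power `Y`
#' (default `M/2`, the transformation under which a Gaussian-mixture
#' distortion curve jumps most sharply at the true component count) and
#' the estimate is the `k` with the largest jump
#' `J_k = d_k^{-Y} - d_{k-1}^{-Y}` (with `d_0^{-Y} = 0`).
#'
#' @inheritParams gap_statistic
#' @param power the jump exponent `Y > 0`; default `ncol(prototypes)/2`.
#' @return A `k_estimate` with the jump curve.
#' @export
jump_statistic <- function(prototypes, k_range = 1:10, power = NULL) {
  x <- as_values(prototypes)
  k_range <- check_k_range(k_range, nrow(x), lo = 1L)
  power <- power %||% (ncol(x) / 2)
  if (power <= 0) stop("`power` must be positive", call. = FALSE)
  tree <- proto_tree(x)
  ks <- sort(unique(c(k_range, pmax(k_range - 1L, 1L))))
  w <- wss_for_cuts(x, tree, ks)
  if (any(diff(w) > 1e-8 * max(w)))
    warning("W_k increased along the tree-cut path; distortion curve is not monotone")
  if (any(w == 0)) {
    warning("zero within-cluster sum of squares (duplicate prototypes); applying epsilon floor")
    w <- pmax(w, .Machine$double.eps * max(max(w), 1))
  }
  d_of <- setNames(w / (nrow(x) * ncol(x)), ks)
  jump <- vapply(k_range, function(k) {
    prev <- if (k - 1L >= 1L) d_of[[as.character(k - 1L)]]^(-power) else 0
    d_of[[as.character(k)]]^(-power) - prev
  }, numeric(1L))
  new_k_estimate("jump", k_range[which.max(jump)], k_range,
                 setNames(jump, k_range))
}

#' Slope statistic for the number of clusters
#'
#' Scores `-(s(k+1) - s(k)) * s(k)^v` on the mean-silhouette curve `s`:
#' large values flag the `k` after which the silhouette stops improving
#' (the elbow). The curve has one fewer point than `k_range`.
#'
#' @inheritParams silhouette_statistic
#' @param v_exp the silhouette exponent `v > 0` (default 1).
#' @return A `k_estimate`.
#' @export
slope_statistic <- function(d, k_range = 2:10, v_exp = 1) {
  v <- dm_values(d)
  k_range <- check_k_range(k_range, nrow(v), lo = 2L)
  if (v_exp <= 0) stop("`v_exp` must be positive", call. = FALSE)
  if (length(k_range) < 2L) stop("k_range must span at least 2 values", call. = FALSE)
  tree <- hierarchical_average(v)
  s <- vapply(k_range, function(k)
    mean(silhouette_widths(v, cutree(tree, k = k))), numeric(1L))
  m <- length(k_range)
  slope <- -(s[-1L] - s[-m]) * s[-m]^v_exp
  new_k_estimate("slope", k_range[which.max(slope)], k_range,
                 setNames(slope, k_range[-m]), details = list(silhouette = s))
}

#' Within-cluster-distance elbow estimate
#'
#' The mean within-cluster pairwise distance shrinks as `k` grows; the
#' estimate is the interior `k` where the curve bends most (largest
#' discrete second difference), ties to the smallest such `k`.
#'
#' @inheritParams gap_statistic
#' @return A `k_estimate` with the WCD curve.
#' @export
wcd_elbow <- function(prototypes, k_range = 2:10) {
  x <- as_values(prototypes)
  k_range <- check_k_range(k_range, nrow(x), lo = 1L)
  if (length(k_range) < 3L)
    stop("k_range must span at least 3 values", call. = FALSE)
  v <- dm_values(pairwise_distance(x, "euclidean"))
  tree <- proto_tree(x)
  curve <- vapply(k_range, function(k) {
    lab <- cutree(tree, k = k)
    same <- outer(lab, lab, "==") & upper.tri(v)
    if (!any(same)) return(0)
    mean(v[same])
  }, numeric(1L))
  m <- length(k_range)
  d2 <- curve[seq_len(m - 2L)] - 2 * curve[seq(2L, m - 1L)] + curve[seq(3L, m)]
  new_k_estimate("wcd", k_range[1L + which.max(d2)], k_range,
                 setNames(curve, k_range), details = list(second_diff = d2))
}

#' Hartigan-type dip test of unimodality
#'
#' The dip statistic is the smallest uniform-band half-width within which
#' the empirical CDF can be matched by some unimodal CDF (convex rising
#' flank, then concave flank, with a jump allowed only at the mode). Large
#' values indicate at least bimodality; the maximum possible dip, 0.25, is
#' attained by two equal point masses. The p-value is Monte Carlo,
#' comparing against dips of `b` uniform samples of the same size (the
#' least favorable unimodal null).
#'
#' @param x numeric vector, `n >= 4`.
#' @param b Monte Carlo replicates for the p-value.
#' @param seed integer seed for the null draws.
#' @return A `dip_result`: list with `statistic`, `p_value`, `n`, `b`.
#' @export
dip_test <- function(x, b = 2000L, seed = 42L) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("dip test needs n >= 4", call. = FALSE)
  if (anyNA(x)) stop("missing values in `x`", call. = FALSE)
  b <- stopifnot_scalar_int(b, "b")
  stat <- dip_statistic_sorted(sort(x))
  null <- with_seed(seed, dip_null_mc(length(x), b))
  structure(list(statistic = stat,
                 p_value = (1 + sum(null >= stat)) / (b + 1),
                 n = length(x), b = b),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip = %.4f, p = %.4g (n = %d, %d Monte Carlo reps)\n",
              x$statistic, x$p_value, x$n, x$b))
  invisible(x)
}

#' Maximum-clusterability discriminant projection
#'
#' Projects points onto the direction that maximizes between-class
#' separation relative to within-class spread for a two-class split (the
#' two-class discriminant direction `(S_w + lambda I)^{-1} (m_1 - m_2)`,
#' with the within-class scatter ridge-regularized by a trace-scaled
#' identity so degenerate splits still project).
#'
#' @param points numeric matrix.
#' @param split two-group labels (logical or two-level vector), each class
#'   with at least 2 members.
#' @return numeric vector of 1-D projections (unit-norm direction as
#'   attribute `direction`).
#' @export
max_clusterability_projection <- function(points, split) {
  x <- as_values(points)
  f <- as.integer(factor(split))
  if (length(f) != nrow(x) || length(unique(f)) != 2L)
    stop("`split` must give two classes over the rows", call. = FALSE)
  if (min(tabulate(f)) < 2L)
    stop("each class needs at least 2 members", call. = FALSE)
  x1 <- x[f == 1L, , drop = FALSE]; x2 <- x[f == 2L, , drop = FALSE]
  delta <- colMeans(x1) - colMeans(x2)
  sw <- crossprod(sweep(x1, 2L, colMeans(x1))) +
    crossprod(sweep(x2, 2L, colMeans(x2)))
  lam <- 1e-6 * mean(diag(sw))
  if (lam <= 0) lam <- 1e-6
  w <- solve(sw + lam * diag(ncol(x)), delta)
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  structure(as.vector(x %*% w), direction = as.vector(w))
}

## members of each internal node of an hclust tree
merge_members <- function(merge) {
  p <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    get1 <- function(v) if (v < 0L) -v else members[[v]]
    members[[i]] <- c(get1(merge[i, 1L]), get1(merge[i, 2L]))
  }
  members
}

#' Discriminant estimate of the number of clusters
#'
#' Builds the average-linkage tree of the prototypes, and for every
#' internal node whose two children jointly contain at least
#' `min_node_size` points (each child with >= 2), projects the node's
#' points onto the two-class discriminant direction
#' ([max_clusterability_projection()]) and dip-tests the projections for
#' multimodality. Node p-values are adjusted for family-wise error (Holm
#' step-down by default) and the estimate is the number of significant
#' nodes plus one: `s` significant binary splits imply `s + 1` groups.
#'
#' Because the projection direction is chosen to separate the node's two
#' children, even projections of unimodal data look somewhat bimodal; a
#' plain uniform dip null would therefore reject far too often, especially
#' at small nodes. The per-node null is instead selection-matched: each
#' Monte Carlo replicate draws an n-matched isotropic Gaussian sample in
#' the same dimension, splits it in two by 2-means (standing in for the
#' dendrogram's binary split), projects it onto its own discriminant
#' direction, and takes the dip — so the p-value measures evidence beyond
#' what the split-then-project selection alone produces.
#'
#' @param prototypes numeric matrix, `P >= 8`.
#' @param alpha family-wise significance level.
#' @param min_node_size smallest node (children combined) that is tested.
#' @param seed integer seed for the dip null draws.
#' @param b Monte Carlo replicates per dip test.
#' @param adjust `"holm"` (valid under arbitrary dependence) or
#'   `"bonferroni"`.
#' @return A `k_estimate`; `details` holds the per-node table.
#' @export
discriminant_k <- function(prototypes, alpha = 0.05, min_node_size = 10L,
                           seed = 42L, b = 2000L, adjust = c("holm", "bonferroni")) {
  x <- as_values(prototypes)
  if (nrow(x) < 8L) stop("need at least 8 prototypes", call. = FALSE)
  adjust <- match.arg(adjust)
  min_node_size <- stopifnot_scalar_int(min_node_size, "min_node_size", 2L)
  tree <- proto_tree(x)
  members <- merge_members(tree$merge)
  child_members <- function(i, which) {
    v <- tree$merge[i, which]
    if (v < 0L) -v else members[[v]]
  }
  nodes <- integer(0); stats <- numeric(0); pvals <- numeric(0); ns <- integer(0)
  null_cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (i in seq_along(members)) {
      left <- child_members(i, 1L); right <- child_members(i, 2L)
      if (length(left) < 2L || length(right) < 2L) next
      if (length(left) + length(right) < min_node_size) next
      idx <- c(left, right)
      proj <- max_clusterability_projection(
        x[idx, , drop = FALSE],
        rep(c(1L, 2L), c(length(left), length(right))))
      stat <- dip_statistic_sorted(sort(proj))
      key <- as.character(length(idx))
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- dip_null_projsplit_mc(length(idx), ncol(x), b)
      p <- (1 + sum(null_cache[[key]] >= stat)) / (b + 1)
      nodes <- c(nodes, i); ns <- c(ns, length(idx))
      stats <- c(stats, stat); pvals <- c(pvals, p)
    }
  })
  p_adj <- if (length(pvals)) p.adjust(pvals, method = adjust) else numeric(0)
  n_sig <- sum(p_adj < alpha)
  details <- data.frame(node = nodes, n = ns, statistic = stats,
                        p_value = pvals, p_adjusted = p_adj)
  new_k_estimate("discriminant", n_sig + 1L, k_range = c(1L, nrow(x)),
                 curve = setNames(p_adj, nodes), alpha = alpha,
                 details = details)
}

#' Run one (or all) cluster-number estimators on SOM prototypes
#'
#' Convenience dispatcher used by the command-line interface. Coordinate
#' methods (gap, jump, wcd, discriminant) see the prototype matrix;
#' dissimilarity methods (silhouette, slope) see the Euclidean prototype
#' distances.
#'
#' @param prototypes numeric matrix.
#' @param method one of `"gap"`, `"silhouette"`, `"jump"`, `"slope"`,
#'   `"wcd"`, `"discriminant"`, or `"all"`.
#' @param k_range candidate counts for the curve-based methods.
#' @param seed integer seed.
#' @param ... passed to the individual estimator.
#' @return A `k_estimate`, or a named list of them for `"all"`.
#' @export
estimate_k <- function(prototypes, method = "discriminant", k_range = 2:10,
                       seed = 42L, ...) {
  x <- as_values(prototypes)
  methods <- c("gap", "silhouette", "jump", "slope", "wcd", "discriminant")
  if (identical(method, "all")) {
    out <- lapply(methods, function(m)
      estimate_k(x, m, k_range = k_range, seed = seed, ...))
    return(setNames(out, methods))
  }
  if (!method %in% methods) stop("unknown method: ", method, call. = FALSE)
  d <- function() pairwise_distance(x, "euclidean")
  switch(method,
    gap = gap_statistic(x, k_range = sort(unique(c(1L, k_range))), seed = seed, ...),
    silhouette = silhouette_statistic(d(), k_range = k_range, ...),
    jump = jump_statistic(x, k_range = sort(unique(c(1L, k_range))), ...),
    slope = slope_statistic(d(), k_range = k_range, ...),
    wcd = wcd_elbow(x, k_range = k_range, ...),
    discriminant = discriminant_k(x, seed = seed, ...))
}
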