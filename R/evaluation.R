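new_partition <- function(labels, method = "unknown", k = length(unique(labels)),
                          seed = NA_integer_, ids = NULL) {
  structure(list(labels = as.integer(labels), method = method,
                 k = as.integer(k), seed = seed, ids = ids),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d items in %d clusters (method: %s)\n",
              length(x$labels), length(unique(x$labels)), x$method))
  invisible(x)
}

part_labels <- function(x) {
  if (inherits(x, "partition")) return(x$labels)
  if (is.factor(x) || is.character(x)) return(as.integer(factor(x)))
  as.integer(x)
}

#' Contingency table of two partitions
#'
#' `counts[i, j]` is the number of items placed in group `i` of `x` and
#' group `j` of `y`; all pair-counting indices are computed from it.
#'
#' @param x,y partitions of the same items (`partition` objects, integer
#'   vectors, or factors).
#' @return A `contingency_table`: list with integer matrix `counts` and
#'   total `n`.
#' @export
contingency <- function(x, y) {
  lx <- part_labels(x); ly <- part_labels(y)
  if (length(lx) != length(ly))
    stop("partitions have different lengths", call. = FALSE)
  counts <- unname(table(lx, ly))
  structure(list(counts = matrix(as.integer(counts), nrow(counts)),
                 n = length(lx)),
            class = "contingency_table")
}

## Pairwise confusion counts over all unordered item pairs.
pair_confusion <- function(x, y) {
  ct <- contingency(x, y)
  nij <- ct$counts
  a <- rowSums(nij); b <- colSums(nij); n <- ct$n
  ch2 <- function(v) sum(v * (v - 1) / 2)
  TP <- ch2(nij)
  FP <- ch2(a) - TP   # same in x, different in y
  FN <- ch2(b) - TP
  TN <- n * (n - 1) / 2 - TP - FP - FN
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, rescaled so that the
#' expected value under random labelings (with fixed margins) is 0 and the
#' maximum is 1. Negative values indicate less agreement than chance.
#' When the adjustment denominator is exactly 0 (both partitions
#' degenerate), returns 1 if the two partitions are identical as set
#' partitions and 0 otherwise.
#'
#' @param x,y partitions of the same `n >= 2` items. Conventionally `x` is
#'   the algorithm output and `y` the curated annotation, but ARI is
#'   symmetric.
#' @return a number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(x, y) {
  ct <- contingency(x, y)
  if (ct$n < 2L) stop("need at least 2 items", call. = FALSE)
  nij <- ct$counts
  a <- rowSums(nij); b <- colSums(nij); n <- ct$n
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(nij)
  exp_ij <- ch2(a) * ch2(b) / (n * (n - 1) / 2)
  max_ij <- (ch2(a) + ch2(b)) / 2
  if (max_ij == exp_ij) {   # both all-singletons or both one cluster
    same <- all(rowSums(nij > 0) <= 1L) && all(colSums(nij > 0) <= 1L)
    return(if (same) 1 else 0)
  }
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

#' Normalized mutual information
#'
#' `2 I(X;Y) / (H(X) + H(Y))` with natural-log entropies computed from the
#' empirical joint frequencies; 0 for independent partitions, 1 for
#' identical ones. When both partitions are the single-cluster partition
#' (both entropies zero) the 0/0 is resolved to 1.
#'
#' @inheritParams adjusted_rand_index
#' @return a number in `[0, 1]`.
#' @export
normalized_mutual_information <- function(x, y) {
  ct <- contingency(x, y)
  p <- ct$counts / ct$n
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- ent(px); hy <- ent(py)
  if (hx + hy == 0) return(1)
  pe <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / pe[nz]))
  mi <- max(mi, 0)  # guard tiny negative rounding
  2 * mi / (hx + hy)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)` over all unordered item pairs; 0 when no pair is co-placed
#' in both partitions.
#'
#' @inheritParams adjusted_rand_index
#' @return a number in `[0, 1]`.
#' @export
fowlkes_mallows <- function(x, y) {
  pc <- pair_confusion(x, y)
  if (pc$TP + pc$FP == 0 && pc$TP + pc$FN == 0)
    stop("both partitions are all singletons: no co-placed pairs", call. = FALSE)
  if (pc$TP == 0) return(0)
  pc$TP / sqrt((pc$TP + pc$FP) * (pc$TP + pc$FN))
}

#' Pairwise F-measure
#'
#' Harmonic mean of the same pairwise precision and recall used by
#' [fowlkes_mallows()] (so F-measure <= FM-index always, by the AM-GM
#' inequality applied to 1/P and 1/R). The first argument is treated as
#' the prediction and the second as the truth; 0 when `P + R = 0`.
#'
#' @inheritParams adjusted_rand_index
#' @return a number in `[0, 1]`.
#' @export
f_measure <- function(x, y) {
  pc <- pair_confusion(x, y)
  if (pc$TP + pc$FP == 0 && pc$TP + pc$FN == 0)
    stop("both partitions are all singletons: no co-placed pairs", call. = FALSE)
  if (pc$TP == 0) return(0)
  prec <- pc$TP / (pc$TP + pc$FP)
  rec <- pc$TP / (pc$TP + pc$FN)
  2 * prec * rec / (prec + rec)
}

#' All four external evaluation indices at once
#'
#' @param pred predicted partition.
#' @param truth reference partition (curated annotations).
#' @return named numeric vector: `ari`, `nmi`, `fm`, `f`.
#' @export
evaluate_partitions <- function(pred, truth) {
  c(ari = adjusted_rand_index(pred, truth),
    nmi = normalized_mutual_information(pred, truth),
    fm = fowlkes_mallows(pred, truth),
    f = f_measure(pred, truth))
}
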