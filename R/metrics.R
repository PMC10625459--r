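METRIC_NAMES <- c("euclidean", "manhattan", "maximum",
                  "pearson", "spearman", "cosine")
CORRELATION_METRICS <- c("pearson", "spearman", "cosine")

new_distance_matrix <- function(values, metric, item_ids = NULL) {
  item_ids <- item_ids %||% rownames(values) %||% paste0("item", seq_len(nrow(values)))
  dimnames(values) <- list(item_ids, item_ids)
  structure(list(values = values, metric = metric, item_ids = item_ids),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d x %d\n", x$metric,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

dm_values <- function(d) {
  if (inherits(d, c("distance_matrix", "fused_distance"))) d$values
  else if (is.matrix(d)) d
  else stop("expected a distance matrix", call. = FALSE)
}

#' Pairwise dissimilarity between cells (or prototypes)
#'
#' Computes the full symmetric dissimilarity matrix between the rows of
#' `data` under one of six metrics, in two classes:
#'
#' * distance-based: `euclidean` \eqn{\sqrt{\sum_m (x_{im}-x_{jm})^2}},
#'   `manhattan` \eqn{\sum_m |x_{im}-x_{jm}|}, and `maximum`
#'   (Chebyshev) \eqn{\max_m |x_{im}-x_{jm}|};
#' * correlation-based: `pearson`, `spearman` (Pearson on per-row average
#'   ranks), and `cosine`, each mapped to a dissimilarity by
#'   \eqn{\sqrt{2(1-r)}} (see [correlation_to_distance()]).
#'
#' Correlation-class metrics compare the *profile* of a cell across markers
#' and are therefore invariant to per-cell intensity rescaling, which is
#' why they are robust to cross-image staining-intensity artifacts;
#' distance-class metrics are not.
#'
#' A row that is constant across markers has no defined correlation and is
#' an error under the correlation-class metrics: degenerate cells must be
#' filtered by the caller, not silently zeroed.
#'
#' @param data numeric matrix (rows = items) or [expression_matrix()].
#' @param metric one of `"euclidean"`, `"manhattan"`, `"maximum"`,
#'   `"pearson"`, `"spearman"`, `"cosine"`.
#' @return A `distance_matrix`: symmetric, zero diagonal, entries >= 0.
#' @export
pairwise_distance <- function(data, metric) {
  x <- as_values(data)
  if (length(metric) != 1L || !metric %in% METRIC_NAMES)
    stop("unknown metric: ", paste(metric, collapse = ","), call. = FALSE)
  if (metric %in% CORRELATION_METRICS) {
    if (ncol(x) < 2L)
      stop("correlation metrics need at least 2 markers", call. = FALSE)
    const <- which(apply(x, 1L, function(r) all(r == r[1L])))
    if (length(const))
      stop(sprintf("correlation undefined for constant row(s): %s",
                   paste(head(rownames(x) %||% const, 5L)[seq_len(min(5L, length(const)))],
                         collapse = ", ")), call. = FALSE)
  }
  v <- switch(metric,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    manhattan = as.matrix(dist(x, method = "manhattan")),
    maximum   = as.matrix(dist(x, method = "maximum")),
    pearson   = correlation_to_distance(cor_rows(x)),
    spearman  = correlation_to_distance(cor_rows(rank_transform(x))),
    cosine    = correlation_to_distance(cosine_rows(x)))
  ## exact symmetry + zero diagonal by construction
  v[upper.tri(v)] <- t(v)[upper.tri(v)]
  diag(v) <- 0
  new_distance_matrix(v, metric, rownames(x))
}

## row-by-row Pearson correlation, clamped to [-1, 1]
cor_rows <- function(x) {
  r <- cor(t(x))
  pmin(pmax(r, -1), 1)
}

cosine_rows <- function(x) {
  g <- tcrossprod(x)
  nrm <- sqrt(diag(g))
  if (any(nrm == 0))
    stop("cosine undefined for all-zero row(s)", call. = FALSE)
  r <- g / outer(nrm, nrm)
  pmin(pmax(r, -1), 1)
}

#' Transform a correlation into a dissimilarity
#'
#' Maps a correlation (or cosine similarity) `r` in `[-1, 1]` to
#' \eqn{\sqrt{2(1-r)}} in `[0, 2]`: perfectly correlated profiles are at
#' distance 0, uncorrelated ones at \eqn{\sqrt 2}, anti-correlated ones at
#' 2. This equals the Euclidean distance between the z-scored profiles
#' divided by \eqn{\sqrt M}, so correlation-based clustering is Euclidean
#' clustering of standardized profiles. Values within `1e-12` of the
#' bounds are clamped; values beyond are a domain error.
#'
#' @param r numeric vector/matrix of correlations.
#' @return dissimilarities, same shape as `r`.
#' @export
correlation_to_distance <- function(r) {
  tol <- 1e-12
  if (any(r < -1 - tol | r > 1 + tol, na.rm = TRUE))
    stop("correlation outside [-1, 1]", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  sqrt(2 * (1 - r))
}

#' Per-row rank transform
#'
#' Replaces each row by the ranks of its entries (average ranks for ties),
#' the transform underlying the Spearman dissimilarity.
#'
#' @param data numeric matrix.
#' @return matrix of the same shape holding per-row ranks.
#' @export
rank_transform <- function(data) {
  x <- as_values(data)
  out <- t(apply(x, 1L, rank, ties.method = "average"))
  dimnames(out) <- dimnames(x)
  out
}
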