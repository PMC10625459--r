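## Published quantiles of the Tracy-Widom TW1 (GOE) distribution,
## P(TW1 <= q). Used as critical values for the sequential eigenvalue test.
TW1_QUANTILES <- data.frame(
  p = c(0.900,   0.950,    0.975,    0.990,    0.995,    0.999),
  q = c(0.45014, 0.97931,  1.45375,  2.02334,  2.42240,  3.27242)
)

tw1_critical <- function(alpha) {
  p <- 1 - alpha
  tab <- TW1_QUANTILES
  if (p < min(tab$p) || p > max(tab$p))
    stop("alpha must be in [", 1 - max(tab$p), ", ", 1 - min(tab$p),
         "] (tabulated TW1 quantiles)", call. = FALSE)
  stats::approx(tab$p, tab$q, xout = p)$y
}

#' Estimate the SOM grid side from significant covariance eigenvalues
#'
#' Counts how many leading eigenvalues of the covariance matrix of the
#' (column-centered) data are significantly larger than expected for pure
#' noise, using the Tracy-Widom law for the largest eigenvalue of a white
#' Wishart matrix, and maps that count to a square grid side.
#'
#' Sequentially, for the i-th eigenvalue, the remaining spectrum
#' \eqn{\lambda_i \ge \dots \ge \lambda_M} is treated as an
#' \eqn{(M - i + 1)}-dimensional noise block whose variance is estimated by
#' its mean eigenvalue; the rescaled eigenvalue is standardized with the
#' Johnstone centering/scaling constants (with the second-order \eqn{-1/2}
#' corrections) and compared to the TW1 critical value at level `alpha`.
#' Counting stops at the first non-significant eigenvalue. Estimating the
#' noise variance from the mean of the remaining eigenvalues makes the test
#' invariant to global intensity rescaling and, at typical cytometry sizes
#' (thousands of cells, tens of markers), calibrated close to its nominal
#' level; fully variance-scaling each column first (`scale. = TRUE`) makes
#' it markedly conservative because the correlation matrix's fixed trace
#' suppresses the fluctuation the test measures.
#'
#' The grid side is `max(s_min, ceiling(sqrt(c * k_sig)))`: `c` prototypes
#' per significant component, floored at `s_min` so that even
#' near-unstructured data gets a workable grid.
#'
#' @param data [expression_matrix()] or numeric matrix, `N >= 10` cells.
#' @param alpha significance level of each sequential test.
#' @param s_min minimum grid side.
#' @param c_per_signal prototypes allotted per significant component.
#' @param scale. also scale columns to unit variance before testing
#'   (conservative; see above).
#' @return integer grid side, with attributes `k_sig` (significant
#'   eigenvalue count) and `statistics` (the standardized eigenvalues).
#' @export
estimate_grid_side <- function(data, alpha = 0.05, s_min = 5L,
                               c_per_signal = 5, scale. = FALSE) {
  x <- as_values(data)
  n_cells <- nrow(x); m <- ncol(x)
  if (m < 2L) stop("need at least 2 markers", call. = FALSE)
  if (n_cells < 10L) stop("need at least 10 cells", call. = FALSE)
  cvar <- apply(x, 2L, var)
  if (any(cvar == 0))
    stop("zero-variance marker(s): ",
         paste(colnames(x)[cvar == 0], collapse = ", "), call. = FALSE)
  x <- scale(x, center = TRUE, scale = scale.)
  lam <- eigen(crossprod(x) / (n_cells - 1), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, 0)
  crit <- tw1_critical(alpha)
  n <- n_cells - 1   # degrees of freedom after centering
  stats_seq <- rep(NA_real_, m - 1L)
  k_sig <- 0L
  for (i in seq_len(m - 1L)) {
    p_i <- m - i + 1L
    sigma2 <- mean(lam[i:m])
    if (sigma2 <= 0) break
    ell <- lam[i] * n / sigma2
    mu <- (sqrt(n - 0.5) + sqrt(p_i - 0.5))^2
    sig <- sqrt(mu) * (1 / sqrt(n - 0.5) + 1 / sqrt(p_i - 0.5))^(1 / 3)
    stats_seq[i] <- (ell - mu) / sig
    if (stats_seq[i] > crit) k_sig <- i else break
  }
  side <- max(as.integer(s_min), as.integer(ceiling(sqrt(c_per_signal * k_sig))))
  structure(side, k_sig = k_sig, statistics = stats_seq)
}

#' Define a rectangular SOM grid
#'
#' @param side_x,side_y grid sides (square by default); at least 4
#'   prototypes in total.
#' @return A `som_grid` with the `P = side_x * side_y` node coordinates.
#' @export
som_grid <- function(side_x, side_y = side_x) {
  side_x <- stopifnot_scalar_int(side_x, "side_x")
  side_y <- stopifnot_scalar_int(side_y, "side_y")
  if (side_x * side_y < 4L)
    stop("grid needs at least 4 prototypes", call. = FALSE)
  pos <- as.matrix(expand.grid(gx = seq_len(side_x), gy = seq_len(side_y)))
  structure(list(side_x = side_x, side_y = side_y, topology = "rectangular",
                 positions = pos),
            class = "som_grid")
}

## squared euclidean distances between all rows of a and b (guards < 0)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Train a batch self-organizing map
#'
#' Batch SOM on a rectangular grid: each epoch assigns every cell to its
#' nearest prototype (Euclidean best-matching unit, ties to the lowest
#' index) and then replaces every prototype by the neighborhood-weighted
#' mean of all cells, with a Gaussian kernel on grid coordinates whose
#' radius decays linearly from `max(side)/2` to 0.5 over the epochs.
#' Prototypes are initialized on the plane spanned by the first two
#' principal axes of the data (linear initialization) plus a small
#' seed-controlled jitter, so the whole fit is deterministic given the
#' seed. Prototypes that receive no neighborhood mass keep their previous
#' value.
#'
#' @param data [expression_matrix()] or numeric matrix (`N` cells).
#' @param grid a [som_grid()]; `P <= N` required.
#' @param epochs number of batch epochs (>= 1).
#' @param seed integer seed (used only for the initialization jitter).
#' @return A `som_model`: list with `grid`, `P x M` `prototypes`, per-cell
#'   `bmu`, `quantization_error_trace` (length `epochs + 1`: before each
#'   epoch's update and after the last), and `seed`.
#' @export
fit_som <- function(data, grid, epochs = 10L, seed = 42L) {
  x <- as_values(data)
  if (!inherits(grid, "som_grid")) stop("`grid` must be a som_grid", call. = FALSE)
  epochs <- stopifnot_scalar_int(epochs, "epochs")
  n <- nrow(x); m <- ncol(x)
  p <- grid$side_x * grid$side_y
  if (p > n) stop("more prototypes (", p, ") than cells (", n, ")", call. = FALSE)

  ## linear initialization along the first two principal axes
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc, nu = 0L, nv = 2L)
  v <- sv$v
  if (ncol(v) < 2L) v <- cbind(v, 0)
  sdev <- sv$d[seq_len(min(2L, length(sv$d)))] / sqrt(max(n - 1L, 1L))
  if (length(sdev) < 2L) sdev <- c(sdev, 0)
  ax <- if (grid$side_x > 1L) (grid$positions[, 1L] - (grid$side_x + 1) / 2) /
    ((grid$side_x - 1) / 2) else rep(0, p)
  ay <- if (grid$side_y > 1L) (grid$positions[, 2L] - (grid$side_y + 1) / 2) /
    ((grid$side_y - 1) / 2) else rep(0, p)
  proto <- matrix(center, p, m, byrow = TRUE) +
    outer(ax * 2 * sdev[1L], v[, 1L]) + outer(ay * 2 * sdev[2L], v[, 2L])
  proto <- proto + with_seed(seed,
    matrix(rnorm(p * m, sd = 0.01 * max(sdev[1L], 1e-8)), p, m))

  gd2 <- cross_dist2(grid$positions, grid$positions)
  r0 <- max(grid$side_x, grid$side_y) / 2
  r1 <- 0.5
  qe_trace <- numeric(epochs + 1L)
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    d2 <- cross_dist2(x, proto)
    bmu <- max.col(-d2, ties.method = "first")
    qe_trace[e] <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
    radius <- if (epochs == 1L) r1 else r0 + (e - 1) / (epochs - 1) * (r1 - r0)
    h <- exp(-gd2 / (2 * radius^2))
    counts <- tabulate(bmu, nbins = p)
    s <- matrix(0, p, m)
    agg <- rowsum(x, group = bmu)
    s[as.integer(rownames(agg)), ] <- agg
    num <- h %*% s
    den <- as.vector(h %*% counts)
    upd <- den > 1e-12
    proto[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- cross_dist2(x, proto)
  bmu <- max.col(-d2, ties.method = "first")
  qe_trace[epochs + 1L] <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
  rownames(proto) <- paste0("proto", seq_len(p))
  colnames(proto) <- colnames(x)
  structure(list(grid = grid, prototypes = proto, bmu = bmu,
                 quantization_error_trace = qe_trace, seed = seed),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d grid (%d prototypes), final QE %.4g\n",
              x$grid$side_x, x$grid$side_y, nrow(x$prototypes),
              tail(x$quantization_error_trace, 1L)))
  invisible(x)
}

#' Map rows to their best-matching unit
#'
#' @param model a fitted `som_model`.
#' @param data matrix with the same number of columns as the prototypes.
#' @return integer vector of prototype indices (Euclidean argmin, ties
#'   broken by the lowest prototype index).
#' @export
assign_bmu <- function(model, data) {
  x <- as_values(data)
  if (ncol(x) != ncol(model$prototypes))
    stop("data has ", ncol(x), " columns but prototypes have ",
         ncol(model$prototypes), call. = FALSE)
  max.col(-cross_dist2(x, model$prototypes), ties.method = "first")
}

#' Quantization error of a SOM fit
#'
#' Mean Euclidean distance from each row to its best-matching prototype.
#'
#' @inheritParams assign_bmu
#' @return nonnegative scalar.
#' @export
quantization_error <- function(model, data) {
  x <- as_values(data)
  d2 <- cross_dist2(x, model$prototypes)
  mean(sqrt(apply(d2, 1L, min)))
}
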