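# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (double loops, pair enumeration,
# bisection) and must stay independent of the package's code paths.

naive_metric_oracle <- function(x, metric) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  cord <- function(r) sqrt(max(0, 2 * (1 - r)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- x[i, ]; b <- x[j, ]
    D[i, j] <- switch(metric,
      euclidean = sqrt(sum((a - b)^2)),
      manhattan = sum(abs(a - b)),
      maximum   = max(abs(a - b)),
      pearson   = cord(sum((a - mean(a)) * (b - mean(b))) /
                         sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))),
      spearman  = {
        ra <- rank(a); rb <- rank(b)
        cord(sum((ra - mean(ra)) * (rb - mean(rb))) /
               sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2)))
      },
      cosine    = cord(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))
  }
  D
}

# pair-enumeration confusion counts over all unordered pairs
pair_counts_oracle <- function(x, y) {
  n <- length(x)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) tp <- tp + 1L
    else if (sx && !sy) fp <- fp + 1L
    else if (!sx && sy) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

ari_oracle <- function(x, y) {
  pc <- pair_counts_oracle(x, y)
  n2 <- choose(length(x), 2)
  sxy <- pc$TP
  sx <- pc$TP + pc$FP
  sy <- pc$TP + pc$FN
  exp_ <- sx * sy / n2
  max_ <- (sx + sy) / 2
  if (max_ == exp_) return(if (pc$FP + pc$FN == 0) 1 else 0)
  (sxy - exp_) / (max_ - exp_)
}

nmi_oracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  cj <- matrix(0L, length(ux), length(uy))
  for (i in seq_len(n)) {
    a <- match(x[i], ux); b <- match(y[i], uy)
    cj[a, b] <- cj[a, b] + 1L
  }
  pj <- cj / n
  px <- rowSums(pj); py <- colSums(pj)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (h(px) + h(py) == 0) return(1)
  mi <- 0
  for (a in seq_along(ux)) for (b in seq_along(uy))
    if (pj[a, b] > 0) mi <- mi + pj[a, b] * log(pj[a, b] / (px[a] * py[b]))
  2 * max(mi, 0) / (h(px) + h(py))
}

# O(P^3) UPGMA: returns merge heights in merge order
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  p <- nrow(d)
  size <- rep(1L, p)
  active <- rep(TRUE, p)
  heights <- numeric(p - 1L)
  for (s in seq_len(p - 1L)) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(p - 1L)) if (active[i])
      for (j in seq(i + 1L, p)) if (active[j])
        if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    heights[s] <- best
    for (k in seq_len(p)) if (active[k] && k != bi && k != bj)
      d[bi, k] <- d[k, bi] <-
        (size[bi] * d[bi, k] + size[bj] * d[bj, k]) / (size[bi] + size[bj])
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  heights
}

# Exhaustive dip oracle: bisection over the band half-width d, feasibility
# of a convex-then-concave CDF fit checked per mode placement with
# brute-force chord (convex-hull) evaluation. The mode can sit at a knot
# (where its jump absorbs that knot's mass) or inside a gap, in which case
# the flank on each side must extend to the mode itself (a virtual band
# point at the mode); the mode position within a gap is found by bisection
# using the one-sided monotonicities. Small n only.
dip_oracle <- function(x, tol = 1e-12) {
  xs <- sort(x)
  t <- unique(xs); K <- length(t)
  n <- length(xs)
  cu <- cumsum(tabulate(match(xs, t), nbins = K)) / n
  cl <- c(0, cu[-K])
  if (K == 1L) return(0)
  # does a convex function lo <= g <= up exist on knots ts? brute-force:
  # the greatest convex minorant of `up` is the chord-wise minimum
  convex_ok <- function(ts, lo, up) {
    k <- length(ts)
    if (k == 0L) return(TRUE)
    if (any(lo > up)) return(FALSE)
    if (k <= 2L) return(TRUE)
    gcm <- up
    for (i in seq_len(k - 1L)) for (m2 in seq(i + 1L, k)) {
      idx <- i:m2
      vals <- up[i] + (up[m2] - up[i]) * (ts[idx] - ts[i]) / (ts[m2] - ts[i])
      gcm[idx] <- pmin(gcm[idx], vals)
    }
    all(gcm >= lo - 1e-13)
  }
  concave_ok <- function(ts, lo, up)   # mirror: negate values
    convex_ok(ts, -up, -lo)
  feasible <- function(d) {
    lo <- pmax(cu - d, 0); up <- pmin(cl + d, 1)
    left_ok <- function(k, m)   # mode at m right of knot k; virtual upper
      convex_ok(c(t[seq_len(k)], m), c(lo[seq_len(k)], 0),
                c(up[seq_len(k)], min(cu[k] + d, 1)))
    right_ok <- function(k, m)  # suffix k+1..K; virtual lower at m
      concave_ok(c(m, t[seq(k + 1L, K)]),
                 c(max(cu[k] - d, 0), lo[seq(k + 1L, K)]),
                 c(1, up[seq(k + 1L, K)]))
    # mode outside the data
    if (concave_ok(t, lo, up)) return(TRUE)
    if (convex_ok(t, lo, up)) return(TRUE)
    # mode inside gap k: left_ok decreasing in m, right_ok increasing;
    # feasible iff left still holds at the smallest workable m
    for (k in seq_len(K - 1L)) {
      a <- t[k]; b <- t[k + 1L]
      if (!right_ok(k, b - 1e-12 * (b - a))) next
      if (left_ok(k, a + 1e-12 * (b - a))) {
        for (it in seq_len(45L)) {
          mid <- (a + b) / 2
          if (right_ok(k, mid)) b <- mid else a <- mid
        }
        if (left_ok(k, b)) return(TRUE)
      }
    }
    for (k0 in seq_len(K)) {                  # mode at knot k0 (jump there)
      li <- seq_len(k0 - 1L)
      ri <- if (k0 < K) seq(k0 + 1L, K) else integer(0)
      okL <- convex_ok(c(t[li], t[k0]), c(lo[li], 0),
                       c(up[li], min(cl[k0] + d, 1)))
      okR <- concave_ok(c(t[k0], t[ri]),
                        c(max(cu[k0] - d, 0), lo[ri]),
                        c(min(cu[k0] + d, 1), up[ri]))
      if (okL && okR) return(TRUE)
    }
    FALSE
  }
  lo_d <- 0; hi_d <- 0.5
  while (hi_d - lo_d > tol) {
    mid <- (lo_d + hi_d) / 2
    if (feasible(mid)) hi_d <- mid else lo_d <- mid
  }
  (lo_d + hi_d) / 2
}

# shorthand generators used across tests
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  k <- nrow(centers)
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

random_partition <- function(n, kmax = 4L)
  sample.int(sample.int(kmax, 1L), n, replace = TRUE)
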