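# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive quantities from first principles, without touching
# the package's implementation paths.

# O(n^2) non-dominated filter by definition (minimization).
bf_nondominated <- function(points) {
  n <- nrow(points)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(points[j, ] <= points[i, ]) &&
          any(points[j, ] < points[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# Monte-Carlo hypervolume estimate over the box [min(front), ref].
bf_hv_mc <- function(front, ref, n = 1e6, seed = 1) {
  lo <- pmin(apply(front, 2, min), ref)
  set.seed(seed)
  u <- cbind(runif(n, lo[1], ref[1]), runif(n, lo[2], ref[2]))
  dominated <- rep(FALSE, n)
  for (i in seq_len(nrow(front))) {
    dominated <- dominated |
      (u[, 1] >= front[i, 1] & u[, 2] >= front[i, 2])
  }
  mean(dominated) * prod(ref - lo)
}

# Double-loop decision-space proximity (mean over obtained of min squared
# distance to the reference set).
bf_igdx <- function(obtained, ref) {
  tot <- 0
  for (i in seq_len(nrow(obtained))) {
    best <- Inf
    for (j in seq_len(nrow(ref))) {
      d2 <- sum((obtained[i, ] - ref[j, ])^2)
      if (d2 < best) best <- d2
    }
    tot <- tot + best
  }
  tot / nrow(obtained)
}

# Plain neighborhood preserving embedding, written directly from the
# textbook recipe (kNN graph, LLE weights, generalized eigenproblem).
# Matches the package's regularization constants so the single-graph
# equivalence is exact, but shares no code with it.
direct_npe <- function(X, k, d) {
  N <- ncol(X)
  D <- nrow(X)
  dm <- as.matrix(dist(t(X)))
  diag(dm) <- Inf
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- order(dm[i, ], seq_len(N))[seq_len(k)]
    Z <- X[, nb, drop = FALSE] - X[, i]
    G <- t(Z) %*% Z
    G <- G + diag(1e-3 * max(sum(diag(G)), 1), k)
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  M <- t(diag(N) - W) %*% (diag(N) - W)
  A_mat <- X %*% M %*% t(X)
  B_mat <- X %*% t(X)
  eps <- 1e-6 * sum(diag(B_mat)) / D
  B_mat <- B_mat + diag(eps, D)
  es <- eigen(solve(B_mat, A_mat))
  ord <- order(Re(es$values))
  vecs <- Re(es$vectors[, ord[seq_len(d)], drop = FALSE])
  # B-normalize and sign-fix like the package contract
  for (j in seq_len(d)) {
    v <- vecs[, j]
    v <- v / sqrt(drop(t(v) %*% B_mat %*% v))
    if (v[which.max(abs(v))] < 0) v <- -v
    vecs[, j] <- v
  }
  list(projection = vecs, eigenvalues = sort(Re(es$values))[seq_len(d)])
}

# Textbook single-objective global-best PSO on a scalar function.
direct_pso <- function(fn, lower, upper, pop = 50, iters = 39, seed = 1) {
  set.seed(seed)
  D <- length(lower)
  x <- matrix(runif(pop * D, lower, upper), pop, D, byrow = FALSE)
  v <- matrix(0, pop, D)
  f <- apply(x, 1, fn)
  pb <- x; pf <- f
  g <- x[which.min(f), ]; gf <- min(f)
  for (t in seq_len(iters)) {
    for (i in seq_len(pop)) {
      r1 <- runif(D); r2 <- runif(D)
      v[i, ] <- 0.7298 * v[i, ] + 1.49445 * r1 * (pb[i, ] - x[i, ]) +
        1.49445 * r2 * (g - x[i, ])
      v[i, ] <- pmin(pmax(v[i, ], -0.2 * (upper - lower)),
                     0.2 * (upper - lower))
      x[i, ] <- pmin(pmax(x[i, ] + v[i, ], lower), upper)
      fi <- fn(x[i, ])
      if (fi < pf[i]) { pf[i] <- fi; pb[i, ] <- x[i, ] }
      if (fi < gf) { gf <- fi; g <- x[i, ] }
    }
  }
  gf
}

# Brute-force grid estimate of the star discrepancy of 2-D points.
bf_star_discrepancy <- function(pts, grid = 64) {
  n <- nrow(pts)
  worst <- 0
  for (a in seq_len(grid) / grid) {
    in_a <- pts[, 1] < a
    for (b in seq_len(grid) / grid) {
      frac <- sum(in_a & pts[, 2] < b) / n
      worst <- max(worst, abs(frac - a * b))
    }
  }
  worst
}

# Small two-class Gaussian classification fixture (samples x features).
make_gauss_classes <- function(n_per = 40, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  y <- rep(c("a", "b"), each = n_per)
  list(X = X, y = y)
}

# Tiny expression CSV + labels on disk; returns the two paths.
write_toy_expression <- function(dir, values, labels) {
  mpath <- file.path(dir, "expr.csv")
  lpath <- file.path(dir, "labels.txt")
  df <- data.frame(gene = rownames(values), values, check.names = FALSE)
  write.csv(df, mpath, row.names = FALSE, quote = FALSE)
  writeLines(as.character(labels), lpath)
  list(matrix = mpath, labels = lpath)
}

# A bi-objective wrapper of the sphere function; both objectives coincide,
# so Pareto dominance reduces to the scalar comparison.
sphere_problem <- function() {
  structure(list(
    name = "SPHERE2", n_var = 2L, lower = c(-5, -5), upper = c(5, 5),
    fn = function(x) {
      x <- matrix(x, ncol = 2)
      s <- rowSums(x^2)
      cbind(s, s, deparse.level = 0)
    },
    reference_ps = matrix(0, 1, 2),
    reference_pf = matrix(0, 1, 2),
    hv_reference_point = c(1, 1)
  ), class = "benchmark_problem")
}
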