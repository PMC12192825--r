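# Weighted neighborhood-preserving ensemble embedding (WNPEE).
#
# A linear projection A is sought so that each embedded sample is well
# reconstructed from its neighbours under an ensemble of KNN graphs with
# different neighbourhood sizes. Graph k contributes a row-stochastic LLE
# weight matrix W_k; the ensemble is combined with simplex weights alpha
# raised to a control exponent r > 1, giving the objective
#
#   J(A, alpha) = sum_k alpha_k^r * tr(A' X (I - W_k)' (I - W_k) X' A),
#
# minimized by alternating an exact generalized-eigenvector step for A and
# the closed-form alpha update  alpha_k prop (1 / tr_k)^(1/(r-1)).  With a
# single graph (alpha = 1) the procedure is exactly neighborhood preserving
# embedding (NPE). X holds samples in columns (D features x N samples).

#' Build an ensemble of directed KNN graphs
#'
#' Graph `g` has a directed edge `i -> j` iff `j` is among the `k_list[g]`
#' nearest Euclidean neighbours of `i`. Ties are broken by smaller sample
#' index, so the ensemble is reproducible.
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @param k_list strictly increasing positive neighbourhood sizes, all
#'   `< ncol(X)`.
#' @return list of graphs; each graph is a list with `k` and an
#'   `N x k` integer matrix `neighbors`.
#' @export
build_graph_ensemble <- function(X, k_list) {
  X <- as.matrix(X)
  N <- ncol(X)
  k_list <- as.integer(k_list)
  if (any(k_list <= 0) || is.unsorted(k_list, strictly = TRUE)) {
    stop("parameter error: k_list must be strictly increasing positive integers")
  }
  if (max(k_list) >= N) stop("parameter error: k must be < number of samples")
  nb_all <- knn_index(t(X), max(k_list))
  lapply(k_list, function(k) {
    list(k = k, neighbors = nb_all[, seq_len(k), drop = FALSE])
  })
}

#' LLE reconstruction weights for one graph
#'
#' Row `i` of the returned `N x N` matrix minimizes
#' `||x_i - sum_j W_ij x_j||^2` over the neighbours of `i`, subject to the
#' row summing to 1. Solved through the local Gram system with ridge term
#' `1e-3 * tr(G) * I` for stability when neighbours outnumber features.
#'
#' @param X feature x sample matrix.
#' @param graph one element of [build_graph_ensemble()].
#' @param ridge relative ridge coefficient for the Gram system.
#' @return a dense `N x N` row-stochastic weight matrix (zero off-graph).
#' @export
reconstruction_weights <- function(X, graph, ridge = 1e-3) {
  X <- as.matrix(X)
  N <- ncol(X)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- graph$neighbors[i, ]
    Z <- X[, nb, drop = FALSE] - X[, i]
    G <- crossprod(Z)
    tr <- sum(diag(G))
    reg <- ridge * if (tr > 0) tr else 1
    w <- tryCatch(solve(G + diag(reg, length(nb)), rep(1, length(nb))),
                  error = function(e) stop("numerical error: singular Gram system"))
    W[i, nb] <- w / sum(w)
  }
  W
}

#' Update ensemble graph weights
#'
#' Closed-form minimizer of `sum_k alpha_k^r * loss_k` over the simplex:
#' `alpha_k` proportional to `(1 / loss_k)^(1/(r-1))`. Smaller per-graph loss
#' gives larger weight. Graphs with exactly zero loss take the whole weight,
#' split equally among them (the limit case).
#'
#' @param losses per-graph reconstruction losses `tr_k >= 0`.
#' @param r ensemble control parameter, `> 1`.
#' @return non-negative weights summing to 1.
#' @export
update_alphas <- function(losses, r = 2) {
  if (r <= 1) stop("parameter error: r must be > 1")
  if (any(losses < 0)) stop("parameter error: losses must be non-negative")
  zero <- losses == 0
  if (any(zero)) {
    a <- rep(0, length(losses))
    a[zero] <- 1 / sum(zero)
    return(a)
  }
  u <- (1 / losses)^(1 / (r - 1))
  u / sum(u)
}

# Per-graph embedded-space reconstruction loss tr(Y (I-W_k)'(I-W_k) Y')
graph_losses <- function(Y, weight_matrices) {
  vapply(weight_matrices, function(W) {
    E <- Y - Y %*% t(W)
    sum(E * E)
  }, 0)
}

#' Solve the WNPEE projection for fixed graph weights
#'
#' Finds the `d` generalized eigenvectors of `X M X' a = lambda (X X' + eps I) a`
#' with the smallest eigenvalues, where
#' `M = sum_k alpha_k^r (I - W_k)'(I - W_k)`. The right-hand side is
#' regularized with `eps = 1e-6 * tr(XX') / D`, as the Gram matrix is rank
#' deficient whenever features outnumber samples. Eigenvector signs are fixed
#' by making the largest-magnitude entry positive.
#'
#' @param X feature x sample matrix (D x N).
#' @param weight_matrices list of `N x N` weight matrices from
#'   [reconstruction_weights()].
#' @param alphas ensemble weights (simplex).
#' @param d target dimension, `< min(D, N)`.
#' @param r ensemble control parameter.
#' @return list with `projection` (D x d), `embedded` (d x N), `M`,
#'   `eigenvalues`, and the scalar ensemble `loss`.
#' @export
solve_embedding <- function(X, weight_matrices, alphas, d, r = 2) {
  X <- as.matrix(X)
  D <- nrow(X)
  N <- ncol(X)
  if (d >= min(D, N)) stop("parameter error: d must be < min(D, N)")
  M <- matrix(0, N, N)
  I <- diag(N)
  for (k in seq_along(weight_matrices)) {
    E <- I - weight_matrices[[k]]
    M <- M + alphas[k]^r * crossprod(E)
  }
  A_mat <- X %*% M %*% t(X)
  B_mat <- tcrossprod(X)
  eps <- 1e-6 * sum(diag(B_mat)) / D
  if (eps <= 0) eps <- 1e-12
  B_reg <- B_mat + diag(eps, D)
  R <- tryCatch(chol(B_reg), error = function(e) {
    stop(sprintf("numerical error: XX' not positive definite (rcond ~ %.2e)",
                 1 / kappa(B_reg)))
  })
  Ri <- backsolve(R, diag(D))
  C <- crossprod(Ri, A_mat %*% Ri)
  C <- (C + t(C)) / 2
  es <- eigen(C, symmetric = TRUE)
  take <- seq(D, D - d + 1L)          # eigen() sorts decreasing; take smallest d
  vecs <- Ri %*% es$vectors[, take, drop = FALSE]
  vals <- es$values[take]
  for (j in seq_len(d)) {
    s <- sign(vecs[which.max(abs(vecs[, j])), j])
    if (s < 0) vecs[, j] <- -vecs[, j]
  }
  Y <- t(vecs) %*% X
  losses <- graph_losses(Y, weight_matrices)
  list(projection = vecs, embedded = Y, M = M, eigenvalues = vals,
       loss = sum(alphas^r * losses), graph_losses = losses)
}

#' Fit a weighted neighborhood-preserving ensemble embedding
#'
#' Builds the KNN graph ensemble, solves the reconstruction weights once per
#' graph in the input space, then alternates the projection eigen-step and
#' the closed-form graph-weight update until the ensemble loss converges.
#' The recorded loss trace is non-increasing because both steps are exact
#' minimizers of the shared objective.
#'
#' @param X feature x sample matrix (D x N).
#' @param k_list neighbourhood sizes of the graph ensemble; clipped to
#'   `N - 1`.
#' @param d target dimension (default `min(20, N - 2)`).
#' @param r ensemble control parameter (> 1).
#' @param max_iter maximum alternation count.
#' @param tol absolute loss-change tolerance for convergence.
#' @return an object of class `wnpee`: projection `A` (D x d), embedded
#'   coordinates `Y = A'X` (d x N), graph weight matrices, `alphas`,
#'   `loss_trace`, and a `converged` flag.
#' @export
fit_wnpee <- function(X, k_list = c(5, 10, 15), d = NULL, r = 2,
                      max_iter = 30, tol = 1e-8) {
  X <- as.matrix(X)
  N <- ncol(X)
  k_list <- sort(unique(pmin(as.integer(k_list), N - 1L)))
  if (is.null(d)) d <- min(20L, N - 2L)
  d <- as.integer(d)
  graphs <- build_graph_ensemble(X, k_list)
  Wk <- lapply(graphs, function(g) reconstruction_weights(X, g))
  Lg <- length(Wk)
  alphas <- rep(1 / Lg, Lg)
  loss_trace <- numeric(0)
  sol <- NULL
  for (it in seq_len(max_iter)) {
    sol <- solve_embedding(X, Wk, alphas, d, r)
    alphas <- update_alphas(sol$graph_losses, r)
    loss_trace <- c(loss_trace, sum(alphas^r * sol$graph_losses))
    if (!is.finite(tol)) break   # tol = Inf: stop after the first pass
    if (it > 1 && abs(loss_trace[it] - loss_trace[it - 1]) <= tol) break
  }
  converged <- !is.finite(tol) || length(loss_trace) < max_iter ||
    (length(loss_trace) >= 2 &&
       abs(diff(utils::tail(loss_trace, 2))) <= tol)
  if (!converged) warning("WNPEE did not converge; returning best iterate")
  structure(
    list(projection = sol$projection, embedded = sol$embedded, M = sol$M,
         eigenvalues = sol$eigenvalues, alphas = alphas, k_list = k_list,
         weight_matrices = Wk, graphs = graphs, r = r, d = d,
         loss_trace = loss_trace, converged = converged),
    class = "wnpee"
  )
}

#' Project new samples with a fitted WNPEE model
#'
#' @param object a fitted `wnpee` model.
#' @param newdata feature x sample matrix with the same feature count used
#'   in fitting.
#' @param ... unused.
#' @return embedded coordinates, `d x n` matrix.
#' @export
predict.wnpee <- function(object, newdata, ...) {
  t(object$projection) %*% as.matrix(newdata)
}

#' @export
print.wnpee <- function(x, ...) {
  cat(sprintf("WNPEE embedding: d = %d, graphs k = {%s}, r = %g\n",
              x$d, paste(x$k_list, collapse = ", "), x$r))
  cat(sprintf("  alphas: %s\n", paste(signif(x$alphas, 4), collapse = ", ")))
  cat(sprintf("  final loss %.6g after %d iterations (%s)\n",
              utils::tail(x$loss_trace, 1), length(x$loss_trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
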