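test_that("graph ensemble follows the directed-KNN contract", {
  X <- rbind(c(0, 1, 10))               # 1 feature, 3 samples on a line
  g <- build_graph_ensemble(X, 1)[[1]]
  expect_equal(g$neighbors[1, ], 2L)    # 0 -> 1
  expect_equal(g$neighbors[2, ], 1L)    # 1 -> 0
  expect_equal(g$neighbors[3, ], 2L)    # 10 -> 1

  set.seed(2)
  X2 <- matrix(rnorm(2 * 6), 2)
  gfull <- build_graph_ensemble(X2, 5)[[1]]
  expect_equal(sort(unique(as.vector(
    cbind(gfull$neighbors, seq_len(6))))), 1:6)  # complete directed graph
  expect_equal(ncol(gfull$neighbors), 5L)

  # duplicate points: ties broken to the smaller index, reproducibly
  X3 <- matrix(c(0, 0, 0, 0, 5, 5), nrow = 1)
  g3a <- build_graph_ensemble(X3, 2)[[1]]
  g3b <- build_graph_ensemble(X3, 2)[[1]]
  expect_identical(g3a, g3b)
  expect_equal(g3a$neighbors[3, ], c(1L, 2L))

  expect_error(build_graph_ensemble(X2, 6), "parameter error")
  expect_error(build_graph_ensemble(X2, c(3, 2)), "parameter error")
})

test_that("reconstruction weights solve the local least-squares problem", {
  # midpoint of two neighbours -> weights (1/2, 1/2)
  X <- rbind(c(-1, 0, 1), c(0, 0, 0))
  g <- build_graph_ensemble(X, 2)[[1]]
  W <- reconstruction_weights(X, g)
  expect_equal(unname(W[2, c(1, 3)]), c(0.5, 0.5), tolerance = 1e-9)

  # coincident with one neighbour -> weight ~ 1 there
  X2 <- rbind(c(0, 0.0001, 3, 7), c(0, 0, 0, 0))
  W2 <- reconstruction_weights(X2, build_graph_ensemble(X2, 2)[[1]])
  expect_gt(W2[1, 2], 1 - 1e-2)

  # every row beats 10,000 random simplex draws on its own objective
  set.seed(4)
  X3 <- matrix(rnorm(3 * 6), 3)
  g3 <- build_graph_ensemble(X3, 3)[[1]]
  W3 <- reconstruction_weights(X3, g3)
  expect_lt(max(abs(rowSums(W3) - 1)), 1e-10)
  for (i in 1:6) {
    nb <- g3$neighbors[i, ]
    obj <- function(w) sum((X3[, i] - X3[, nb, drop = FALSE] %*% w)^2)
    mine <- obj(W3[i, nb])
    draws <- matrix(rexp(10000 * 3), ncol = 3)
    draws <- draws / rowSums(draws)
    rnd <- apply(draws, 1, obj)
    # the ridge-regularized solution may be epsilon-suboptimal
    expect_lte(mine, min(rnd) + 1e-3 * mine + 1e-9)
  }
})

test_that("alpha updates follow the closed form and stay on the simplex", {
  expect_equal(update_alphas(c(1, 1)), c(0.5, 0.5))
  expect_equal(update_alphas(c(1, 4), r = 2), c(0.8, 0.2))
  for (r in c(1.5, 2, 4)) {
    expect_equal(update_alphas(c(1, 1, 1), r = r), rep(1, 3) / 3)
  }
  a <- update_alphas(c(0.3, 2, 0.05), r = 3)
  expect_equal(sum(a), 1)
  expect_true(all(diff(a[order(c(0.3, 2, 0.05))]) <= 0))  # smaller loss, larger alpha
  expect_equal(update_alphas(c(0, 2, 0)), c(0.5, 0, 0.5)) # zero-loss limit
  expect_error(update_alphas(c(1, 2), r = 1), "r must be")
})

test_that("embedding solves the generalized eigenproblem to tolerance", {
  set.seed(9)
  X <- matrix(rnorm(8 * 25), 8)
  fit <- fit_wnpee(X, k_list = c(3, 6), d = 3, max_iter = 10)
  B <- tcrossprod(X) + diag(1e-6 * sum(X^2) / nrow(X), nrow(X))
  AX <- X %*% fit$M %*% t(X)
  for (j in 1:3) {
    a <- fit$projection[, j]
    lam <- fit$eigenvalues[j]
    expect_lt(sqrt(sum((AX %*% a - lam * B %*% a)^2)),
              1e-6 * sqrt(sum(a^2)) * max(1, abs(lam)) * sum(abs(diag(B))))
  }
  # row stochasticity of every graph weight matrix
  for (W in fit$weight_matrices) {
    expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
  }
  expect_equal(sum(fit$alphas), 1, tolerance = 1e-12)
})

test_that("single-graph WNPEE reproduces plain NPE", {
  set.seed(5)
  X <- matrix(rnorm(6 * 20), 6)
  fit <- fit_wnpee(X, k_list = 4, d = 2, max_iter = 5)
  ref <- direct_npe(X, k = 4, d = 2)
  expect_equal(fit$eigenvalues, ref$eigenvalues, tolerance = 1e-6)
  for (j in 1:2) {
    expect_lt(max(abs(fit$projection[, j] - ref$projection[, j])), 1e-6)
  }
})

test_that("smallest eigenvalue beats any feasible one-dimensional candidate", {
  set.seed(11)
  X <- matrix(rnorm(4 * 15), 4)
  fit <- fit_wnpee(X, k_list = 14, d = 1, max_iter = 3)
  B <- tcrossprod(X) + diag(1e-6 * sum(X^2) / nrow(X), nrow(X))
  AX <- X %*% fit$M %*% t(X)
  for (j in 1:4) {
    e <- numeric(4); e[j] <- 1
    e <- e / sqrt(drop(t(e) %*% B %*% e))
    expect_lte(fit$eigenvalues[1], drop(t(e) %*% AX %*% e) + 1e-9)
  }
})

test_that("the alternation is monotone, convergent and deterministic", {
  set.seed(3)
  for (trial in 1:20) {
    X <- matrix(rnorm(10 * 30), 10)
    # tol = 0 forces the full iteration budget; the non-convergence warning
    # is expected
    fit <- suppressWarnings(
      fit_wnpee(X, k_list = c(4, 8, 12), d = 4, max_iter = 8, tol = 0))
    expect_true(all(diff(fit$loss_trace) <= 1e-9))
  }
  X <- matrix(rnorm(6 * 20), 6)
  one <- fit_wnpee(X, k_list = c(3, 6), d = 2, tol = Inf)
  expect_length(one$loss_trace, 1L)          # tol = Inf: a single pass
  a <- fit_wnpee(X, k_list = c(3, 6), d = 2)
  b <- fit_wnpee(X, k_list = c(3, 6), d = 2)
  expect_identical(a$projection, b$projection)
})

test_that("embedding commutes with sample reordering", {
  set.seed(13)
  X <- matrix(rnorm(5 * 18), 5)
  perm <- sample(18)
  f1 <- fit_wnpee(X, k_list = c(4, 7), d = 2, max_iter = 6)
  f2 <- fit_wnpee(X[, perm], k_list = c(4, 7), d = 2, max_iter = 6)
  expect_equal(f2$embedded, f1$embedded[, perm], tolerance = 1e-8)
})
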