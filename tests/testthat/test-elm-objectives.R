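test_that("ELM separates well-separated Gaussian classes and is seeded", {
  d <- make_gauss_classes(n_per = 40, sep = 4, seed = 1)
  m <- train_elm(d$X, d$y, H = 50, seed = 3)
  expect_gte(classification_accuracy(m, d$X, d$y), 95)
  m2 <- train_elm(d$X, d$y, H = 50, seed = 3)
  expect_identical(predict(m, d$X), predict(m2, d$X))
  # normal-equation residual of the output solve
  Hm <- 1 / (1 + exp(-sweep(d$X %*% m$input_weights, 2, m$biases, "+")))
  Tm <- cbind(as.integer(d$y == "a"), as.integer(d$y == "b"))
  res <- crossprod(Hm, Hm %*% m$output_weights - Tm) +
    m$ridge * m$output_weights
  expect_lt(max(abs(res)), 1e-6)
})

test_that("a single hidden unit cannot solve XOR", {
  xor_x <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(1, 1), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 1), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE))
  set.seed(8)
  xor_x <- xor_x + matrix(rnorm(nrow(xor_x) * 2, sd = 0.05), ncol = 2)
  xor_y <- rep(c("a", "a", "b", "b"), each = 20)
  accs <- vapply(1:20, function(sd) {
    classification_accuracy(train_elm(xor_x, xor_y, H = 1, seed = sd),
                            xor_x, xor_y)
  }, 0)
  expect_lte(mean(accs), 75.5)
})

test_that("accuracy is the exact percentage of agreeing labels", {
  lv <- c("a", "b")
  # the arithmetic on crafted predictions
  y <- rep(lv, each = 25)
  pred <- y; pred[1:5] <- "b"            # 45 of 50 correct
  expect_equal(100 * mean(pred == y), 90)
  d <- make_gauss_classes(n_per = 25, sep = 6, seed = 2)
  m <- train_elm(d$X, d$y, H = 30, seed = 1)
  expect_equal(classification_accuracy(m, d$X, d$y), 100)
  expect_warning(classification_accuracy(m, d$X, rep("zz", 50)), "unseen")
  expect_error(classification_accuracy(m, d$X[0, ], character(0)), "empty")
})

test_that("shuffled predictions give chance-level accuracy", {
  set.seed(10)
  y <- rep(c("a", "b"), each = 50)
  cas <- vapply(1:1000, function(i) 100 * mean(sample(y) == y), 0)
  se <- sd(cas) / sqrt(length(cas))
  expect_lt(abs(mean(cas) - 50), 3 * se + 1e-9)
})

test_that("gene_count is a strict popcount", {
  expect_identical(gene_count(c(1, 0, 1, 1)), 3L)
  expect_identical(gene_count(rep(0, 10)), 0L)
  expect_identical(gene_count(rep(1L, 2000)), 2000L)
  expect_identical(gene_count(c(TRUE, FALSE, TRUE)), 2L)
  expect_error(gene_count(c(0, 2, 1)), "contract error")
})

test_that("neighborhood preservation is zero on preserved structure", {
  set.seed(6)
  sub <- matrix(rnorm(30 * 4), 30)
  expect_equal(neighborhood_preservation(sub, sub, 5), 0)
  # feature permutation / rigid rotation preserve all neighbour orderings
  expect_equal(neighborhood_preservation(sub[, c(3, 1, 4, 2)], sub, 5), 0)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(neighborhood_preservation(sub %*% q, sub, 5), 0)
  expect_error(neighborhood_preservation(sub, sub, 30), "parameter error")
})

test_that("5-point line fixture matches the hand-enumerated value", {
  ref <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  sub <- matrix(c(10, 1, 2, 0, 11), ncol = 1)   # points 1 and 4 swapped
  expect_equal(neighborhood_preservation(ref, sub, 1), 7.6)
})

test_that("fitness evaluation is pure, memoized and ground-truth aware", {
  g <- generate_synthetic(synthetic_spec(n_genes = 60, n_samples = 90,
                                         n_classes = 3, n_informative = 5,
                                         n_redundant = 0, effect_size = 5,
                                         seed = 2))
  ctx <- gene_objectives(g$dataset, hidden_units = 50, seed = 9)
  mask <- rep(FALSE, 60); mask[1:5] <- TRUE
  f1 <- evaluate_fitness(mask, ctx)
  f2 <- evaluate_fitness(mask, ctx)
  expect_identical(f1, f2)
  expect_equal(unname(f1["NF"]), 5)
  expect_gte(f1[["CA"]], 0); expect_lte(f1[["CA"]], 100)
  expect_gte(f1[["NP"]], 0)
  empty <- evaluate_fitness(rep(FALSE, 60), ctx)
  expect_equal(unname(empty), c(0, 0, Inf))
  full <- evaluate_fitness(rep(TRUE, 60), ctx)
  expect_equal(unname(full["NF"]), 60)

  # informative mask beats random equal-size masks in most paired draws
  wins <- 0
  for (sd in 1:10) {
    set.seed(sd)
    rnd <- rep(FALSE, 60); rnd[sample(6:60, 5)] <- TRUE
    if (f1[["CA"]] > evaluate_fitness(rnd, ctx)[["CA"]]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("adding pure-noise genes to the informative set hurts accuracy", {
  wins <- 0
  for (sd in 1:20) {
    g <- generate_synthetic(synthetic_spec(n_genes = 80, n_samples = 90,
                                           n_classes = 3, n_informative = 5,
                                           n_redundant = 0, effect_size = 5,
                                           seed = 300 + sd))
    ctx <- gene_objectives(g$dataset, hidden_units = 50, reference = "raw",
                           seed = sd)
    base <- rep(FALSE, 80); base[1:5] <- TRUE
    noisy <- base; noisy[31:70] <- TRUE
    ca0 <- evaluate_fitness(base, ctx)[["CA"]]
    ca1 <- evaluate_fitness(noisy, ctx)[["CA"]]
    if (ca1 < ca0) wins <- wins + 1
  }
  # one-sided binomial: >= 15/20 rejects "no effect" at alpha = 0.01
  expect_gte(wins, 15)
})

test_that("cross-validated accuracy ranks the true markers above noise", {
  g <- generate_synthetic(synthetic_spec(n_genes = 40, n_samples = 100,
                                         n_classes = 2, n_informative = 3,
                                         n_redundant = 0, effect_size = 5,
                                         seed = 77))
  ctx <- gene_objectives(g$dataset, hidden_units = 50, reference = "raw",
                         seed = 1)
  expect_gt(cv_accuracy(1:3, ctx), cv_accuracy(10:12, ctx))
  expect_equal(cv_accuracy(integer(0), ctx), 0)
})
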