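test_that("DE mutation and the adaptive term follow the update equations", {
  expect_equal(de_mutant(c(1, 1), c(2, 2), c(0, 0), F = 0.5), c(2, 2))
  expect_equal(de_mutant(c(3, -1), c(2, 2), c(2, 2), F = 0.9), c(3, -1))
  expect_equal(de_mutant(c(1, 2), c(5, 5), c(1, 1), F = 0), c(1, 2))
  expect_equal(adaptive_velocity_term(c(1, 1), c(1, 1), K = 0.7), c(0, 0))
  expect_equal(adaptive_velocity_term(c(2, -1), c(1, 1), K = 1), c(1, -2))
})

test_that("rank-adaptive K maps front extremes onto [K_min, K_max]", {
  cfg <- swarm_config()
  K <- anpmopso:::rank_to_K(c(1, 3, 2, 3), cfg)
  expect_equal(K[1], cfg$K_min)
  expect_equal(K[2], cfg$K_max)
  expect_equal(anpmopso:::rank_to_K(rep(1L, 4), cfg), rep(cfg$K_min, 4))
})

test_that("velocity/position updates respect clamps and fixed points", {
  cfg <- swarm_config(seed = 1)
  lower <- c(0, 0); upper <- c(1, 1)
  # stationary fixed point: x = pbest = gbest, v = 0, no DE term
  set.seed(1)
  upd <- update_velocity_position(c(0.4, 0.6), c(0, 0), c(0.4, 0.6),
                                  c(0.4, 0.6), c(0, 0), cfg, lower, upper)
  expect_equal(upd$position, c(0.4, 0.6))
  expect_equal(upd$velocity, c(0, 0))
  # any update keeps components inside the bounds and the velocity clamp
  set.seed(2)
  for (i in 1:50) {
    upd <- update_velocity_position(runif(2), runif(2, -1, 1), runif(2),
                                    runif(2), rnorm(2), cfg, lower, upper)
    expect_true(all(upd$position >= lower & upd$position <= upper))
    expect_true(all(abs(upd$velocity) <= 0.2 * (upper - lower) + 1e-12))
  }
})

test_that("max_iter = 0 returns the non-dominated set of the Sobol swarm", {
  p <- make_problem("MMF1")
  cfg <- swarm_config(pop_size = 60, max_iter = 0, archive_cap = 60, seed = 5)
  res <- run_anpmopso(p, cfg)
  pos <- scale_population(sobol_points(60, 2), p$lower, p$upper)
  obj <- p$fn(pos)
  nd <- nondominated_filter(obj)
  got <- res$archive$objectives[order(res$archive$objectives[, 1]), ]
  want <- obj[nd, ][order(obj[nd, 1]), ]
  expect_equal(unname(got), unname(want))
})

test_that("runs are bit-reproducible under a fixed seed", {
  p <- make_problem("MMF4")
  cfg <- swarm_config(pop_size = 40, max_iter = 8, archive_cap = 40, seed = 123)
  a <- run_anpmopso(p, cfg)
  b <- run_anpmopso(p, cfg)
  expect_identical(a$archive, b$archive)
  expect_identical(a$history, b$history)
})

test_that("the archive stays mutually non-dominated and capped", {
  p <- make_problem("MMF5")
  cfg <- swarm_config(pop_size = 40, max_iter = 10, archive_cap = 25, seed = 3)
  res <- run_anpmopso(p, cfg)
  obj <- res$archive$objectives
  expect_lte(nrow(obj), 25)
  expect_length(nondominated_filter(obj), nrow(obj))
  expect_true(all(diff(res$history$iteration) == 1))
})

test_that("with the DE term off the loop degenerates to textbook PSO", {
  p <- sphere_problem()
  cfg <- swarm_config(pop_size = 50, max_iter = 39, archive_cap = 10,
                      variant = "no_de", seed = 7)
  res <- run_anpmopso(p, cfg)
  expect_lt(min(res$archive$objectives[, 1]), 1e-3)
  oracle <- direct_pso(function(x) sum(x^2), p$lower, p$upper,
                       pop = 50, iters = 39, seed = 7)
  expect_lt(oracle, 1e-3)
})

test_that("ablation variants run and tag their output", {
  p <- make_problem("MMF1")
  for (v in c("full", "no_init", "no_de", "no_select")) {
    cfg <- swarm_config(pop_size = 30, max_iter = 5, archive_cap = 30,
                        seed = 11, variant = v)
    res <- run_anpmopso(p, cfg)
    expect_equal(res$config$variant, v)
    expect_gt(nrow(res$archive$objectives), 0)
  }
})

test_that("gene-mode runs recover strong markers on a small panel", {
  g <- generate_synthetic(synthetic_spec(n_genes = 50, n_samples = 90,
                                         n_classes = 3, n_informative = 3,
                                         n_redundant = 0, effect_size = 5,
                                         seed = 19))
  cfg <- swarm_config(pop_size = 40, max_iter = 15, archive_cap = 40, seed = 19)
  run <- select_genes(g$dataset, cfg, hidden_units = 50)
  expect_s3_class(run$best, "SelectionResult")
  ov <- run$best$objective_vector
  expect_equal(unname(ov["NF"]), length(run$best$selected_gene_ids))
  expect_gte(ov[["CA"]], 60)
  # error-rate trace is a running minimum
  expect_true(all(diff(run$history$best_error_rate) <= 1e-12))
  # determinism end to end
  run2 <- select_genes(g$dataset, cfg, hidden_units = 50)
  expect_identical(run$best, run2$best)
})
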