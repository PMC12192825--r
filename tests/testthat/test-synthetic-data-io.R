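test_that("loader round-trips a toy matrix and applies min-max scaling", {
  vals <- matrix(c(2, 4, 6, 1,
                   1, 1, 1, 1,
                   0, 5, 10, 2), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  paths <- write_toy_expression(withr::local_tempdir(), vals,
                                c("x", "x", "y", "y"))
  ds <- load_expression(paths$matrix, paths$labels)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_equal(ds$gene_ids, c("gA", "gB", "gC"))
  expect_equal(as.character(ds$labels), c("x", "x", "y", "y"))

  norm <- load_expression(paths$matrix, paths$labels, normalize = TRUE)
  expect_equal(unname(norm$values["gA", ]), c(1, 3, 5, 0) / 5)
  expect_equal(unname(norm$values["gB", ]), rep(0, 4))  # constant gene
  expect_equal(range(norm$values), c(0, 1))
})

test_that("loader rejects malformed inputs", {
  vals <- matrix(1:12, nrow = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  dir <- withr::local_tempdir()
  paths <- write_toy_expression(dir, vals, c("x", "x", "y"))  # 3 labels, 4 samples
  expect_error(load_expression(paths$matrix, paths$labels), "format error")
  expect_error(load_expression(file.path(dir, "nope.csv"), paths$labels),
               "I/O error")
  expect_error(expression_dataset(vals, gene_ids = c("g1", "g1", "g3"),
                                  labels = c("x", "x", "y", "y")),
               "duplicate gene IDs")
  withna <- vals; withna[2, 2] <- NA
  expect_error(expression_dataset(withna, labels = c("x", "x", "y", "y")),
               "missing values")
})

test_that("synthetic generator is deterministic and honors its contracts", {
  spec <- synthetic_spec(n_genes = 60, n_samples = 50, n_classes = 2,
                         n_informative = 4, n_redundant = 6,
                         effect_size = 3, seed = 7)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_equal(a$informative, 1:4)
  expect_true(all(table(a$dataset$labels[a$dataset$split$train]) >= 2))

  # redundant genes hit the requested correlation with their parents
  spec2 <- synthetic_spec(n_genes = 50, n_samples = 4000, n_classes = 2,
                          n_informative = 2, n_redundant = 2,
                          within_block_correlation = 0.8, effect_size = 2,
                          seed = 3)
  g <- generate_synthetic(spec2)
  r1 <- cor(g$dataset$values[1, ], g$dataset$values[3, ])
  r2 <- cor(g$dataset$values[2, ], g$dataset$values[4, ])
  expect_lt(max(abs(c(r1, r2) - 0.8)), 0.05)

  expect_error(synthetic_spec(n_genes = 5, n_informative = 4, n_redundant = 4),
               "parameter error")
  expect_error(synthetic_spec(n_classes = 1), "parameter error")
})

test_that("strong effect sizes put informative genes above all noise genes", {
  g <- generate_synthetic(synthetic_spec(n_genes = 100, n_samples = 200,
                                         n_classes = 2, n_informative = 5,
                                         n_redundant = 0, effect_size = 5,
                                         seed = 21))
  v <- g$dataset$values
  cls <- as.integer(g$dataset$labels)
  tstat <- function(row, marked) {
    a <- row[cls == marked]; b <- row[cls != marked]
    abs(mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  t_inf <- vapply(1:5, function(j) tstat(v[j, ], ((j - 1) %% 2) + 1), 0)
  t_noise <- vapply(6:100, function(j) max(tstat(v[j, ], 1), tstat(v[j, ], 2)), 0)
  expect_gt(min(t_inf), max(t_noise))
})

test_that("null generator (effect 0) yields chance-level signal", {
  # per-gene ANOVA p-values of 'informative' genes behave like the null
  pvals <- unlist(lapply(1:50, function(sd) {
    g <- generate_synthetic(synthetic_spec(n_genes = 12, n_samples = 60,
                                           n_classes = 3, n_informative = 5,
                                           n_redundant = 0, effect_size = 0,
                                           seed = sd))
    vapply(g$informative, function(j) {
      summary(aov(g$dataset$values[j, ] ~ g$dataset$labels))[[1]][1, "Pr(>F)"]
    }, 0)
  }))
  n <- length(pvals)
  prop <- mean(pvals < 0.05)
  bounds <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(prop, bounds[1])
  expect_lte(prop, bounds[2])

  # held-out ELM accuracy on the informative set is chance-level
  accs <- vapply(1:20, function(sd) {
    g <- generate_synthetic(synthetic_spec(n_genes = 30, n_samples = 90,
                                           n_classes = 3, n_informative = 5,
                                           n_redundant = 0, effect_size = 0,
                                           seed = 100 + sd))
    ds <- normalize_minmax(g$dataset)
    tr <- ds$split$train; te <- ds$split$test
    m <- train_elm(t(ds$values[1:5, tr]), ds$labels[tr], H = 50, seed = sd)
    classification_accuracy(m, t(ds$values[1:5, te]), ds$labels[te]) / 100
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 1e-9)
})

test_that("held-out accuracy is monotone in effect size (paired seeds)", {
  acc_at <- function(effect, sd) {
    g <- generate_synthetic(synthetic_spec(n_genes = 30, n_samples = 90,
                                           n_classes = 3, n_informative = 5,
                                           n_redundant = 0,
                                           effect_size = effect, seed = sd))
    ds <- normalize_minmax(g$dataset)
    tr <- ds$split$train; te <- ds$split$test
    m <- train_elm(t(ds$values[1:5, tr]), ds$labels[tr], H = 50, seed = 500)
    classification_accuracy(m, t(ds$values[1:5, te]), ds$labels[te])
  }
  seeds <- 1:8
  means <- vapply(c(0, 2, 5), function(e) {
    mean(vapply(seeds, function(sd) acc_at(e, sd), 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("selection results round-trip through TSV + JSON", {
  res <- selection_result(c("gB", "gA", "gC"),
                          c(CA = 97.5, NF = 3, NP = 0.412),
                          metadata = list(seed = 5, iterations = 50))
  path <- file.path(withr::local_tempdir(), "sel.tsv")
  save_selection(res, path)
  lines <- readLines(path)
  expect_length(lines, 4L)  # header + 3 rows
  back <- read_selection(path)
  expect_equal(back$selected_gene_ids, res$selected_gene_ids)
  expect_equal(back$objective_vector, res$objective_vector)
  expect_equal(back$metadata$seed, 5)

  empty <- selection_result(character(0), c(CA = 0, NF = 0, NP = Inf))
  path2 <- file.path(withr::local_tempdir(), "empty.tsv")
  expect_warning(save_selection(empty, path2), "empty")
  expect_length(readLines(path2), 1L)
  expect_error(selection_result(c("g1"), c(CA = 1, NF = 2, NP = 0)),
               "contract error")
})
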