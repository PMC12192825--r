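# Run configuration: YAML parsing, validation against the module contracts,
# and the top-level runner that ties the modules together and writes run
# artifacts (outputs + MANIFEST.json).

default_run_config <- function() {
  list(
    mode = "select",
    seed = 1L,
    output_dir = ".",
    data = NULL,
    labels = NULL,
    problem = NULL,
    runs = 15L,
    variant = "full",
    wnpee = list(k_list = c(5, 10, 15), d = NULL, r = 2,
                 max_iter = 30, tol = 1e-8),
    init = list(scramble = FALSE, skip_zero = FALSE),
    objectives = list(hidden_units = 100, np_k = 10,
                      reference_space = "wnpee"),
    swarm = list(pop_size = 200, max_iter = 50, w = 0.7298,
                 c1 = 1.49445, c2 = 1.49445, F = 0.5, CR = 0.5,
                 K_min = 0.2, K_max = 0.8, beta = 0.5,
                 archive_cap = NULL, theta = 0.6, neighborhood_size = 10)
  )
}

# Nearest known key, for error messages on typos.
suggest_key <- function(key, known) {
  d <- utils::adist(key, known)
  known[which.min(d)]
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) {
      stop(sprintf("config error: unknown key `%s` (did you mean `%s`?)",
                   full, suggest_key(k, names(base))))
    }
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

check_range <- function(value, field, lo = -Inf, hi = Inf,
                        open_lo = FALSE, open_hi = FALSE) {
  bad <- !is.numeric(value) || anyNA(value) ||
    any(if (open_lo) value <= lo else value < lo) ||
    any(if (open_hi) value >= hi else value > hi)
  if (bad) {
    stop(sprintf("config error: `%s` must be in %s%g, %g%s",
                 field, if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"))
  }
  invisible(value)
}

#' Parse and validate a run configuration
#'
#' Fills unset fields with the package defaults (constriction PSO weights,
#' `F = CR = 0.5`, `beta = 0.5`, neighbourhood size 10, swarm of 200 over
#' 50 iterations), validates every numeric field against the module
#' contracts, and rejects unknown keys with a suggestion.
#'
#' @param config `NULL`, a path to a YAML file, or a nested list of
#'   overrides mirroring the config blocks (`mode`, `seed`, `output_dir`,
#'   `data`, `labels`, `problem`, `runs`, `variant`, `wnpee`, `init`,
#'   `objectives`, `swarm`).
#' @return a validated `run_config` list with a `hash` attribute.
#' @export
parse_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    base <- merge_config(base, config)
  }
  cfg <- base
  if (!cfg$mode %in% c("select", "benchmark", "embed", "ablate", "metrics")) {
    stop("config error: `mode` must be one of select|benchmark|embed|ablate|metrics")
  }
  if (!cfg$variant %in% c("full", "no_init", "no_de", "no_select")) {
    stop("config error: `variant` must be full|no_init|no_de|no_select")
  }
  cfg$seed <- as.integer(check_range(cfg$seed, "seed", 0, 2^31 - 1))
  check_range(cfg$runs, "runs", 1)
  check_range(cfg$swarm$beta, "swarm.beta", 0, 1)
  check_range(cfg$swarm$theta, "swarm.theta", 0, 1, TRUE, TRUE)
  check_range(cfg$swarm$pop_size, "swarm.pop_size", 4)
  check_range(cfg$swarm$max_iter, "swarm.max_iter", 0)
  check_range(cfg$swarm$F, "swarm.F", 0)
  check_range(cfg$swarm$CR, "swarm.CR", 0, 1)
  check_range(cfg$swarm$w, "swarm.w", 0)
  check_range(cfg$objectives$hidden_units, "objectives.hidden_units", 1)
  check_range(cfg$objectives$np_k, "objectives.np_k", 1)
  check_range(cfg$wnpee$r, "wnpee.r", 1, Inf, TRUE)
  check_range(cfg$wnpee$max_iter, "wnpee.max_iter", 1)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  hash_index(utf8ToInt(paste(names(flat), flat, collapse = ";")))
}

swarm_from_config <- function(cfg) {
  s <- cfg$swarm
  swarm_config(pop_size = s$pop_size, max_iter = s$max_iter, w = s$w,
               c1 = s$c1, c2 = s$c2, F = s$F, CR = s$CR,
               K_min = s$K_min, K_max = s$K_max, beta = s$beta,
               archive_cap = if (is.null(s$archive_cap)) s$pop_size else
                 s$archive_cap,
               theta = s$theta, neighborhood_size = s$neighborhood_size,
               seed = cfg$seed, variant = cfg$variant)
}

#' Execute a validated run configuration
#'
#' Dispatches on `mode`, writes the mode's artifacts into `output_dir`
#' together with a `MANIFEST.json` (mode, seed, config hash, package
#' version, wall time), and returns the result invisibly.
#'
#' * `select`: gene selection on `data`/`labels`; writes `selection.tsv` +
#'   JSON sidecar, `archive.tsv`, `error_rate.csv`.
#' * `benchmark`: `runs` optimizer runs on `problem`; writes
#'   `metrics.csv` and `summary.json`.
#' * `embed`: WNPEE embedding of `data`; writes `embedded.tsv`,
#'   `projection.tsv`, `loss_trace.json`.
#' * `ablate`: variant comparison on `problem`; writes `ablation.csv`.
#' * `metrics`: score an archive TSV (`data`) against `problem`; writes
#'   `metrics.json`.
#'
#' @param cfg a [parse_run_config()] result.
#' @return the mode's result object, invisibly.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- switch(
    cfg$mode,
    select = run_mode_select(cfg),
    benchmark = run_mode_benchmark(cfg),
    embed = run_mode_embed(cfg),
    ablate = run_mode_ablate(cfg),
    metrics = run_mode_metrics(cfg)
  )
  manifest <- list(mode = cfg$mode, seed = cfg$seed,
                   config_hash = attr(cfg, "hash"),
                   package_version = as.character(utils::packageVersion("anpmopso")),
                   wall_time_sec = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

require_field <- function(cfg, field) {
  if (is.null(cfg[[field]])) {
    stop(sprintf("config error: mode `%s` requires `%s`", cfg$mode, field))
  }
  cfg[[field]]
}

run_mode_select <- function(cfg) {
  data <- require_field(cfg, "data")
  labels <- require_field(cfg, "labels")
  ds <- load_expression(data, labels)
  run <- select_genes(ds, swarm_from_config(cfg),
                      hidden_units = cfg$objectives$hidden_units,
                      np_k = cfg$objectives$np_k,
                      reference = cfg$objectives$reference_space,
                      wnpee_args = cfg$wnpee[c("k_list", "d", "r",
                                               "max_iter", "tol")])
  run$best$metadata$config_hash <- attr(cfg, "hash")
  save_selection(run$best, file.path(cfg$output_dir, "selection.tsv"))
  arch <- data.frame(run$archive$objectives)
  names(arch) <- c("err_pct", "nf", "np_dist")
  utils::write.table(arch, file.path(cfg$output_dir, "archive.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(
    data.frame(iteration = run$history$iteration,
               best_error_rate = run$history$best_error_rate),
    file.path(cfg$output_dir, "error_rate.csv"), row.names = FALSE)
  run
}

run_mode_benchmark <- function(cfg) {
  problem <- require_field(cfg, "problem")
  bench <- run_benchmark(problem, runs = cfg$runs, seed = cfg$seed)
  utils::write.csv(bench$per_run, file.path(cfg$output_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(problem = bench$problem, runs = bench$runs,
         hv_reference_point = bench$hv_reference_point,
         summary = bench$summary),
    file.path(cfg$output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  bench
}

run_mode_embed <- function(cfg) {
  data <- require_field(cfg, "data")
  labels <- require_field(cfg, "labels")
  ds <- load_expression(data, labels, normalize = TRUE)
  w <- cfg$wnpee
  fit <- fit_wnpee(ds$values, k_list = w$k_list, d = w$d, r = w$r,
                   max_iter = w$max_iter, tol = w$tol)
  utils::write.table(t(fit$embedded), file.path(cfg$output_dir, "embedded.tsv"),
                     sep = "\t", quote = FALSE, row.names = ds$sample_ids,
                     col.names = paste0("dim", seq_len(fit$d)))
  utils::write.table(fit$projection, file.path(cfg$output_dir, "projection.tsv"),
                     sep = "\t", quote = FALSE, row.names = ds$gene_ids,
                     col.names = paste0("dim", seq_len(fit$d)))
  jsonlite::write_json(list(loss_trace = fit$loss_trace,
                            alphas = fit$alphas, converged = fit$converged),
                       file.path(cfg$output_dir, "loss_trace.json"),
                       auto_unbox = TRUE, digits = NA)
  fit
}

run_mode_ablate <- function(cfg) {
  problem <- require_field(cfg, "problem")
  tab <- run_ablation(problem, runs = cfg$runs, seed = cfg$seed)
  utils::write.csv(tab, file.path(cfg$output_dir, "ablation.csv"),
                   row.names = FALSE)
  tab
}

run_mode_metrics <- function(cfg) {
  data <- require_field(cfg, "data")         # archive TSV: decision columns
  problem <- make_problem(require_field(cfg, "problem"))
  pos <- as.matrix(utils::read.table(data, header = TRUE, sep = "\t"))
  rep <- metric_report(pos, problem$fn(pos), problem)
  jsonlite::write_json(rep, file.path(cfg$output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  rep
}
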