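# Expression-matrix I/O and the synthetic microarray generator.
#
# The unit of gene-selection work is an ExpressionDataset: a genes x samples
# real matrix with gene/sample identifiers, per-sample class labels, and an
# optional train/test split. Microarray panels of the kind emulated here run
# to thousands of genes over tens to a couple of hundred samples with 2-5
# classes.

#' Construct an expression dataset
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames or `g1..gL`).
#' @param sample_ids character vector of unique sample identifiers.
#' @param labels vector of class labels, one per sample, at least two
#'   distinct values.
#' @param split optional list with integer index vectors `train` and `test`.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, gene_ids = NULL, sample_ids = NULL,
                               labels, split = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  L <- nrow(values)
  N <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(L))
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(N))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != L) stop("format error: gene_ids length != nrow(values)")
  if (length(sample_ids) != N) stop("format error: sample_ids length != ncol(values)")
  if (anyDuplicated(gene_ids)) stop("format error: duplicate gene IDs")
  if (anyDuplicated(sample_ids)) stop("format error: duplicate sample IDs")
  if (length(labels) != N) stop("format error: labels length != number of samples")
  if (anyNA(values)) stop("data error: missing values in expression matrix")
  lab <- factor(labels)
  if (nlevels(lab) < 2) stop("format error: need at least 2 classes")
  if (!is.null(split)) {
    stopifnot(is.list(split), all(c("train", "test") %in% names(split)))
    split$train <- as.integer(split$train)
    split$test <- as.integer(split$test)
    if (any(table(lab[split$train]) < 2)) {
      stop("data error: every class needs >= 2 training samples")
    }
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = lab, split = split),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples, %d classes\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d train / %d test\n",
                length(x$split$train), length(x$split$test)))
  }
  invisible(x)
}

#' Per-gene min-max normalization
#'
#' Rescales each gene to `[0, 1]`. When the dataset carries a train/test
#' split, the minimum and maximum are computed on the training samples only
#' and applied to all samples, so no information leaks from held-out data.
#' Constant genes map to 0.
#'
#' @param dataset an `ExpressionDataset`.
#' @return the dataset with normalized values.
#' @export
normalize_minmax <- function(dataset) {
  v <- dataset$values
  ref <- if (!is.null(dataset$split)) v[, dataset$split$train, drop = FALSE] else v
  lo <- apply(ref, 1L, min)
  hi <- apply(ref, 1L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  dataset$values <- (v - lo) / rng
  dataset
}

#' Load an expression matrix with labels
#'
#' Reads a delimited text matrix (comma or tab, auto-detected from the
#' extension or content) with genes in rows and a header of sample IDs,
#' plus labels either from a separate single-column file or from a named
#' row... labels are matched positionally to samples.
#'
#' @param path_matrix path to the CSV/TSV expression matrix (first column =
#'   gene IDs, header = sample IDs).
#' @param path_labels path to a labels file: one label per line, or a
#'   two-column delimited file whose last column holds the labels.
#' @param normalize apply per-gene min-max scaling after loading.
#' @param impute replace missing values by the gene mean instead of erroring.
#' @param transpose set when the file stores samples in rows.
#' @return an `ExpressionDataset`.
#' @export
load_expression <- function(path_matrix, path_labels, normalize = FALSE,
                            impute = FALSE, transpose = FALSE) {
  if (!file.exists(path_matrix)) stop("I/O error: missing matrix file")
  if (!file.exists(path_labels)) stop("I/O error: missing labels file")
  sep <- detect_sep(path_matrix)
  tab <- utils::read.table(path_matrix, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  labs <- read_labels(path_labels)
  if (length(labs) != ncol(m)) {
    stop(sprintf("format error: %d labels for %d samples",
                 length(labs), ncol(m)))
  }
  if (anyNA(m)) {
    if (!impute) stop("data error: missing values (set impute = TRUE to mean-impute)")
    for (i in which(rowSums(is.na(m)) > 0)) {
      mu <- mean(m[i, ], na.rm = TRUE)
      m[i, is.na(m[i, ])] <- mu
    }
  }
  ds <- expression_dataset(m, labels = labs)
  if (normalize) ds <- normalize_minmax(ds)
  ds
}

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) return("\t")
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

read_labels <- function(path) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(first) > 1L) {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    as.character(tab[[ncol(tab)]])
  } else {
    as.character(utils::read.table(path, header = FALSE,
                                   stringsAsFactors = FALSE)[[1]])
  }
}

#' Specification of a synthetic microarray dataset
#'
#' Describes a genes x samples panel with three gene strata: informative
#' genes that act as one-vs-rest class markers (the class-conditional mean of
#' marker gene j is shifted by `effect_size * noise_sd` in its marked class),
#' a redundant block correlated with the informative genes, and pure
#' Gaussian noise genes.
#'
#' @param n_genes,n_samples,n_classes panel dimensions; `n_classes >= 2`.
#' @param n_informative number of class-marker genes.
#' @param n_redundant number of genes correlated with informative ones.
#' @param effect_size class mean shift in units of `noise_sd`.
#' @param within_block_correlation target Pearson correlation between each
#'   redundant gene and its parent informative gene, in `[0, 1)`.
#' @param noise_sd standard deviation of the Gaussian noise floor.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 2000, n_samples = 150, n_classes = 5,
                           n_informative = 5, n_redundant = 20,
                           effect_size = 2, within_block_correlation = 0.8,
                           noise_sd = 1, seed = 1) {
  spec <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
               n_classes = as.integer(n_classes),
               n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               effect_size = as.numeric(effect_size),
               within_block_correlation = as.numeric(within_block_correlation),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (spec$n_informative + spec$n_redundant > spec$n_genes) {
    stop("parameter error: n_informative + n_redundant > n_genes")
  }
  if (spec$n_classes < 2) stop("parameter error: n_classes < 2")
  if (spec$within_block_correlation < 0 || spec$within_block_correlation >= 1) {
    stop("parameter error: within_block_correlation must be in [0, 1)")
  }
  if (spec$noise_sd <= 0) stop("parameter error: noise_sd must be > 0")
  if (spec$n_samples < 2 * spec$n_classes) {
    stop("parameter error: need >= 2 samples per class")
  }
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic microarray dataset with known informative genes
#'
#' Emulates the structure of public microarray panels so that gene selection
#' can be validated against a known ground truth. Informative gene `j` is a
#' one-vs-rest marker of class `((j - 1) mod n_classes) + 1`: its mean in
#' that class is shifted upward by `effect_size * noise_sd`. Each redundant
#' gene copies one informative gene plus calibrated Gaussian noise so that
#' its population Pearson correlation with the parent equals
#' `within_block_correlation`. Remaining genes are i.i.d. Gaussian noise.
#' Samples are assigned to classes in a balanced round-robin; a stratified
#' 2/3-1/3 train/test split is attached.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` (an `ExpressionDataset`) and
#'   `informative` (integer indices of the ground-truth marker genes).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  L <- spec$n_genes; N <- spec$n_samples; C <- spec$n_classes
  ni <- spec$n_informative; nr <- spec$n_redundant
  with_seed(spec$seed, {
    classes <- rep_len(seq_len(C), N)
    m <- matrix(stats::rnorm(L * N, sd = spec$noise_sd), nrow = L)
    shift <- spec$effect_size * spec$noise_sd
    for (j in seq_len(ni)) {
      marked <- ((j - 1L) %% C) + 1L
      m[j, classes == marked] <- m[j, classes == marked] + shift
    }
    if (nr > 0) {
      rho <- spec$within_block_correlation
      for (j in seq_len(nr)) {
        parent <- ((j - 1L) %% max(ni, 1L)) + 1L
        if (ni == 0L || rho <= 0) next
        # population SD of the parent: noise + between-class marker variance
        p <- mean(classes == (((parent - 1L) %% C) + 1L))
        sd_par <- sqrt(spec$noise_sd^2 + p * (1 - p) * shift^2)
        sd_extra <- sd_par * sqrt(1 / rho^2 - 1)
        m[ni + j, ] <- m[parent, ] + stats::rnorm(N, sd = sd_extra)
      }
    }
    train <- stratified_split(classes, 2 / 3)
    ds <- expression_dataset(
      m,
      gene_ids = paste0("g", seq_len(L)),
      sample_ids = paste0("s", seq_len(N)),
      labels = paste0("class", classes),
      split = list(train = train, test = setdiff(seq_len(N), train))
    )
    list(dataset = ds, informative = seq_len(ni))
  })
}

# Deterministic stratified split: within each class take the first
# ceil(fraction * size) samples in index order.
stratified_split <- function(classes, fraction) {
  idx <- seq_along(classes)
  unlist(lapply(split(idx, classes), function(ix) {
    ix[seq_len(max(2L, ceiling(fraction * length(ix))))]
  }), use.names = FALSE)
}

#' Assemble a gene-selection result
#'
#' @param selected_gene_ids character vector of selected genes, ranked.
#' @param objective_vector named numeric vector with elements `CA`
#'   (classification accuracy, percent), `NF` (number of selected genes) and
#'   `NP` (neighborhood-preservation distance, lower is better).
#' @param metadata list of run metadata (seed, config hash, iterations, ...).
#' @return a `SelectionResult`.
#' @export
selection_result <- function(selected_gene_ids, objective_vector,
                             metadata = list()) {
  selected_gene_ids <- as.character(selected_gene_ids)
  objective_vector <- unlist(objective_vector)
  stopifnot(all(c("CA", "NF", "NP") %in% names(objective_vector)))
  if (objective_vector[["NF"]] != length(selected_gene_ids)) {
    stop("contract error: NF must equal the number of selected genes")
  }
  structure(list(selected_gene_ids = selected_gene_ids,
                 objective_vector = objective_vector,
                 metadata = metadata),
            class = "SelectionResult")
}

#' Write a selection result to disk
#'
#' Writes a TSV of `(gene_id, rank)` rows plus a JSON sidecar (same path,
#' `.json` extension) carrying the objective vector and metadata. The pair
#' round-trips losslessly through [read_selection()].
#'
#' @param result a `SelectionResult`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
save_selection <- function(result, path) {
  stopifnot(inherits(result, "SelectionResult"))
  if (length(result$selected_gene_ids) == 0L) {
    warning("writing an empty selection")
  }
  df <- data.frame(gene_id = result$selected_gene_ids,
                   rank = seq_along(result$selected_gene_ids))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(objective_vector = as.list(result$objective_vector),
         metadata = result$metadata),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a selection result written by [save_selection()]
#'
#' @param path the TSV path passed to [save_selection()].
#' @return a `SelectionResult`.
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing selection file")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  selection_result(df$gene_id,
                   unlist(meta$objective_vector),
                   as.list(meta$metadata))
}
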