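# The three-objective fitness of a gene subset: classification accuracy of
# an ELM wrapper (percent, higher better), the number of selected genes, and
# a neighborhood-preservation distance comparing the subset feature space
# against a fixed reference embedding (lower better). Internally the
# optimizer minimizes (100 - CA, NF, NP_dist).

#' Count selected genes in a binary mask
#'
#' @param mask binary (0/1 or logical) vector over all genes.
#' @return integer number of ones.
#' @export
gene_count <- function(mask) {
  if (is.logical(mask)) mask <- as.integer(mask)
  if (!all(mask %in% c(0, 1))) stop("contract error: mask must be binary")
  as.integer(sum(mask))
}

#' Neighborhood-preservation distance between two sample spaces
#'
#' For each sample `i`, its j-th nearest neighbour in the reference space is
#' matched with its j-th nearest neighbour in the subset space, and the
#' Euclidean distance between these two neighbour points is measured in the
#' subset space; distances are averaged over `j = 1..k` and all samples.
#' The value is zero iff the neighbour orderings agree, and in particular
#' when both spaces coincide (or differ only by a rigid transformation that
#' preserves the neighbour ranking).
#'
#' @param reference_space samples x features matrix of the reference
#'   representation (e.g. a WNPEE embedding).
#' @param subset_space samples x features matrix of the candidate
#'   representation; same number of rows.
#' @param k number of neighbours compared, `< N`.
#' @param reference_order optional precomputed neighbour index matrix for
#'   the reference space (as produced by the internal KNN helper), to avoid
#'   recomputation across repeated calls.
#' @return non-negative scalar; lower means better preservation.
#' @export
neighborhood_preservation <- function(reference_space, subset_space, k,
                                      reference_order = NULL) {
  sub <- as.matrix(subset_space)
  N <- nrow(sub)
  if (k >= N) stop("parameter error: k must be < number of samples")
  if (is.null(reference_order)) {
    ref <- as.matrix(reference_space)
    if (nrow(ref) != N) stop("parameter error: sample counts differ")
    reference_order <- knn_index(ref, k)
  }
  sn <- rowSums(sub * sub)
  .np_from_gram(tcrossprod(sub), sn,
                reference_order[, seq_len(k), drop = FALSE])
}

#' Prepare a gene-selection fitness context
#'
#' Precomputes everything the per-mask fitness needs: the min-max-normalized
#' expression matrix (scaled on the training split), the train/validation
#' partition, the WNPEE reference embedding of the full normalized data and
#' its neighbour ordering, and a memoization cache keyed by mask.
#'
#' @param dataset an `ExpressionDataset` with a train/test split (one is
#'   created stratified 2/3-1/3 if absent).
#' @param hidden_units ELM hidden-layer size.
#' @param np_k neighbourhood size of the preservation objective.
#' @param reference one of `"wnpee"` (default: embed the full normalized
#'   data) or `"raw"` (use the full-gene space as reference).
#' @param wnpee_args list of extra arguments passed to [fit_wnpee()].
#' @param seed base seed; each mask derives its ELM seed from it.
#' @return an object of class `gene_objectives`.
#' @export
gene_objectives <- function(dataset, hidden_units = 100, np_k = 10,
                            reference = c("wnpee", "raw"),
                            wnpee_args = list(), seed = 1) {
  reference <- match.arg(reference)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$split)) {
    cls <- as.integer(dataset$labels)
    train <- stratified_split(cls, 2 / 3)
    dataset$split <- list(train = train,
                          test = setdiff(seq_along(cls), train))
  }
  dataset <- normalize_minmax(dataset)
  X <- dataset$values                       # genes x samples, in [0,1]
  ref_space <- if (reference == "wnpee") {
    emb <- do.call(fit_wnpee, c(list(X = X), wnpee_args))
    t(emb$embedded)                          # samples x d
  } else {
    t(X)
  }
  structure(
    list(dataset = dataset, X = X,
         train = dataset$split$train, validation = dataset$split$test,
         hidden_units = hidden_units, np_k = np_k,
         reference = reference,
         reference_order = knn_index(ref_space, np_k),
         seed = as.integer(seed),
         cache = new.env(parent = emptyenv())),
    class = "gene_objectives"
  )
}

#' Cross-validated ELM accuracy of a gene subset
#'
#' Stratified k-fold cross-validation restricted to the training split of
#' the fitness context (the held-out validation samples are never touched),
#' with `k = n_train` giving leave-one-out. Used to pick the final reported
#' subset among archive candidates: the cross-validated estimate separates
#' genuinely informative genes from their correlated shadows much more
#' reliably than a single small holdout can.
#'
#' @param sel integer indices of the selected genes.
#' @param ctx a [gene_objectives()] context.
#' @param folds number of folds (default 5).
#' @return mean accuracy percentage over the folds.
#' @export
cv_accuracy <- function(sel, ctx, folds = 5) {
  if (length(sel) == 0L) return(0)
  Xs <- t(ctx$X[sel, , drop = FALSE])[ctx$train, , drop = FALSE]
  y <- ctx$dataset$labels[ctx$train]
  n <- length(y)
  folds <- min(folds, n)
  # deterministic stratified fold assignment: round-robin within class
  fold_id <- integer(n)
  for (cl in levels(y)) {
    ix <- which(y == cl)
    fold_id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
    m <- train_elm(Xs[tr, , drop = FALSE], y[tr], H = ctx$hidden_units,
                   seed = derive_seed(ctx$seed, 7919L + f))
    classification_accuracy(m, Xs[!tr, , drop = FALSE], y[!tr])
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Evaluate the three-objective fitness of a gene mask
#'
#' Trains an ELM on the masked training features and scores it on the
#' validation split (CA, percent), counts the selected genes (NF), and
#' measures the neighborhood-preservation distance of the masked feature
#' space against the reference embedding (NP, lower better). Results are
#' memoized per unique mask, and the ELM seed is derived from the context
#' seed plus a mask hash, so evaluation is a pure function of
#' `(mask, dataset, seed)`. An empty mask is assigned worst-case objectives
#' (`CA = 0`, `NP = Inf`) instead of failing.
#'
#' @param mask binary vector over genes (length = number of genes).
#' @param ctx a [gene_objectives()] context.
#' @return named numeric vector `c(CA, NF, NP)`.
#' @export
evaluate_fitness <- function(mask, ctx) {
  stopifnot(inherits(ctx, "gene_objectives"))
  sel <- which(as.logical(mask))
  key <- paste0("m", paste(sel, collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(sel) == 0L) {
    out <- c(CA = 0, NF = 0, NP = Inf)
    ctx$cache[[key]] <- out
    return(out)
  }
  Xs <- t(ctx$X[sel, , drop = FALSE])       # samples x selected genes
  elm_seed <- derive_seed(ctx$seed, hash_index(sel))
  model <- train_elm(Xs[ctx$train, , drop = FALSE],
                     ctx$dataset$labels[ctx$train],
                     H = ctx$hidden_units, seed = elm_seed)
  ca <- classification_accuracy(model, Xs[ctx$validation, , drop = FALSE],
                                ctx$dataset$labels[ctx$validation])
  np <- neighborhood_preservation(NULL, Xs, ctx$np_k,
                                  reference_order = ctx$reference_order)
  out <- c(CA = ca, NF = length(sel), NP = np)
  ctx$cache[[key]] <- out
  out
}
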