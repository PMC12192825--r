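#' @keywords internal
#' @useDynLib anpmopso, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a component seed from a global seed
#'
#' One global seed fans out to per-component seeds through a counter-based
#' map, so that toggling one component does not shift the random stream of
#' another. Results stay inside the 32-bit integer range R requires.
#'
#' @param seed integer base seed.
#' @param component integer counter or character label of the component.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, component) {
  if (is.character(component)) {
    component <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  }
  val <- (as.double(seed) %% 2147483647) * 48271 + 1000003 * as.double(component)
  as.integer(val %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pairwise Euclidean distances between rows of a (and rows of b, if given).
row_dist <- function(a, b = a) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Index matrix of the k nearest neighbours of each row (self excluded),
# ties broken by smaller index for reproducibility.
knn_index <- function(x, k) {
  n <- nrow(x)
  stopifnot(k < n)
  d <- row_dist(x)
  diag(d) <- Inf
  idx <- apply(d, 1L, function(di) order(di, seq_len(n))[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

# Min-max map to [0,1]; constant vectors map to 0 (degenerate term drops out).
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps * max(1, abs(r[2]))) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Deterministic 31-bit hash of an integer vector (used to key fitness caches
# and derive per-mask classifier seeds).
hash_index <- function(idx) {
  h <- 17
  for (v in as.double(idx)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}
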