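# Quality metrics for fronts, Pareto-set approximations, and embeddings:
# exact bi-objective hypervolume (reported as 1/HV, smaller = better),
# error rate, decision-space proximity (IGDX and the PSP family), average
# neighborhood overlap, and Spearman rank correlation of pairwise distances.

#' Exact bi-objective hypervolume
#'
#' Sweep-line computation of the area dominated by `front` and bounded by
#' `ref_point`. Points that do not strictly dominate the reference point are
#' dropped with a warning; with no usable point the hypervolume is 0 and
#' `inv_hv` is `Inf`.
#'
#' @param front numeric matrix (rows = objective vectors, 2 columns),
#'   minimization orientation.
#' @param ref_point numeric length-2 reference point.
#' @return list with `hv` and `inv_hv = 1/hv`.
#' @export
hypervolume <- function(front, ref_point) {
  front <- matrix(as.matrix(front), ncol = 2)
  ok <- front[, 1] < ref_point[1] & front[, 2] < ref_point[2]
  if (any(!ok)) {
    warning(sprintf("dropping %d point(s) not dominating the reference point",
                    sum(!ok)))
    front <- front[ok, , drop = FALSE]
  }
  if (nrow(front) == 0L) return(list(hv = 0, inv_hv = Inf))
  front <- front[nondominated_filter(front), , drop = FALSE]
  ord <- order(front[, 1], front[, 2])
  front <- front[ord, , drop = FALSE]
  f1 <- c(front[, 1], ref_point[1])
  hv <- sum((f1[-1] - front[, 1]) * (ref_point[2] - front[, 2]))
  list(hv = hv, inv_hv = 1 / hv)
}

#' Error rate from a classification accuracy
#'
#' @param accuracy accuracy as a fraction in `[0, 1]`.
#' @return `1 - accuracy`.
#' @export
error_rate <- function(accuracy) {
  if (any(accuracy < 0 | accuracy > 1)) {
    stop("contract error: accuracy must be a fraction in [0, 1]")
  }
  1 - accuracy
}

#' Decision-space proximity metrics (IGDX / PSP family)
#'
#' `igdx` is the mean over the obtained set of the minimum *squared*
#' decision-space distance to the reference Pareto set. The suite-convention
#' Pareto-sets-proximity is also reported: `igdx_suite` (mean over the
#' reference set of the minimum distance to the obtained set — the coverage-
#' sensitive orientation), `cr` (per-dimension cover rate of the reference
#' set's extent), `psp = cr / igdx_suite` (larger = better) and
#' `inv_psp = 1/psp` (smaller = better). All three conventions are returned
#' so no orientation is silently guessed.
#'
#' @param obtained_ps matrix of obtained decision vectors (rows).
#' @param problem a `benchmark_problem` (supplies `reference_ps`), or a
#'   matrix of reference decision vectors.
#' @return list with `igdx`, `igdx_suite`, `cr`, `psp`, `inv_psp`.
#' @export
psp_family <- function(obtained_ps, problem) {
  obtained_ps <- as.matrix(obtained_ps)
  if (nrow(obtained_ps) == 0L) stop("parameter error: empty obtained set")
  ref <- if (inherits(problem, "benchmark_problem")) problem$reference_ps else
    as.matrix(problem)
  d <- row_dist(obtained_ps, ref)
  igdx <- mean(apply(d, 1L, min)^2)
  igdx_suite <- mean(apply(d, 2L, min))
  cr_dims <- vapply(seq_len(ncol(ref)), function(j) {
    lo_r <- min(ref[, j]); hi_r <- max(ref[, j])
    if (hi_r == lo_r) return(1)
    lo_o <- min(obtained_ps[, j]); hi_o <- max(obtained_ps[, j])
    delta <- (min(hi_o, hi_r) - max(lo_o, lo_r)) / (hi_r - lo_r)
    min(max(delta, 0), 1)^2
  }, 0)
  cr <- prod(cr_dims)^(1 / (2 * ncol(ref)))
  psp <- if (igdx_suite > 0) cr / igdx_suite else Inf
  list(igdx = igdx, igdx_suite = igdx_suite, cr = cr, psp = psp,
       inv_psp = 1 / psp)
}

#' Average neighborhood overlap between two representations
#'
#' Mean fraction of shared members between the k-nearest-neighbour sets of
#' each sample in a high-dimensional space and its low-dimensional
#' representation. 1 means the local structure is perfectly retained.
#'
#' @param high_space,low_space samples x features matrices with the same
#'   number of rows.
#' @param k neighbourhood size, `< N`.
#' @return scalar in `[0, 1]`.
#' @export
average_neighborhood_overlap <- function(high_space, low_space, k) {
  hi <- as.matrix(high_space)
  lo <- as.matrix(low_space)
  if (nrow(hi) != nrow(lo)) stop("parameter error: sample counts differ")
  if (k >= nrow(hi)) stop("parameter error: k must be < number of samples")
  nh <- knn_index(hi, k)
  nl <- knn_index(lo, k)
  mean(vapply(seq_len(nrow(hi)), function(i) {
    length(intersect(nh[i, ], nl[i, ])) / k
  }, 0))
}

#' Spearman rank correlation of paired distance lists
#'
#' Computed on the classical rank-difference formula
#' `1 - 6 sum(d_i^2) / (N (N^2 - 1))` with average ranks for ties. A
#' constant list has no defined ranking; `NA` is returned with a warning.
#'
#' @param dist_high,dist_low equal-length numeric vectors (typically the
#'   flattened pairwise distances before and after dimensionality
#'   reduction).
#' @return scalar in `[-1, 1]`, or `NA`.
#' @export
spearman_rank_correlation <- function(dist_high, dist_low) {
  if (length(dist_high) != length(dist_low)) {
    stop("parameter error: lists must have equal length")
  }
  n <- length(dist_high)
  if (length(unique(dist_high)) == 1L || length(unique(dist_low)) == 1L) {
    warning("constant distance list: rank correlation undefined")
    return(NA_real_)
  }
  d <- rank(dist_high) - rank(dist_low)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Neighborhood-preservation reporting score
#'
#' Maps the minimized preservation distance onto a bounded
#' larger-is-better score `1 / (1 + NP_dist)` for reporting next to ANO and
#' SRC (which are also larger-is-better).
#'
#' @param np_dist non-negative preservation distance.
#' @return score in `(0, 1]`.
#' @export
np_score <- function(np_dist) 1 / (1 + np_dist)

#' Score an optimizer result on a benchmark problem
#'
#' Convenience wrapper assembling the metric report used by the benchmark
#' runner: 1/HV of the final front and the PSP family of the final archive
#' positions.
#'
#' @param positions matrix of archived decision vectors.
#' @param objectives matrix of their objective vectors.
#' @param problem a `benchmark_problem`.
#' @return list with `hv`, `inv_hv`, `igdx`, `igdx_suite`, `cr`, `psp`,
#'   `inv_psp`.
#' @export
metric_report <- function(positions, objectives, problem) {
  hv <- suppressWarnings(hypervolume(objectives, problem$hv_reference_point))
  psp <- psp_family(positions, problem)
  c(list(hv = hv$hv, inv_hv = hv$inv_hv), psp)
}
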