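# Pareto dominance, the external archive, and its selection score.
#
# All objective vectors here are in minimization orientation. The archive
# keeps mutually non-dominated solutions; when it overflows, entries are
# ranked by a combined score S that trades off isolation in objective space
# (harmonic mean distance to the other members) against
# neighborhood-preservation quality, and the worst-scored entries are
# dropped.

#' Pareto dominance (minimization)
#'
#' `u` dominates `v` iff `u <= v` in every objective and `u < v` in at least
#' one.
#'
#' @param u,v equal-length numeric objective vectors.
#' @return logical scalar.
#' @export
dominates <- function(u, v) {
  all(u <= v) && any(u < v)
}

#' Extract the non-dominated subset of a point set
#'
#' Returns exactly the points not dominated by any other point, preserving
#' input order. Duplicate points do not dominate each other and are all
#' kept.
#'
#' @param points numeric matrix, one objective vector per row.
#' @return integer indices of the non-dominated rows.
#' @export
nondominated_filter <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stop("parameter error: need at least one point")
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    ge <- rowSums(points >= rep(points[i, ], each = n)) == ncol(points)
    gt <- rowSums(points >  rep(points[i, ], each = n)) > 0
    dominated_by_i <- ge & gt
    dominated_by_i[i] <- FALSE
    keep[dominated_by_i] <- FALSE
  }
  # transitivity guarantees correctness even though flagged points are
  # skipped as pivots: whatever flagged the pivot also dominates its victims
  which(keep)
}

# Non-domination rank (front index, 1 = best) by iterative peeling.
nondomination_rank <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  front <- 1L
  while (length(remaining) > 0L) {
    idx <- nondominated_filter(points[remaining, , drop = FALSE])
    rank[remaining[idx]] <- front
    remaining <- remaining[-idx]
    front <- front + 1L
  }
  rank
}

#' Harmonic mean distance of one archive entry to the others
#'
#' `HMD = n / sum_j 1/d_j` over the `n` distances to the other entries.
#' A zero distance (a duplicate in objective space) yields `HMD = 0`, which
#' marks the entry for removal first.
#'
#' @param distances positive distances to the other archive members.
#' @return the harmonic mean, or 0 when any distance is zero.
#' @export
harmonic_mean_distance <- function(distances) {
  n <- length(distances)
  if (n < 1) stop("parameter error: need at least one other entry")
  if (any(distances == 0)) return(0)
  n / sum(1 / distances)
}

#' Combined archive selection score
#'
#' Convex combination `S = beta * hmd_norm + (1 - beta) * np_norm`; lower
#' values are preferred. Callers pass terms already normalized to `[0, 1]`
#' within the current archive and oriented so that 0 is best (the archive
#' update feeds `1 - minmax(HMD)` so that isolated entries score low, and
#' `minmax(NP_dist)` so that structure-preserving entries score low). A
#' degenerate term (all entries equal) is normalized to 0 and drops out.
#'
#' @param hmd_norm,np_norm normalized score components in `[0, 1]`.
#' @param beta trade-off weight in `[0, 1]`.
#' @return the combined score (same length as the inputs).
#' @export
combined_score <- function(hmd_norm, np_norm, beta = 0.5) {
  if (beta < 0 || beta > 1) stop("parameter error: beta must be in [0, 1]")
  beta * hmd_norm + (1 - beta) * np_norm
}

# Scores for every archive entry: objective-space HMD (after per-objective
# min-max normalization) and the NP quality term, combined into S.
archive_scores <- function(objectives, np_quality, beta) {
  n <- nrow(objectives)
  if (n == 1L) {
    return(list(hmd = Inf, S = 0))
  }
  norm_obj <- apply(objectives, 2L, minmax01)
  d <- row_dist(norm_obj)
  hmd <- vapply(seq_len(n), function(i) {
    harmonic_mean_distance(d[i, -i])
  }, 0)
  S <- combined_score(1 - minmax01(hmd), minmax01(np_quality), beta)
  list(hmd = hmd, S = S)
}

#' Update the bounded Pareto archive
#'
#' Merges candidate solutions into the archive, keeps the non-dominated set,
#' and truncates it to `cap` entries by repeatedly dropping the entries with
#' the worst (highest) combined score `S`. Removal proceeds in small batches
#' (at most a tenth of the excess, at least one entry) and the HMD/S scores
#' are recomputed after every batch, so the retained set stays spread out.
#'
#' @param archive list with matrices `positions`, `objectives`, and the
#'   vector `np_quality` (or `NULL` for an empty archive).
#' @param candidates same-shaped list of new solutions.
#' @param cap maximum archive size.
#' @param beta trade-off weight of [combined_score()].
#' @return the updated archive, with `hmd` and `S` fields refreshed.
#' @export
update_archive <- function(archive, candidates, cap, beta = 0.5) {
  merged <- if (is.null(archive) || length(archive$np_quality) == 0L) {
    candidates
  } else {
    list(positions = rbind(archive$positions, candidates$positions),
         objectives = rbind(archive$objectives, candidates$objectives),
         np_quality = c(archive$np_quality, candidates$np_quality))
  }
  keep <- nondominated_filter(merged$objectives)
  merged <- list(positions = merged$positions[keep, , drop = FALSE],
                 objectives = merged$objectives[keep, , drop = FALSE],
                 np_quality = merged$np_quality[keep])
  repeat {
    n <- length(merged$np_quality)
    sc <- archive_scores(merged$objectives, merged$np_quality, beta)
    merged$hmd <- sc$hmd
    merged$S <- sc$S
    excess <- n - cap
    if (excess <= 0L) break
    batch <- max(1L, min(excess, floor(excess / 10)))
    drop <- order(sc$S, decreasing = TRUE)[seq_len(batch)]
    merged$positions <- merged$positions[-drop, , drop = FALSE]
    merged$objectives <- merged$objectives[-drop, , drop = FALSE]
    merged$np_quality <- merged$np_quality[-drop]
  }
  merged
}
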