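# Multimodal multi-objective benchmark problems.
#
# The MMF family, the SYM-PART problems and the Omni-test are the standard
# bi-objective test suite for optimizers that must find several equivalent
# Pareto sets in decision space mapping onto one front (Yue, Qu & Liang,
# IEEE TEVC 2018; Rudolph et al. 2007; Deb & Tiwari 2005). Each problem
# carries its bounds, a vectorized objective map, analytic reference Pareto
# set/front samples, and the hypervolume reference point used in published
# evaluations of the suite.

mmf_names <- c("MMF1", "MMF2", "MMF3", "MMF4", "MMF5", "MMF6", "MMF7",
               "MMF8", "SYM_PART_SIMPLE", "SYM_PART_ROTATED", "OMNI3")

#' List the supported benchmark problems
#'
#' @return character vector of problem names accepted by [make_problem()].
#' @export
benchmark_names <- function() mmf_names

# The reference front is the analytic trade-off curve f2(f1), sampled on a
# fine uniform f1 grid united with the f1 values the reference Pareto set
# maps to (so PS samples land on the front to floating precision), and
# filtered to be strictly decreasing so the front is exactly mutually
# non-dominated.
new_problem <- function(name, n_var, lower, upper, fn, ps, curve, f1_range,
                        hv_ref, n_ref = 1000) {
  f1 <- sort(unique(c(seq(f1_range[1], f1_range[2], length.out = n_ref),
                      fn(ps)[, 1])))
  f2 <- curve(f1)
  keep <- logical(length(f1))
  last <- Inf
  for (i in seq_along(f1)) {
    if (f2[i] < last) {
      keep[i] <- TRUE
      last <- f2[i]
    }
  }
  pf <- cbind(f1[keep], f2[keep], deparse.level = 0)
  structure(list(name = name, n_var = n_var, lower = lower, upper = upper,
                 fn = fn, reference_ps = ps, reference_pf = pf,
                 hv_reference_point = hv_ref),
            class = "benchmark_problem")
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat(sprintf("benchmark problem %s: %d variables, 2 objectives\n",
              x$name, x$n_var))
  cat(sprintf("  bounds [%s] .. [%s]; HV reference (%s)\n",
              paste(x$lower, collapse = ", "),
              paste(x$upper, collapse = ", "),
              paste(x$hv_reference_point, collapse = ", ")))
  invisible(x)
}

# Two-branch helper used by most MMFs: deviation of x2 from the nearer of
# two copies of the optimal curve (the second copy shifted by `offset`).
# Both copies are exact Pareto-set branches; the deviation enters the
# objectives only through even functions.
branch_dev <- function(x2, curve, offset) {
  pmin(abs(x2 - curve), abs(x2 - offset - curve))
}

#' Construct a benchmark problem
#'
#' Returns the named problem with its decision-space bounds, vectorized
#' objective function (rows = decision vectors), analytic reference Pareto
#' set/front samples (`n_ref` points), and the problem's hypervolume
#' reference point.
#'
#' @param name one of [benchmark_names()] (case/('-','_')-insensitive;
#'   `"SYM-PART simple"`, `"Omni-test"` style spellings are accepted).
#' @param n_ref number of reference Pareto-set samples.
#' @return a `benchmark_problem`.
#' @export
make_problem <- function(name, n_ref = 1000) {
  key <- toupper(gsub("[ -]", "_", name))
  key <- sub("^OMNI_?TEST.*", "OMNI3", key)
  if (!key %in% mmf_names) {
    stop(sprintf("parameter error: unknown problem '%s'", name))
  }
  switch(
    key,
    MMF1 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- abs(x[, 1] - 2)
        t <- x[, 2] - sin(6 * pi * f1 + pi)
        cbind(f1, 1 - sqrt(f1) + 2 * t^2, deparse.level = 0)
      }
      g <- seq(1, 3, length.out = n_ref)
      ps <- cbind(g, sin(6 * pi * abs(g - 2) + pi))
      new_problem(key, 2L, c(1, -1), c(3, 1), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF2 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- x[, 1]
        t <- branch_dev(x[, 2], sqrt(f1), 1)
        cbind(f1, 1 - sqrt(f1) +
                2 * (4 * t^2 - 2 * cos(20 * t * pi / sqrt(2)) + 2),
              deparse.level = 0)
      }
      g <- seq(0, 1, length.out = ceiling(n_ref / 2))
      ps <- rbind(cbind(g, sqrt(g)), cbind(g, 1 + sqrt(g)))
      new_problem(key, 2L, c(0, 0), c(1, 2), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF3 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- x[, 1]
        t <- branch_dev(x[, 2], sqrt(f1), 0.5)
        cbind(f1, 1 - sqrt(f1) +
                2 * (4 * t^2 - 2 * cos(20 * t * pi / sqrt(2)) + 2),
              deparse.level = 0)
      }
      g1 <- seq(0, 0.25, length.out = ceiling(n_ref / 2))
      g2 <- seq(0, 1, length.out = ceiling(n_ref / 2))
      ps <- rbind(cbind(g1, sqrt(g1)), cbind(g2, 0.5 + sqrt(g2)))
      new_problem(key, 2L, c(0, 0), c(1, 1.5), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF4 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- abs(x[, 1])
        t <- branch_dev(x[, 2], sin(pi * f1), 1)
        cbind(f1, 1 - x[, 1]^2 + 2 * t^2, deparse.level = 0)
      }
      g <- seq(-1, 1, length.out = ceiling(n_ref / 2))
      ps <- rbind(cbind(g, sin(pi * abs(g))), cbind(g, 1 + sin(pi * abs(g))))
      new_problem(key, 2L, c(-1, 0), c(1, 2), fn, ps,
                  function(f) 1 - f^2, c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF5 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- abs(x[, 1] - 2)
        t <- branch_dev(x[, 2], sin(6 * pi * f1 + pi), 2)
        cbind(f1, 1 - sqrt(f1) + 2 * t^2, deparse.level = 0)
      }
      g <- seq(1, 3, length.out = ceiling(n_ref / 2))
      crv <- sin(6 * pi * abs(g - 2) + pi)
      ps <- rbind(cbind(g, crv), cbind(g, 2 + crv))
      new_problem(key, 2L, c(1, -1), c(3, 3), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF6 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- abs(x[, 1] - 2)
        t <- branch_dev(x[, 2], sin(6 * pi * f1 + pi), 1)
        cbind(f1, 1 - sqrt(f1) + 2 * t^2, deparse.level = 0)
      }
      g <- seq(1, 3, length.out = ceiling(n_ref / 2))
      crv <- sin(6 * pi * abs(g - 2) + pi)
      ps <- rbind(cbind(g, crv), cbind(g, 1 + crv))
      new_problem(key, 2L, c(1, -1), c(3, 2), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF7 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        f1 <- abs(x[, 1] - 2)
        crv <- (0.3 * f1^2 * cos(24 * pi * f1 + 4 * pi) + 0.6 * f1) *
          sin(6 * pi * f1 + pi)
        cbind(f1, 1 - sqrt(f1) + (x[, 2] - crv)^2, deparse.level = 0)
      }
      g <- seq(1, 3, length.out = n_ref)
      f1 <- abs(g - 2)
      crv <- (0.3 * f1^2 * cos(24 * pi * f1 + 4 * pi) + 0.6 * f1) *
        sin(6 * pi * f1 + pi)
      ps <- cbind(g, crv)
      new_problem(key, 2L, c(1, -1), c(3, 1), fn, ps,
                  function(f) 1 - sqrt(f), c(0, 1), c(1.1, 1.1), n_ref)
    },
    MMF8 = {
      fn <- function(x) {
        x <- matrix(x, ncol = 2)
        a <- abs(x[, 1])
        f1 <- sin(a)
        t <- branch_dev(x[, 2], sqrt(a), 4)
        cbind(f1, sqrt(pmax(1 - f1^2, 0)) + 2 * t^2, deparse.level = 0)
      }
      g <- seq(-pi, pi, length.out = ceiling(n_ref / 2))
      ps <- rbind(cbind(g, sqrt(abs(g))), cbind(g, 4 + sqrt(abs(g))))
      new_problem(key, 2L, c(-pi, 0), c(pi, 9), fn, ps,
                  function(f) sqrt(pmax(1 - f^2, 0)), c(0, 1),
                  c(1.1, 1.1), n_ref)
    },
    SYM_PART_SIMPLE = {
      fn <- sym_part_fn(rotate = FALSE)
      ps <- sym_part_ps(n_ref, rotate = FALSE)
      new_problem(key, 2L, c(-20, -20), c(20, 20), fn, ps,
                  function(f) (sqrt(f) - 2)^2, c(0, 4), c(4.4, 4.4), n_ref)
    },
    SYM_PART_ROTATED = {
      fn <- sym_part_fn(rotate = TRUE)
      ps <- sym_part_ps(n_ref, rotate = TRUE)
      new_problem(key, 2L, c(-20, -20), c(20, 20), fn, ps,
                  function(f) (sqrt(f) - 2)^2, c(0, 4), c(4.4, 4.4), n_ref)
    },
    OMNI3 = {
      n <- 3L
      fn <- function(x) {
        x <- matrix(x, ncol = 3)
        cbind(rowSums(sin(pi * x)), rowSums(cos(pi * x)), deparse.level = 0)
      }
      # 27 equivalent Pareto subsets: every variable in [1, 1.5] modulo 2
      base <- seq(1, 1.5, length.out = max(2L, ceiling(n_ref / 27)))
      shifts <- as.matrix(expand.grid(c(0, 2, 4), c(0, 2, 4), c(0, 2, 4)))
      ps <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i) {
        cbind(base + shifts[i, 1], base + shifts[i, 2], base + shifts[i, 3])
      }))
      new_problem(key, n, rep(0, 3), rep(6, 3), fn, ps,
                  function(f) -sqrt(pmax(9 - f^2, 0)), c(-3, 0),
                  c(5, 5), n_ref)
    }
  )
}

# SYM-PART tile parameters a = 1, b = 10, c = 8: nine translated copies of
# the same two-objective quadratic problem on a 3 x 3 grid of tiles.
sym_part_fn <- function(rotate) {
  a <- 1; b <- 10; cc <- 8
  w <- pi / 4
  function(x) {
    x <- matrix(x, ncol = 2)
    if (rotate) {
      x <- cbind(cos(w) * x[, 1] + sin(w) * x[, 2],
                 -sin(w) * x[, 1] + cos(w) * x[, 2])
    }
    t1 <- clamp(sign(x[, 1]) * ceiling((abs(x[, 1]) - a - cc / 2) / (2 * a + cc)),
                -1, 1)
    t2 <- clamp(sign(x[, 2]) * ceiling((abs(x[, 2]) - b / 2) / b), -1, 1)
    X1 <- x[, 1] - t1 * (cc + 2 * a)
    X2 <- x[, 2] - t2 * b
    cbind((X1 + a)^2 + X2^2, (X1 - a)^2 + X2^2, deparse.level = 0)
  }
}

sym_part_ps <- function(n_ref, rotate) {
  a <- 1; b <- 10; cc <- 8
  w <- pi / 4
  seg <- seq(-a, a, length.out = max(2L, ceiling(n_ref / 9)))
  tiles <- as.matrix(expand.grid(-1:1, -1:1))
  ps <- do.call(rbind, lapply(seq_len(nrow(tiles)), function(i) {
    cbind(seg + tiles[i, 1] * (cc + 2 * a), tiles[i, 2] * b)
  }))
  if (rotate) {
    ps <- cbind(cos(w) * ps[, 1] - sin(w) * ps[, 2],
                sin(w) * ps[, 1] + cos(w) * ps[, 2])
  }
  ps
}
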